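# Ground-truth panning simulator: a designed CDR repertoire with planted
# per-clone amplification fitness that is linear in positional residue
# identities, propagated through an exponential selection-amplification
# model and sampled into finite read counts. This provides the statistical
# structure the enrichment-score and model-training stages assume, with the
# truth tables needed for oracle tests.

#' Configuration for the panning simulator
#'
#' The defaults emulate the study conditions of a protein-A panning NGS
#' experiment on a designed repertoire: a few thousand designed clones of
#' one CDR-H3 length, three rounds of selection, about 10^6 reads per
#' repertoire, modest per-(position, residue) fitness effects whose implied
#' log10 fold-change spread leaves a small tail of clones beyond 20-fold
#' enrichment or depletion, and a mildly skewed pre-panning library
#' (symmetric Dirichlet, concentration 5).
#'
#' @param n_clones Number of designed clones (ignored when `sequences` is
#'   given).
#' @param length CDR length in amino acids.
#' @param sequences Optional explicit designed sequences.
#' @param effect_table Optional tibble (`position`, `residue`, `effect`)
#'   of per-round log-scale fitness effects; by default drawn
#'   `N(0, effect_sd)` for every (position, residue) over the 18 designed
#'   residues.
#' @param effect_sd Standard deviation of the default effect draw.
#' @param rounds Number of selection rounds (>= 1).
#' @param reads_per_repertoire Reads sampled per repertoire (recommended at
#'   least 10x the clone count).
#' @param noise_sd Clone-level fitness noise not explained by sequence.
#' @param dirichlet_concentration Symmetric Dirichlet concentration of the
#'   pre-panning frequencies.
#' @param seed Integer seed.
#' @return An object of class `panning_sim_config`.
#' @export
panning_sim_config <- function(n_clones = 5000, length = 9, sequences = NULL,
                               effect_table = NULL, effect_sd = 0.12,
                               rounds = 3, reads_per_repertoire = 1e6,
                               noise_sd = 0.05, dirichlet_concentration = 5,
                               seed = 1) {
  if (rounds < 1) abort("`rounds` must be at least 1.")
  if (!is.null(sequences)) {
    if (anyDuplicated(sequences)) abort("`sequences` must be unique.")
    if (length(unique(nchar(sequences))) != 1) abort("`sequences` must share one length.")
    length <- nchar(sequences[1])
    n_clones <- base::length(sequences)
  }
  if (n_clones < 2) abort("At least 2 clones are required.")
  if (reads_per_repertoire < 10 * n_clones) {
    warning("reads_per_repertoire < 10x clone count; counts will be very noisy.")
  }
  structure(
    list(n_clones = n_clones, length = length, sequences = sequences,
         effect_table = effect_table, effect_sd = effect_sd, rounds = rounds,
         reads_per_repertoire = reads_per_repertoire, noise_sd = noise_sd,
         dirichlet_concentration = dirichlet_concentration, seed = seed),
    class = "panning_sim_config"
  )
}

default_effect_table <- function(length, effect_sd) {
  tibble::tibble(
    position = rep(seq_len(length), each = base::length(aa_designed())),
    residue = rep(aa_designed(), times = length),
    effect = rnorm(length * base::length(aa_designed()), 0, effect_sd)
  )
}

sequence_fitness <- function(sequences, effect_table) {
  L <- nchar(sequences[1])
  eff <- matrix(0, nrow = L, ncol = 26,
                dimnames = list(NULL, LETTERS))
  eff[cbind(effect_table$position, match(effect_table$residue, LETTERS))] <-
    effect_table$effect
  chars <- matrix(match(unlist(strsplit(sequences, "")), LETTERS),
                  ncol = L, byrow = TRUE)
  rowSums(matrix(eff[cbind(rep(seq_len(L), each = base::length(sequences)),
                           as.vector(chars))],
                 ncol = L))
}

#' Simulate a pre/post panning read-count table with planted truth
#'
#' Draws pre-panning clone frequencies from a symmetric Dirichlet, assigns
#' each clone an amplification fitness `w = sum of positional effects +
#' N(0, noise_sd)`, propagates frequencies through `rounds` rounds of
#' exponential selection (`post proportional to pre * exp(rounds * w)`), and
#' samples each repertoire multinomially at the configured read depth. The
#' exponential-growth model is the minimal selection-amplification model
#' consistent with clone-dependent amplification efficiency; it is a test
#' harness, not a claim about panning physics.
#'
#' @param config A [panning_sim_config()].
#' @return A list with elements `counts` (a `cdr_counts` table with
#'   `designed = TRUE`) and `truth` (list: `effects` tibble, per-clone
#'   `clones` tibble with fitness and true frequencies, and the `config`).
#' @export
simulate_panning <- function(config) {
  stopifnot(inherits(config, "panning_sim_config"))
  with_seed(config$seed, {
    sequences <- as.vector(config$sequences %||% {
      model <- default_cdrh3_frequencies(config$length)
      simulate_cdrh3(model, config$n_clones, rules = list(),
                     seed = sample.int(2^31 - 1, 1))
    })
    n <- base::length(sequences)
    effects <- config$effect_table %||%
      default_effect_table(config$length, config$effect_sd)
    fitness <- sequence_fitness(sequences, effects) +
      rnorm(n, 0, config$noise_sd)
    g <- rgamma(n, shape = config$dirichlet_concentration, rate = 1)
    pre_freq <- g / sum(g)
    post_w <- pre_freq * exp(config$rounds * fitness)
    post_freq <- post_w / sum(post_w)
    count_pre <- as.integer(rmultinom(1, config$reads_per_repertoire, pre_freq))
    count_post <- as.integer(rmultinom(1, config$reads_per_repertoire, post_freq))
    counts <- new_cdr_counts(tibble::tibble(
      region = "H3",
      aa_seq = sequences,
      length = nchar(sequences),
      count_pre = count_pre,
      count_post = count_post,
      designed = TRUE
    ))
    truth <- list(
      effects = effects,
      clones = tibble::tibble(
        aa_seq = sequences, fitness = fitness,
        pre_freq = pre_freq, post_freq = post_freq
      ),
      config = config
    )
    list(counts = counts, truth = truth)
  })
}

#' Emit synthetic anchored reads from a count table
#'
#' Embeds each CDR between the scheme's framework anchors, repeats it
#' according to its read count in the chosen repertoire, optionally spikes in
#' anchored but non-designed contaminant CDRs, and shuffles the reads.
#' Feeding the result to [extract_cdrs()] reproduces the input counts
#' exactly (plus the contaminants).
#'
#' @param table A `cdr_counts` table.
#' @param scheme A [framework_scheme()].
#' @param repertoire Which repertoire's counts to emit.
#' @param seed Integer seed for shuffling and contaminant generation.
#' @param contaminant_fraction Fraction of emitted reads carrying random
#'   off-design CDRs (anchors intact).
#' @param alphabet `"aa"` emits amino-acid reads; `"nt"` reverse-translates
#'   them into nucleotide reads.
#' @param path Optional FASTA output path.
#' @return Character vector of reads (named `read1`, `read2`, ...).
#' @export
emit_reads <- function(table, scheme, repertoire = c("pre", "post"), seed = 1,
                       contaminant_fraction = 0, alphabet = c("aa", "nt"),
                       path = NULL) {
  repertoire <- match.arg(repertoire)
  alphabet <- match.arg(alphabet)
  stopifnot(inherits(scheme, "framework_scheme"))
  counts <- if (repertoire == "pre") table$count_pre else table$count_post
  with_seed(seed, {
    cdr_reads <- rep(table$aa_seq, counts)
    n_design <- base::length(cdr_reads)
    if (n_design == 0 && contaminant_fraction == 0) {
      reads <- setNames(character(0), character(0))
      if (!is.null(path)) {
        Biostrings::writeXStringSet(Biostrings::BStringSet(reads), path)
      }
      return(reads)
    }
    if (contaminant_fraction > 0 && n_design > 0) {
      n_cont <- round(n_design * contaminant_fraction / (1 - contaminant_fraction))
      pool_size <- max(20L, min(200L, ceiling(n_cont / 50)))
      pool <- character(0)
      while (base::length(pool) < pool_size) {
        cand <- vapply(seq_len(pool_size), function(i) {
          L <- sample(seq(scheme$length_range[1], scheme$length_range[2]), 1)
          paste(sample(aa_designed(), L, replace = TRUE), collapse = "")
        }, "")
        pool <- unique(c(pool, setdiff(cand, table$aa_seq)))
      }
      pool <- pool[seq_len(pool_size)]
      cdr_reads <- c(cdr_reads, sample(pool, n_cont, replace = TRUE))
    }
    reads <- paste0(scheme$left_anchor, cdr_reads, scheme$right_anchor)
    reads <- reads[sample.int(base::length(reads))]
    if (alphabet == "nt") reads <- reverse_translate(reads)
    names(reads) <- paste0("read", seq_along(reads))
    if (!is.null(path)) {
      Biostrings::writeXStringSet(Biostrings::BStringSet(reads), path)
    }
    reads
  })
}
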