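# Candidate CDR-H3 generation: sample sequences from positional amino-acid
# frequency tables (18 residues; no Cys/Met), rejecting sequences that carry
# liability motifs prone to post-translational modification.

#' Positional amino-acid frequency model
#'
#' Defines, for each position of a fixed CDR-H3 length, a probability
#' distribution over the 18 designed residues (cysteine and methionine are
#' excluded from the library design and must have zero probability).
#'
#' @param freq A data frame with columns `position` (1-based), `residue`,
#'   `probability`. Probabilities must sum to 1 at every position.
#' @return An object of class `position_frequency_model`: a list with the
#'   CDR length and an L x 18 probability matrix.
#' @export
position_frequency_model <- function(freq) {
  stopifnot(is.data.frame(freq),
            all(c("position", "residue", "probability") %in% names(freq)))
  L <- max(freq$position)
  if (!setequal(unique(freq$position), seq_len(L))) {
    abort("`position` must cover 1..L.")
  }
  bad <- freq$residue %in% c("C", "M") & freq$probability > 0
  if (any(bad)) abort("Cys and Met must have zero probability in designed CDRs.")
  mat <- matrix(0, nrow = L, ncol = length(aa_designed()),
                dimnames = list(NULL, aa_designed()))
  keep <- freq$residue %in% aa_designed()
  mat[cbind(freq$position[keep], match(freq$residue[keep], aa_designed()))] <-
    freq$probability[keep]
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("Probabilities must sum to 1 at every position.")
  }
  structure(list(length = L, prob = mat), class = "position_frequency_model")
}

#' @rdname position_frequency_model
#' @param path Path to a TSV with columns `position`, `residue`,
#'   `probability`.
#' @export
read_frequency_model <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    residue = readr::col_character(),
    probability = readr::col_double()
  ))
  position_frequency_model(df)
}

#' Default CDR-H3 positional frequencies (synthetic stand-in)
#'
#' A bundled stand-in frequency model that mimics coarse features of natural
#' human CDR-H3 amino-acid usage over the 18 designed residues: glycine,
#' serine, tyrosine and aspartate dominate overall, aspartate is favoured
#' toward the C-terminal end and tyrosine at the final position (the common
#' D-Y motif preceding the J-segment framework). It is a synthetic default
#' for simulation and testing, not a measured natural repertoire table;
#' supply your own table via [position_frequency_model()] for design work.
#'
#' @param length CDR-H3 length in amino acids (9 to 16).
#' @return A `position_frequency_model`.
#' @export
default_cdrh3_frequencies <- function(length) {
  if (length < 3 || length > 30) abort("`length` must be within [3, 30].")
  base <- c(
    A = 0.07, D = 0.08, E = 0.03, F = 0.05, G = 0.16, H = 0.02, I = 0.02,
    K = 0.02, L = 0.05, N = 0.04, P = 0.04, Q = 0.02, R = 0.06, S = 0.12,
    T = 0.05, V = 0.04, W = 0.03, Y = 0.10
  )
  base <- base / sum(base)
  rows <- lapply(seq_len(length), function(p) {
    w <- base
    if (p == length) {             # terminal position: Y-rich
      w[c("Y", "V")] <- w[c("Y", "V")] + c(0.20, 0.05)
    } else if (p == length - 1) {  # penultimate: D-rich
      w["D"] <- w["D"] + 0.18
    } else if (p <= 2) {           # stem positions: D/G-rich
      w[c("D", "G")] <- w[c("D", "G")] + 0.05
    }
    w / sum(w)
  })
  freq <- tibble::tibble(
    position = rep(seq_len(length), each = length(base)),
    residue = rep(names(base), times = length),
    probability = unlist(rows)
  )
  position_frequency_model(freq)
}

#' Liability motif rules
#'
#' A motif pattern is a short string over tokens: a plain residue letter
#' matches itself, `X` matches any residue, `[AB]` matches a residue class,
#' and `[^AB]` matches any residue outside the class. `motif_rule()` builds
#' one rule; `default_motif_rules()` returns the standard set of
#' post-translational-modification liabilities excluded from designed CDRs:
#' deamidation (NG, NS), isomerization (DG, DS), acid-labile cleavage (DP),
#' and the N-glycosylation sequon N-X-S/T with X != P.
#'
#' @param name Rule name.
#' @param pattern Degenerate pattern string (length >= 2 tokens).
#' @param rationale Free-text tag describing the liability.
#' @return An object of class `motif_rule`.
#' @export
motif_rule <- function(name, pattern, rationale = "") {
  tokens <- parse_motif_tokens(pattern)
  if (length(tokens) < 2) abort("Motif patterns must span at least 2 positions.")
  structure(list(name = name, pattern = pattern, tokens = tokens,
                 rationale = rationale, regex = motif_regex(tokens)),
            class = "motif_rule")
}

parse_motif_tokens <- function(pattern) {
  tokens <- list()
  i <- 1
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      neg <- FALSE
      if (j <= length(chars) && chars[j] == "^") {
        neg <- TRUE
        j <- j + 1
      }
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1
      }
      if (j > length(chars)) abort("Unterminated residue class in motif pattern.")
      tokens[[length(tokens) + 1]] <-
        if (neg) setdiff(aa_standard(), set) else set
      i <- j + 1
    } else if (ch == "X") {
      tokens[[length(tokens) + 1]] <- aa_standard()
      i <- i + 1
    } else if (ch %in% aa_standard()) {
      tokens[[length(tokens) + 1]] <- ch
      i <- i + 1
    } else {
      abort(sprintf("Invalid motif pattern character: '%s'", ch))
    }
  }
  tokens
}

motif_regex <- function(tokens) {
  paste0(vapply(tokens, function(t) {
    if (length(t) == 1) t else paste0("[", paste(t, collapse = ""), "]")
  }, ""), collapse = "")
}

#' @rdname motif_rule
#' @export
default_motif_rules <- function() {
  list(
    motif_rule("deamidation_NG", "NG", "Asn deamidation"),
    motif_rule("deamidation_NS", "NS", "Asn deamidation"),
    motif_rule("isomerization_DG", "DG", "Asp isomerization"),
    motif_rule("isomerization_DS", "DS", "Asp isomerization"),
    motif_rule("cleavage_DP", "DP", "acid-labile cleavage"),
    motif_rule("n_glycosylation", "N[^P][ST]", "N-glycosylation sequon")
  )
}

#' Read motif rules from a YAML file
#'
#' The YAML file holds a list of entries with fields `name`, `pattern` and,
#' optionally, `rationale`.
#'
#' @param path Path to a YAML file.
#' @return A list of [motif_rule()] objects.
#' @export
read_motif_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(r) motif_rule(r$name, r$pattern, r$rationale %||% ""))
}

#' Does a sequence contain a liability motif?
#'
#' @param aa_seq Character vector of amino-acid sequences.
#' @param rule A [motif_rule()].
#' @return Logical vector: `TRUE` where the pattern occurs at any offset.
#' @export
match_motif <- function(aa_seq, rule) {
  stopifnot(inherits(rule, "motif_rule"))
  grepl(rule$regex, aa_seq)
}

matches_any_motif <- function(aa_seq, rules) {
  hit <- rep(FALSE, length(aa_seq))
  for (rule in rules) hit <- hit | match_motif(aa_seq, rule)
  hit
}

#' Simulate candidate CDR-H3 sequences
#'
#' Samples unique sequences of the model's length position-by-position from
#' the positional frequency model, rejecting any sequence matching a
#' liability motif rule or duplicating an earlier draw. Sampling statistics
#' (draws, motif rejections, duplicate rejections) are attached as the
#' attribute `sampling_stats`.
#'
#' @param model A [position_frequency_model()].
#' @param n Number of unique sequences requested.
#' @param rules List of [motif_rule()]s (default [default_motif_rules()]).
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @param max_tries Total draw budget before giving up (default `100 * n`).
#' @return Character vector of `n` unique, motif-free sequences.
#' @export
simulate_cdrh3 <- function(model, n, rules = default_motif_rules(), seed = 1,
                           max_tries = 100 * n) {
  stopifnot(inherits(model, "position_frequency_model"))
  if (n < 1) abort("`n` must be at least 1.")
  residues <- colnames(model$prob)
  with_seed(seed, {
    accepted <- character(0)
    drawn <- 0L
    rej_motif <- 0L
    rej_dup <- 0L
    while (length(accepted) < n && drawn < max_tries) {
      batch <- min(max(2L * (n - length(accepted)), 100L), max_tries - drawn)
      drawn <- drawn + batch
      cols <- lapply(seq_len(model$length), function(p) {
        sample(residues, batch, replace = TRUE, prob = model$prob[p, ])
      })
      seqs <- do.call(paste0, cols)
      bad <- matches_any_motif(seqs, rules)
      rej_motif <- rej_motif + sum(bad)
      seqs <- seqs[!bad]
      dup <- duplicated(seqs) | seqs %in% accepted
      rej_dup <- rej_dup + sum(dup)
      accepted <- c(accepted, seqs[!dup])
    }
    if (length(accepted) < n) {
      abort(sprintf(
        "Could not generate %d unique motif-free sequences within %d draws (achieved %d).",
        n, max_tries, length(accepted)))
    }
    out <- accepted[seq_len(n)]
    attr(out, "sampling_stats") <- c(drawn = drawn, motif_rejected = rej_motif,
                                     duplicate_rejected = rej_dup)
    out
  })
}
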