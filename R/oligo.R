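# Oligonucleotide pool design: reverse-translate accepted CDRs with a
# human-preferred codon scheme (avoiding E. coli rare codons) and assemble
# fixed-length 136-nt oligos of the form
# adaptor5 + framework flank + CDR + framework flank + adaptor3.

# Human codon preference, most-used first, per amino acid.
human_codon_ranking <- function() {
  list(
    A = c("GCC", "GCT", "GCA", "GCG"),
    R = c("AGG", "AGA", "CGG", "CGC", "CGA", "CGT"),
    N = c("AAC", "AAT"),
    D = c("GAC", "GAT"),
    C = c("TGC", "TGT"),
    Q = c("CAG", "CAA"),
    E = c("GAG", "GAA"),
    G = c("GGC", "GGA", "GGG", "GGT"),
    H = c("CAC", "CAT"),
    I = c("ATC", "ATT", "ATA"),
    L = c("CTG", "CTC", "TTG", "CTT", "TTA", "CTA"),
    K = c("AAG", "AAA"),
    M = "ATG",
    F = c("TTC", "TTT"),
    P = c("CCC", "CCT", "CCA", "CCG"),
    S = c("AGC", "TCC", "TCT", "TCA", "AGT", "TCG"),
    T = c("ACC", "ACA", "ACT", "ACG"),
    W = "TGG",
    Y = c("TAC", "TAT"),
    V = c("GTG", "GTC", "GTT", "GTA")
  )
}

#' Codon selection scheme for reverse translation
#'
#' Selects one codon per amino acid: the most-used human codon, demoted to
#' the next-ranked human codon whenever the top choice belongs to the E. coli
#' rare-codon set (codons poorly decoded in the expression host). If every
#' codon of an amino acid is rare, the top human codon is used and the amino
#' acid is flagged.
#'
#' @param rare_codons Codons considered rare in E. coli.
#' @param usage Named list of human codons per amino acid, most-used first.
#' @return An object of class `codon_scheme` with elements `map` (named
#'   codon per amino acid), `flagged` (amino acids where a rare codon was
#'   unavoidable) and `rare_codons`.
#' @export
codon_scheme <- function(rare_codons = c("ATA", "AGG", "AGA", "CGA", "CTA", "CCC", "GGA"),
                         usage = human_codon_ranking()) {
  map <- character(0)
  flagged <- character(0)
  for (aa in names(usage)) {
    ok <- setdiff(usage[[aa]], rare_codons)
    if (length(ok)) {
      map[aa] <- ok[1]
    } else {
      map[aa] <- usage[[aa]][1]
      flagged <- c(flagged, aa)
    }
  }
  structure(list(map = map, flagged = flagged, rare_codons = rare_codons),
            class = "codon_scheme")
}

#' Reverse-translate a peptide deterministically
#'
#' @param aa_seq Character vector of amino-acid sequences (standard residues
#'   only).
#' @param scheme A [codon_scheme()].
#' @return Character vector of nucleotide sequences; translating each result
#'   with the standard genetic code reproduces the input.
#' @export
reverse_translate <- function(aa_seq, scheme = codon_scheme()) {
  if (!all(is_aa_string(aa_seq))) abort("Input must use the 20 standard residues.")
  vapply(strsplit(aa_seq, ""), function(ch) {
    paste(scheme$map[ch], collapse = "")
  }, "")
}

# Standard-code translation of nucleotide strings (helper around Biostrings).
nt_to_aa <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Region configuration for oligo assembly
#'
#' Holds the common PCR adaptor sequences and the framework nucleotide
#' context on both sides of the CDR insertion point. Flanks must be given in
#' the coding orientation with their inner edges abutting the CDR; they are
#' trimmed distally during assembly.
#'
#' @param adaptor5,adaptor3 Common adaptor nucleotide sequences.
#' @param flank5,flank3 Framework nucleotide context before/after the CDR.
#' @return An object of class `region_config`.
#' @export
region_config <- function(adaptor5, adaptor3, flank5, flank3) {
  for (s in c(adaptor5, adaptor3, flank5, flank3)) {
    if (!is_nt_string(s) || grepl("[UN]", s)) {
      abort("Adaptors and flanks must be unambiguous DNA strings.")
    }
  }
  structure(list(adaptor5 = adaptor5, adaptor3 = adaptor3,
                 flank5 = flank5, flank3 = flank3),
            class = "region_config")
}

#' Default CDR-H3 region configuration
#'
#' Adaptor sequences and framework flanks are inherently configuration (they
#' depend on the synthesis vendor and the scaffold construct); this default
#' uses 20-nt adaptors and flanks reverse-translated from the VH3-23
#' framework-3 tail and framework-4 head so that examples and tests can run
#' end to end.
#'
#' @param scheme A [codon_scheme()] used to build the framework flanks.
#' @return A [region_config()].
#' @export
default_h3_region_config <- function(scheme = codon_scheme()) {
  region_config(
    adaptor5 = "CTACACGACGCTCTTCCGAT",
    adaptor3 = "AGATCGGAAGAGCACACGTC",
    flank5 = reverse_translate("GRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK", scheme),
    flank3 = reverse_translate("WGQGTLVTVSSGGGGSGGGG", scheme)
  )
}

#' Assemble fixed-length oligonucleotides for designed CDRs
#'
#' Reverse-translates each CDR and pads it with framework flank bases so that
#' adaptor5 + flank5 + CDR + flank3 + adaptor3 is exactly `total_length`
#' (136) nucleotides. Flanks keep their CDR-adjacent (inner) bases — the PCR
#' priming context — and are trimmed distally; when the flank budget is odd,
#' the extra base goes to the 5' side.
#'
#' @param cdrs Character vector of CDR amino-acid sequences.
#' @param config A [region_config()].
#' @param scheme A [codon_scheme()].
#' @param total_length Total oligo length in nucleotides (default 136).
#' @return A tibble with columns `name`, `cdr_aa`, `length_bin` (CDR length
#'   in aa), the five segments (`adaptor5`, `flank5`, `cdr_nt`, `flank3`,
#'   `adaptor3`), `oligo`, and `total_len`.
#' @export
assemble_oligos <- function(cdrs, config = default_h3_region_config(),
                            scheme = codon_scheme(), total_length = 136) {
  stopifnot(inherits(config, "region_config"))
  cdr_nt <- reverse_translate(cdrs, scheme)
  fixed <- nchar(config$adaptor5) + nchar(config$adaptor3)
  rem <- total_length - fixed - nchar(cdr_nt)
  if (any(rem < 0)) {
    abort(sprintf("CDR too long for a %d-nt oligo with these adaptors.", total_length))
  }
  f5_len <- ceiling(rem / 2)
  f3_len <- rem - f5_len
  if (any(f5_len > nchar(config$flank5)) || any(f3_len > nchar(config$flank3))) {
    abort("Framework flank exhausted: configured flanks are too short to fill the oligo.")
  }
  f5 <- substr(rep(config$flank5, length(cdrs)),
               nchar(config$flank5) - f5_len + 1, nchar(config$flank5))
  f3 <- substr(rep(config$flank3, length(cdrs)), 1, f3_len)
  out <- tibble::tibble(
    name = sprintf("H3_L%02d_%05d", nchar(cdrs), seq_along(cdrs)),
    cdr_aa = cdrs,
    length_bin = nchar(cdrs),
    adaptor5 = config$adaptor5,
    flank5 = f5,
    cdr_nt = cdr_nt,
    flank3 = f3,
    adaptor3 = config$adaptor3
  )
  out$oligo <- paste0(out$adaptor5, out$flank5, out$cdr_nt, out$flank3, out$adaptor3)
  out$total_len <- nchar(out$oligo)
  stopifnot(all(out$total_len == total_length))
  structure(out, class = c("oligo_tbl", class(tibble::tibble())))
}

#' In-frame peptide of the framework + CDR portion of an oligo
#'
#' Translates the flank5 + CDR + flank3 segment in the reading frame fixed by
#' the CDR (the kept 5' flank need not be a whole number of codons). Used to
#' verify translation consistency of assembled oligos.
#'
#' @param oligos An `oligo_tbl` from [assemble_oligos()].
#' @return A tibble with columns `name`, `peptide`, `cdr_aa_start` (1-based
#'   position of the CDR within the peptide).
#' @export
oligo_peptides <- function(oligos) {
  region <- paste0(oligos$flank5, oligos$cdr_nt, oligos$flank3)
  offset <- nchar(oligos$flank5) %% 3  # partial codon carried by the 5' flank
  start <- ifelse(offset == 0, 1L, offset + 1L)
  usable <- floor((nchar(region) - start + 1) / 3) * 3
  peptide <- nt_to_aa(substr(region, start, start + usable - 1))
  tibble::tibble(
    name = oligos$name,
    peptide = peptide,
    cdr_aa_start = (nchar(oligos$flank5) - start + 1L) / 3L + 1L
  )
}

#' Bin oligos by CDR length
#'
#' CDR-H3 oligo pools are length-separated before amplification; this
#' partitions the design by CDR amino-acid length.
#'
#' @param oligos An `oligo_tbl`.
#' @param range Permitted CDR length range (default 9-16 aa for CDR-H3).
#' @return Named list of `oligo_tbl` subsets keyed by length; bin counts are
#'   attached as attribute `bin_counts`.
#' @export
bin_by_length <- function(oligos, range = c(9L, 16L)) {
  if (nrow(oligos) == 0) {
    return(structure(list(), bin_counts = integer(0)))
  }
  bad <- oligos$length_bin < range[1] | oligos$length_bin > range[2]
  if (any(bad)) {
    abort(sprintf("CDR length outside [%d, %d]: %s", range[1], range[2],
                  paste(unique(oligos$length_bin[bad]), collapse = ", ")))
  }
  lens <- sort(unique(oligos$length_bin))
  out <- lapply(lens, function(L) oligos[oligos$length_bin == L, , drop = FALSE])
  names(out) <- lens
  attr(out, "bin_counts") <- setNames(vapply(out, nrow, 0L), names(out))
  out
}

#' Write an oligo pool to FASTA or TSV
#'
#' @param oligos An `oligo_tbl`.
#' @param path Output path.
#' @return `oligos`, invisibly.
#' @export
write_oligos_fasta <- function(oligos, path) {
  set <- Biostrings::DNAStringSet(setNames(oligos$oligo, oligos$name))
  Biostrings::writeXStringSet(set, path)
  invisible(oligos)
}

#' @rdname write_oligos_fasta
#' @export
write_oligos_tsv <- function(oligos, path) {
  readr::write_tsv(tibble::as_tibble(oligos), path)
  invisible(oligos)
}
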