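# Shared constants and small helpers.

#' Amino-acid alphabets
#'
#' `aa_standard()` returns the 20 standard residues; `aa_designed()` returns
#' the 18 residues permitted in designed CDRs (cysteine and methionine are
#' excluded from the library design because of their oxidation/disulfide
#' liabilities).
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_standard
#' @export
aa_designed <- function() {
  setdiff(aa_standard(), c("C", "M"))
}

is_aa_string <- function(x, alphabet = aa_standard()) {
  !is.na(x) & nchar(x) > 0 &
    !grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), x)
}

is_nt_string <- function(x) {
  !is.na(x) & nchar(x) > 0 & !grepl("[^ACGTUN]", x)
}

# Round half away from zero at a fixed number of decimals (the convention used
# for reported percentages and means; base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Read sequences from a character vector, an XStringSet, or a FASTA/FASTQ
# file path; returns a plain uppercase character vector.
as_sequence_vector <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    return(toupper(as.character(reads)))
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    set <- Biostrings::readBStringSet(reads, format = fmt)
    return(toupper(as.character(set)))
  }
  if (!is.character(reads)) {
    abort("`reads` must be a character vector, an XStringSet, or a file path.")
  }
  toupper(reads)
}
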