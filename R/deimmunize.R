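# T-cell epitope exclusion: flank each CDR with its 8-residue framework
# context, enumerate overlapping 9-mers, and discard any CDR with a window
# predicted to bind strongly (top 0.5 percentile rank) to any allele of a
# 20-allele HLA-DRB panel. The MHC-II predictor itself is pluggable:
# precomputed percentile-rank tables are imported from TSV, and a
# deterministic toy scorer is provided for tests.

#' The 20-allele HLA-DRB panel
#'
#' The most frequent HLA-DRB alleles across Caucasian, East Asian, Black and
#' Hispanic populations, used as the default panel for epitope screening.
#'
#' @return Character vector of 20 allele names.
#' @export
drb_allele_panel <- function() {
  c("DRB1*01:01", "DRB1*03:01", "DRB1*03:02", "DRB1*04:01", "DRB1*04:04",
    "DRB1*04:05", "DRB1*07:01", "DRB1*08:02", "DRB1*08:03", "DRB1*09:01",
    "DRB1*11:01", "DRB1*13:01", "DRB1*13:02", "DRB1*12:02", "DRB1*14:01",
    "DRB1*15:01", "DRB1*15:03", "DRB3*01:01", "DRB4*01:01", "DRB5*01:01")
}

#' Enumerate overlapping 9-mer windows over a flanked CDR
#'
#' Prepends and appends the adjoining 8-residue framework sequences to the
#' CDR and slides a 9-residue window with step 1 over the result, so every
#' peptide register spanning at least one CDR residue is covered. A CDR of
#' length L yields L + 8 windows.
#'
#' @param cdr_seq CDR amino-acid sequence.
#' @param left_flank,right_flank Adjoining framework context, exactly 8
#'   residues each.
#' @return An object of class `epitope_query`: the CDR, flanks, and the
#'   ordered character vector of 9-mer windows.
#' @export
make_windows <- function(cdr_seq, left_flank, right_flank) {
  if (nchar(left_flank) != 8 || nchar(right_flank) != 8) {
    abort("Flanks must be exactly 8 amino acids.")
  }
  if (!is_aa_string(cdr_seq) || !is_aa_string(left_flank) || !is_aa_string(right_flank)) {
    abort("CDR and flanks must be amino-acid strings.")
  }
  full <- paste0(left_flank, cdr_seq, right_flank)
  n_win <- nchar(full) - 9 + 1
  windows <- substring(full, seq_len(n_win), seq_len(n_win) + 8)
  structure(list(cdr_seq = cdr_seq, left_flank = left_flank,
                 right_flank = right_flank, windows = windows),
            class = "epitope_query")
}

#' Build epitope queries for many CDRs
#'
#' @param cdrs Character vector of CDR sequences.
#' @inheritParams make_windows
#' @return A tibble with one row per (CDR, window): columns `cdr_seq`,
#'   `offset` (1-based start in the flanked sequence), `window`.
#' @export
epitope_queries <- function(cdrs, left_flank, right_flank) {
  qs <- lapply(cdrs, make_windows, left_flank = left_flank,
               right_flank = right_flank)
  tibble::tibble(
    cdr_seq = rep(cdrs, vapply(qs, function(q) length(q$windows), 0L)),
    offset = unlist(lapply(qs, function(q) seq_along(q$windows))),
    window = unlist(lapply(qs, function(q) q$windows))
  )
}

#' Deterministic toy MHC-II percentile scorer
#'
#' A stand-in predictor for tests and examples: maps each (window, allele)
#' pair to a reproducible pseudo-uniform percentile rank in (0, 100] via an
#' integer hash of the peptide and allele strings. It carries no biology;
#' real screening must import percentile ranks from an external MHC-II
#' predictor via [read_mhc2_predictions()].
#'
#' @param windows Character vector of 9-mer peptides.
#' @param alleles Allele panel (default [drb_allele_panel()]).
#' @return A tibble with columns `window`, `allele`, `percentile_rank`.
#' @export
toy_mhc2_predict <- function(windows, alleles = drb_allele_panel()) {
  windows <- unique(windows)
  grid <- tidyr::expand_grid(window = windows, allele = alleles)
  hash_string <- function(s) {
    vapply(strsplit(s, ""), function(ch) {
      h <- 7
      for (c in utf8ToInt(paste(ch, collapse = ""))) {
        h <- (h * 131 + c) %% 1048573
      }
      h
    }, 0)
  }
  h <- (hash_string(grid$window) * 31 + hash_string(grid$allele)) %% 1048573
  grid$percentile_rank <- (h %% 100000 + 1) / 1000
  grid
}

#' Import precomputed MHC-II percentile ranks
#'
#' Reads a TSV with columns `window`, `allele`, `percentile_rank`, as
#' exported from an external MHC-II binding predictor run on the enumerated
#' 9-mer windows.
#'
#' @param path TSV path.
#' @return A tibble with columns `window`, `allele`, `percentile_rank`.
#' @export
read_mhc2_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    window = readr::col_character(),
    allele = readr::col_character(),
    percentile_rank = readr::col_double()
  ))
}

#' Discard CDRs with predicted MHC-II strong binders
#'
#' A CDR is discarded when any of its 9-mer windows has a percentile rank at
#' or below the threshold (default 0.5, i.e. within the top 0.5% of
#' predicted binders) for any allele of the panel. The threshold comparison
#' is inclusive. Lowering the threshold can only move CDRs from discarded to
#' kept (filtering is monotone in the threshold).
#'
#' @param queries A tibble from [epitope_queries()] (columns `cdr_seq`,
#'   `window`).
#' @param predictions A tibble with columns `window`, `allele`,
#'   `percentile_rank` covering every (window, allele) combination of the
#'   queries and panel; see [toy_mhc2_predict()] and
#'   [read_mhc2_predictions()].
#' @param threshold Percentile-rank threshold for a strong binder.
#' @param alleles Allele panel that must be covered.
#' @return A list with elements `kept` (character vector of retained CDRs)
#'   and `discarded` (tibble of offending `cdr_seq`, `window`, `allele`,
#'   `percentile_rank`).
#' @export
filter_strong_binders <- function(queries, predictions, threshold = 0.5,
                                  alleles = drb_allele_panel()) {
  predictions <- predictions[predictions$allele %in% alleles, , drop = FALSE]
  need <- tidyr::expand_grid(window = unique(queries$window), allele = alleles)
  have <- paste(predictions$window, predictions$allele)
  missing <- need[!paste(need$window, need$allele) %in% have, , drop = FALSE]
  if (nrow(missing) > 0) {
    abort(sprintf(
      "Missing predictions for %d (window, allele) pairs, e.g. %s / %s.",
      nrow(missing), missing$window[1], missing$allele[1]))
  }
  hits <- dplyr::inner_join(queries, predictions, by = "window",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$percentile_rank <= threshold) |>
    dplyr::select("cdr_seq", "window", "allele", "percentile_rank") |>
    dplyr::arrange(.data$cdr_seq, .data$window, .data$allele)
  list(
    kept = setdiff(unique(queries$cdr_seq), unique(hits$cdr_seq)),
    discarded = hits
  )
}
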