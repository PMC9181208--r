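# Reporting helpers: the published aggregate statistics of the library
# validation campaign, recomputed from bundled transcriptions of the printed
# tables. Arm labels are "T" (the redesigned, amplification-optimized
# library) and "S" (the source library whose panning NGS data trained the
# design). "ND" cells are stored as missing and excluded from sums.

pandesign_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pandesign")
  if (!nzchar(path)) abort(sprintf("Bundled fixture '%s' not found.", file))
  path
}

#' Bundled validation tables
#'
#' Loaders for the transcribed summary tables of the library validation:
#' per-sub-library sizes and dot-blot positives (`sub_library_sizes()`),
#' panning outcomes per antigen/arm/round (`panning_outcomes()`), SPR
#' binding kinetics of isolated binders (`binding_kinetics()`), and purified
#' scFv expression yields and monomer content (`scfv_expression()`).
#' Dot-blot positive counts were back-calculated from the printed
#' percentages at 22 assayed clones per sub-library (the pooled denominators
#' are 176 = 8 x 22 per light-chain class).
#'
#' @return A tibble.
#' @export
sub_library_sizes <- function() {
  readr::read_tsv(pandesign_extdata("sub_library_sizes.tsv"),
                  col_types = "icdii")
}

#' @rdname sub_library_sizes
#' @export
panning_outcomes <- function() {
  readr::read_tsv(pandesign_extdata("panning_outcomes.tsv"),
                  col_types = "cciiiii", na = "NA")
}

#' @rdname sub_library_sizes
#' @export
binding_kinetics <- function() {
  readr::read_tsv(pandesign_extdata("binding_kinetics.tsv"),
                  col_types = "ccddd")
}

#' @rdname sub_library_sizes
#' @export
scfv_expression <- function() {
  readr::read_tsv(pandesign_extdata("scfv_expression.tsv"),
                  col_types = "ccdd")
}

#' Pooled unique-binder fraction for a library arm and panning round
#'
#' Sums unique and sequenced binder counts over all antigens for the rows of
#' one library arm (matched by name prefix) and round, skipping undetermined
#' cells, and reports the percentage of unique sequences rounded to the
#' integer.
#'
#' @param rows Panning outcome rows (see [panning_outcomes()]).
#' @param library_prefix Arm prefix, e.g. `"T"` or `"S"`.
#' @param round Panning round.
#' @return A one-row tibble: `unique`, `sequenced`, `percent`.
#' @export
unique_fraction <- function(rows, library_prefix, round) {
  sel <- rows[startsWith(rows$library, library_prefix) &
                rows$round == round &
                !is.na(rows$unique) & !is.na(rows$sequenced), , drop = FALSE]
  if (nrow(sel) == 0) abort("No determined rows match this arm and round.")
  u <- sum(sel$unique)
  s <- sum(sel$sequenced)
  tibble::tibble(unique = u, sequenced = s,
                 percent = round_half_up(100 * u / s))
}

#' Mean dissociation constant in nanomolar
#'
#' Arithmetic mean of the K_D column over the selected kinetics rows,
#' converted from molar to nanomolar and rounded to the integer.
#'
#' @param rows Kinetics rows (see [binding_kinetics()]).
#' @param antigen Optional antigen filter.
#' @return Mean K_D in nM (numeric scalar).
#' @export
mean_kd <- function(rows, antigen = NULL) {
  if (!is.null(antigen)) rows <- rows[rows$antigen %in% antigen, , drop = FALSE]
  if (nrow(rows) == 0) abort("No kinetics rows selected.")
  round_half_up(mean(rows$k_d) * 1e9)
}

#' Internal-consistency check of kinetics rows
#'
#' Each row should satisfy K_D = k_off / k_on up to the printed rounding.
#'
#' @param rows Kinetics rows.
#' @return The rows with `kd_ratio` (k_off / k_on) and `rel_dev`, the
#'   relative deviation of the printed K_D from that ratio.
#' @export
kinetics_consistency <- function(rows) {
  dplyr::mutate(rows,
                kd_ratio = .data$k_off / .data$k_on,
                rel_dev = abs(.data$k_d - .data$kd_ratio) / .data$kd_ratio)
}

#' Expected in-frame fraction of a multi-CDR library
#'
#' With a per-CDR in-frame probability `p` after proofread panning, a clone
#' carrying `k` independently assembled CDRs is fully in-frame with
#' probability `p^k`; at `p = 0.9` and six CDRs this predicts ~53% of clones
#' expressing full-length scFv.
#'
#' @param p Per-CDR in-frame probability in `[0, 1]`.
#' @param k Number of CDRs (>= 1).
#' @return `p^k` rounded to two decimals.
#' @export
expected_inframe <- function(p, k) {
  if (p < 0 || p > 1 || k < 1) abort("Require 0 <= p <= 1 and k >= 1.")
  round_half_up(p^k, 2)
}

#' Library size and dot-blot summary per light-chain class
#'
#' Sums the sub-library transformation titers within each light-chain class
#' (reported both raw and at two significant figures) and pools the dot-blot
#' counts into a class-level positive percentage.
#'
#' @param rows Sub-library rows (see [sub_library_sizes()]); 8 rows per
#'   class expected.
#' @return A tibble per class: `light_chain`, `total_size`,
#'   `total_size_2sf`, `dot_blot_positive`, `dot_blot_assayed`,
#'   `dot_blot_pct` (one decimal).
#' @export
library_size_summary <- function(rows) {
  counts <- table(rows$light_chain)
  if (any(counts != 8)) abort("Expected 8 sub-library rows per light-chain class.")
  rows |>
    dplyr::group_by(.data$light_chain) |>
    dplyr::summarise(
      total_size = sum(.data$size),
      total_size_2sf = signif(sum(.data$size), 2),
      dot_blot_positive = sum(.data$dot_blot_positive),
      dot_blot_assayed = sum(.data$dot_blot_assayed),
      dot_blot_pct = round_half_up(
        100 * sum(.data$dot_blot_positive) / sum(.data$dot_blot_assayed), 1),
      .groups = "drop"
    )
}

#' Per-arm expression yield and monomer summaries
#'
#' Mean and sample standard deviation of purified yield and monomeric
#' percentage per library arm, rounded to one decimal.
#'
#' @param rows Expression rows (see [scfv_expression()]).
#' @return A tibble per arm with `mean_yield`, `sd_yield`, `mean_monomer`,
#'   `sd_monomer`, `n`.
#' @export
expression_summary <- function(rows) {
  rows |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_yield = round_half_up(mean(.data$yield_mg_per_l), 1),
      sd_yield = round_half_up(sd(.data$yield_mg_per_l), 1),
      mean_monomer = round_half_up(mean(.data$pct_monomer), 1),
      sd_monomer = round_half_up(sd(.data$pct_monomer), 1),
      .groups = "drop"
    )
}
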