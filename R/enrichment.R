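# The per-sequence enrichment score (ES): a log2 frequency ratio between the
# post- and pre-panning repertoires, weighted by a read-count confidence term
# normalized to the median per-sequence counts of the designed set.

#' Repertoire context for enrichment-score computation
#'
#' Holds the total read counts of the pre- and post-panning repertoires and
#' the medians of the per-sequence read counts over the designed sequence
#' set, all of which enter the ES formula.
#'
#' @param N_pre,N_post Total read counts per repertoire.
#' @param med_pre,med_post Medians of per-sequence counts (after
#'   pseudocounting) over the designed set.
#' @return An object of class `es_context`.
#' @export
es_context <- function(N_pre, N_post, med_pre, med_post) {
  vals <- c(N_pre = N_pre, N_post = N_post, med_pre = med_pre, med_post = med_post)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All context terms must be strictly positive.")
  }
  structure(as.list(vals), class = "es_context")
}

#' Compute the enrichment score
#'
#' For a sequence with read counts `n_pre` and `n_post` in repertoires of
#' total size `N_pre` and `N_post`,
#' \deqn{ES = \log_2\frac{n_{post}/N_{post}}{n_{pre}/N_{pre}} \times
#'   \frac{n_{post}+n_{pre}}{\mathrm{median}(n_{post})+\mathrm{median}(n_{pre})}}
#' The first factor measures the frequency change through panning; the second
#' up-weights sequences observed at high depth relative to the typical
#' (median) sequence, for which the frequency ratio is better determined.
#' A raw count of zero is replaced by `pseudocount` in both factors, so that
#' fully depleted (or newly appearing) sequences get a finite score.
#'
#' @param n_pre,n_post Read counts (vectors) of each sequence.
#' @param ctx An [es_context()].
#' @param pseudocount Replacement for zero raw counts (default 0.5).
#' @return Numeric vector of enrichment scores.
#' @examples
#' ctx <- es_context(1e6, 1e6, 10, 20)
#' compute_es(10, 40, ctx)  # log2(4) * 50/30 = 10/3
#' @export
compute_es <- function(n_pre, n_post, ctx, pseudocount = 0.5) {
  stopifnot(inherits(ctx, "es_context"))
  if (any(n_pre < 0 | n_post < 0)) abort("Counts must be non-negative.")
  if (any(n_pre == 0 & n_post == 0)) {
    abort("unobserved_sequence: both counts are zero.")
  }
  np <- ifelse(n_pre == 0, pseudocount, n_pre)
  nq <- ifelse(n_post == 0, pseudocount, n_post)
  log2((nq / ctx$N_post) / (np / ctx$N_pre)) * (nq + np) / (ctx$med_post + ctx$med_pre)
}

#' Enrichment-score table for a designed repertoire
#'
#' Computes one enrichment record per designed sequence observed in at least
#' one repertoire. Totals are the table's repertoire read sums; medians are
#' taken over the designed set itself, per repertoire, after pseudocounting.
#' Alongside the ES, the log10 frequency ratio (`log10_fold`) is stored: a
#' value of 1.3 corresponds to a 20-fold enrichment.
#'
#' @param table A `cdr_counts` table, typically whitelisted with
#'   [apply_whitelist()]. If a `designed` column is present, only designed
#'   rows are used.
#' @param pseudocount Replacement for zero raw counts (default 0.5).
#' @param totals Optional `c(pre, post)` whole-library total read counts to
#'   use as the frequency denominators; by default the column sums of the
#'   (designed) table. Supply the full-library totals when the table has
#'   been restricted to a whitelist but frequencies should refer to the
#'   complete sequenced repertoire.
#' @return A tibble of class `es_tbl` with columns `aa_seq`, `length`,
#'   `n_pre`, `n_post`, `es`, `log10_fold`, `pseudocounted`; the
#'   [es_context()] used is attached as attribute `context`.
#' @export
es_table <- function(table, pseudocount = 0.5, totals = NULL) {
  df <- tibble::as_tibble(table)
  if ("designed" %in% names(df) && !all(is.na(df$designed))) {
    df <- df[df$designed %in% c(TRUE, NA), , drop = FALSE]
  }
  df <- df[df$count_pre + df$count_post > 0, , drop = FALSE]
  if (nrow(df) == 0) abort("No designed sequences observed in either repertoire.")
  N_pre <- totals[1] %||% sum(df$count_pre)
  N_post <- totals[2] %||% sum(df$count_post)
  np <- ifelse(df$count_pre == 0, pseudocount, df$count_pre)
  nq <- ifelse(df$count_post == 0, pseudocount, df$count_post)
  ctx <- es_context(N_pre, N_post, median(np), median(nq))
  out <- tibble::tibble(
    aa_seq = df$aa_seq,
    length = df$length,
    n_pre = df$count_pre,
    n_post = df$count_post,
    es = compute_es(df$count_pre, df$count_post, ctx, pseudocount = pseudocount),
    log10_fold = log10((nq / N_post) / (np / N_pre)),
    pseudocounted = df$count_pre == 0 | df$count_post == 0
  )
  out <- structure(out, class = c("es_tbl", class(tibble::tibble())))
  attr(out, "context") <- ctx
  out
}

#' Histogram of log10 fold enrichment
#'
#' Bins the per-sequence log10 frequency ratios in increments of `bin_width`
#' (default 0.1). Sequences whose frequency changed 20-fold or more
#' (`|log10_fold| > tail_cutoff` with the default 1.3) are additionally
#' tallied in the attribute `tail_counts`.
#'
#' @param records An `es_tbl` from [es_table()].
#' @param bin_width Bin width on the log10 scale.
#' @param tail_cutoff Absolute log10 fold change defining the reported tails.
#' @return A tibble with columns `bin_low`, `bin_high`, `bin_mid`, `n`;
#'   bin counts sum to `nrow(records)`.
#' @export
fold_histogram <- function(records, bin_width = 0.1, tail_cutoff = 1.3) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  idx <- floor(records$log10_fold / bin_width + 1e-9)
  tab <- table(idx)
  bins <- as.integer(names(tab))
  out <- tibble::tibble(
    bin_low = bins * bin_width,
    bin_high = (bins + 1) * bin_width,
    bin_mid = (bins + 0.5) * bin_width,
    n = as.integer(tab)
  )
  attr(out, "tail_counts") <- c(
    below = sum(records$log10_fold < -tail_cutoff),
    above = sum(records$log10_fold > tail_cutoff)
  )
  out
}

#' Split sequences by fold enrichment for logo rendering
#'
#' Partitions the repertoire into the sequences enriched more than
#' `threshold`-fold (frequency ratio strictly above `threshold`) and those
#' depleted more than `threshold`-fold (ratio strictly below
#' `1/threshold`), the two sub-repertoires compared by sequence logos.
#'
#' @param records An `es_tbl` from [es_table()].
#' @param threshold Fold-change threshold (default 2).
#' @return A list with elements `enriched` and `depleted`, each an `es_tbl`
#'   subset.
#' @seealso [write_logo_sequences()]
#' @export
split_by_fold <- function(records, threshold = 2) {
  ratio <- 10^records$log10_fold
  list(
    enriched = records[ratio > threshold, , drop = FALSE],
    depleted = records[ratio < 1 / threshold, , drop = FALSE]
  )
}

#' Write sequences one per line for external logo tools
#'
#' @param records An `es_tbl` (or any tibble with an `aa_seq` column).
#' @param path Output text path.
#' @return `records`, invisibly.
#' @export
write_logo_sequences <- function(records, path) {
  writeLines(records$aa_seq, path)
  invisible(records)
}

#' Positional amino-acid frequency shifts between repertoires
#'
#' For sequences of one CDR-H3 length, computes the read-count-weighted
#' frequency of each residue at each position in the pre- and post-panning
#' repertoires and tests each (position, residue) shift with a two-proportion
#' z-test (pooled variance, no continuity correction). Positions are labelled
#' in the Kabat convention, numbering from H95. Residues absent from both
#' repertoires at a position are omitted.
#'
#' @param records An `es_tbl` from [es_table()].
#' @param length CDR length (aa) to analyse; `records` is subset to it.
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across all (position, residue) tests.
#' @return A tibble with columns `position` (Kabat label), `residue`,
#'   `f_pre`, `f_post`, `delta`, `z`, `p_value`, `stars` (`*` for p < 0.05,
#'   `**` for p < 0.01).
#' @export
positional_shifts <- function(records, length, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  rec <- records[records$length == length, , drop = FALSE]
  if (nrow(rec) == 0) abort("No records of the requested length.")
  chars <- strsplit(rec$aa_seq, "")
  long <- tibble::tibble(
    pos = rep(seq_len(length), times = nrow(rec)),
    residue = unlist(chars),
    n_pre = rep(rec$n_pre, each = length),
    n_post = rep(rec$n_post, each = length)
  ) |>
    dplyr::group_by(.data$pos, .data$residue) |>
    dplyr::summarise(c_pre = sum(.data$n_pre), c_post = sum(.data$n_post),
                     .groups = "drop") |>
    dplyr::filter(.data$c_pre + .data$c_post > 0)
  T_pre <- sum(rec$n_pre)
  T_post <- sum(rec$n_post)
  out <- long |>
    dplyr::mutate(
      f_pre = .data$c_pre / T_pre,
      f_post = .data$c_post / T_post,
      delta = .data$f_post - .data$f_pre,
      pooled = (.data$c_pre + .data$c_post) / (T_pre + T_post),
      se = sqrt(.data$pooled * (1 - .data$pooled) * (1 / T_pre + 1 / T_post)),
      z = ifelse(.data$se > 0, .data$delta / .data$se, 0),
      p_value = 2 * pnorm(-abs(.data$z))
    )
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out |>
    dplyr::mutate(
      position = paste0("H", 95 + .data$pos - 1),
      stars = dplyr::case_when(.data$p_value < 0.01 ~ "**",
                               .data$p_value < 0.05 ~ "*",
                               TRUE ~ "")
    ) |>
    dplyr::select("position", "residue", "f_pre", "f_post", "delta", "z",
                  "p_value", "stars")
}

#' Fold-enrichment histogram plot
#'
#' @param records An `es_tbl` from [es_table()].
#' @param bin_width Bin width on the log10 scale.
#' @return A ggplot object.
#' @export
plot_fold_histogram <- function(records, bin_width = 0.1) {
  h <- fold_histogram(records, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$n)) +
    ggplot2::geom_col(width = bin_width, fill = "grey35") +
    ggplot2::labs(x = "log10 fold enrichment", y = "Sequences")
}
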