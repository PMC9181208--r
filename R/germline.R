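# Germline assignment and per-germline enrichment: non-H3 CDRs were designed
# by simulated somatic hypermutation of human germline CDRs, so each observed
# CDR is traceable to its nearest germline ancestor.

#' Build or read a germline CDR reference
#'
#' `germline_refs()` assembles a reference tibble from vectors;
#' `read_germline_refs()` reads one from a TSV (columns `germline`, `region`,
#' `cdr_aa`) or a FASTA file whose record descriptions are
#' `"<germline> <region>"`. The germline family is parsed from the name up to
#' the first hyphen (`"VH3-23"` belongs to family `"VH3"`).
#'
#' @param germline Germline gene names (e.g. `"VH3-23"`), unique per region.
#' @param region CDR region labels.
#' @param cdr_aa Germline CDR amino-acid sequences.
#' @return A tibble with columns `germline`, `family`, `region`, `cdr_aa`.
#' @export
germline_refs <- function(germline, region, cdr_aa) {
  cdr_aa <- toupper(cdr_aa)
  if (!all(is_aa_string(cdr_aa))) abort("Germline CDRs must be amino-acid strings.")
  refs <- tibble::tibble(
    germline = germline,
    family = sub("-.*$", "", germline),
    region = region,
    cdr_aa = cdr_aa
  )
  dup <- duplicated(refs[, c("germline", "region")])
  if (any(dup)) abort("Germline names must be unique within a region.")
  refs
}

#' @rdname germline_refs
#' @param path Path to a TSV or FASTA reference file.
#' @export
read_germline_refs <- function(path) {
  if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    parts <- strsplit(trimws(names(set)), "\\s+")
    germline_refs(
      germline = vapply(parts, `[[`, "", 1),
      region = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, ""),
      cdr_aa = as.character(set)
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    germline_refs(df$germline, df$region, df$cdr_aa)
  }
}

#' Assign CDR sequences to their nearest germline ancestor
#'
#' Each query is matched to the reference CDR minimizing the global edit
#' (Levenshtein) distance with unit substitution/insertion/deletion costs.
#' Substitutions dominate between a hypermutated CDR and its ancestor, but
#' germline CDRs of one region can differ in length, hence a full edit
#' distance rather than a Hamming distance. Ties at the minimum are broken by
#' lexicographic germline name and flagged `ambiguous`.
#'
#' @param cdrs Character vector of query CDR amino-acid sequences.
#' @param refs A germline reference tibble (see [germline_refs()]).
#' @param region Optional region label used to subset `refs`.
#' @return A tibble with columns `aa_seq`, `germline`, `family`, `distance`,
#'   `ambiguous`, one row per query.
#' @export
assign_germline <- function(cdrs, refs, region = NULL) {
  if (!is.null(region)) refs <- refs[refs$region == region, , drop = FALSE]
  if (nrow(refs) == 0) abort("No germline references available for this region.")
  refs <- dplyr::arrange(refs, .data$germline)
  d <- adist(cdrs, refs$cdr_aa)   # generalized Levenshtein, unit costs
  best <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_along(cdrs), best)]
  ties <- rowSums(d == dmin) >= 2
  tibble::tibble(
    aa_seq = cdrs,
    germline = refs$germline[best],
    family = refs$family[best],
    distance = as.integer(dmin),
    ambiguous = ties
  )
}

#' Per-germline pre/post panning frequencies and fold changes
#'
#' Assigns every CDR in the count table to its nearest germline ancestor and
#' computes read-count-weighted relative frequencies of each germline in the
#' pre- and post-panning repertoires, together with the post/pre fold change.
#' Germlines whose fold change reaches 2 (or 0.5) are flagged enriched
#' (depleted). If a germline is absent from one repertoire, the fold change is
#' `Inf` (enriched) or `0` (depleted); germlines absent from both are omitted.
#'
#' @param table A `cdr_counts` table holding both repertoires.
#' @param refs A germline reference tibble (see [germline_refs()]).
#' @param region Optional region label used to subset `refs`.
#' @return A tibble with columns `germline`, `family`, `f_pre`, `f_post`,
#'   `fold_change`, `flag`; frequencies sum to 1 within each repertoire.
#' @export
germline_frequencies <- function(table, refs, region = NULL) {
  totals <- count_totals(table)
  if (any(totals == 0)) {
    abort("Both repertoires must contain reads to compare frequencies.")
  }
  assign <- assign_germline(table$aa_seq, refs, region = region)
  dplyr::bind_cols(tibble::as_tibble(table)[c("count_pre", "count_post")], assign) |>
    dplyr::group_by(.data$germline, .data$family) |>
    dplyr::summarise(count_pre = sum(.data$count_pre),
                     count_post = sum(.data$count_post), .groups = "drop") |>
    dplyr::filter(.data$count_pre + .data$count_post > 0) |>
    dplyr::mutate(
      f_pre = .data$count_pre / totals[["pre"]],
      f_post = .data$count_post / totals[["post"]],
      fold_change = dplyr::case_when(
        .data$f_pre == 0 ~ Inf,
        TRUE ~ .data$f_post / .data$f_pre
      ),
      flag = dplyr::case_when(
        .data$fold_change >= 2 ~ "enriched",
        .data$fold_change <= 0.5 ~ "depleted",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::select("germline", "family", "f_pre", "f_post", "fold_change", "flag") |>
    dplyr::arrange(.data$germline)
}

#' Pre- vs post-panning germline frequency scatter plot
#'
#' One point per germline; the dashed identity line marks no frequency change
#' after panning, points at twofold enrichment or depletion are labelled by
#' the `flag` colour.
#'
#' @param freqs Output of [germline_frequencies()].
#' @return A ggplot object.
#' @export
plot_germline_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$f_pre, y = .data$f_post,
                                      colour = .data$flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(enriched = "#d95f02",
                                            depleted = "#7570b3",
                                            neutral = "grey30")) +
    ggplot2::labs(x = "Pre-panning frequency", y = "Post-panning frequency",
                  colour = NULL)
}
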