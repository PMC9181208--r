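# Repertoire ingest: locate invariant framework anchors in merged amplicon
# reads, extract the CDR between them, and tabulate counts per unique CDR
# amino-acid sequence.

#' Define a CDR extraction scheme from invariant framework anchors
#'
#' A synthetic library built on a fixed framework has invariant amino-acid
#' sequence on both sides of each CDR. The scheme records the framework
#' suffix preceding the CDR (`left_anchor`), the framework prefix following it
#' (`right_anchor`), and the designed length range of the CDR.
#'
#' @param region_label CDR label, one of `"H1"`, `"H2"`, `"H3"`, `"kL1"`,
#'   `"kL2"`, `"kL3"`, `"lL1"`, `"lL2"`, `"lL3"`.
#' @param left_anchor,right_anchor Invariant framework amino-acid strings
#'   flanking the CDR, at least 4 residues each.
#' @param length_range Inclusive amino-acid length range of valid CDRs,
#'   within `[3, 30]`. CDR-H3 designs span 9 to 16 residues.
#' @return An object of class `framework_scheme`.
#' @examples
#' framework_scheme("H3", "TAVYYCAK", "WGQGTLVT", c(9, 16))
#' @export
framework_scheme <- function(region_label, left_anchor, right_anchor,
                             length_range = if (identical(region_label, "H3")) c(9L, 16L) else c(3L, 30L)) {
  regions <- c("H1", "H2", "H3", "kL1", "kL2", "kL3", "lL1", "lL2", "lL3")
  if (!region_label %in% regions) {
    abort(sprintf("`region_label` must be one of: %s", paste(regions, collapse = ", ")))
  }
  left_anchor <- toupper(left_anchor)
  right_anchor <- toupper(right_anchor)
  for (a in c(left_anchor, right_anchor)) {
    if (!is_aa_string(a) || nchar(a) < 4) {
      abort("Anchors must be amino-acid strings of at least 4 residues.")
    }
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || any(is.na(length_range)) ||
      length_range[1] > length_range[2] ||
      length_range[1] < 3 || length_range[2] > 30) {
    abort("`length_range` must be an inclusive pair within [3, 30].")
  }
  structure(
    list(region_label = region_label, left_anchor = left_anchor,
         right_anchor = right_anchor, length_range = length_range),
    class = "framework_scheme"
  )
}

#' @export
print.framework_scheme <- function(x, ...) {
  cat(sprintf("<framework_scheme> CDR-%s: %s | [%d-%d aa] | %s\n",
              x$region_label, x$left_anchor, x$length_range[1],
              x$length_range[2], x$right_anchor))
  invisible(x)
}

#' Read a framework scheme from a YAML file
#'
#' The file must provide `region_label`, `left_anchor`, `right_anchor` and,
#' optionally, `length_range` (two integers).
#'
#' @param path Path to a YAML file.
#' @return A [framework_scheme()].
#' @export
read_framework_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$length_range)) {
    framework_scheme(cfg$region_label, cfg$left_anchor, cfg$right_anchor)
  } else {
    framework_scheme(cfg$region_label, cfg$left_anchor, cfg$right_anchor,
                     unlist(cfg$length_range))
  }
}

new_cdr_counts <- function(df, rejections = NULL, total_reads = NULL) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("region", "aa_seq", "length", "count_pre", "count_post") %in% names(df)))
  if (!"designed" %in% names(df)) df$designed <- NA
  df <- df[, c("region", "aa_seq", "length", "count_pre", "count_post", "designed")]
  structure(df,
            class = c("cdr_counts", class(tibble::tibble()))) -> out
  attr(out, "rejections") <- rejections %||%
    tibble::tibble(reason = character(), reads = integer())
  attr(out, "total_reads") <- total_reads %||% sum(df$count_pre + df$count_post)
  out
}

#' Total read counts of a CDR count table
#'
#' @param table A `cdr_counts` table.
#' @return Named numeric vector with elements `pre` and `post`.
#' @export
count_totals <- function(table) {
  c(pre = sum(table$count_pre), post = sum(table$count_post))
}

#' Per-reason read rejection summary from CDR extraction
#'
#' @param table A `cdr_counts` table produced by [extract_cdrs()].
#' @return A tibble with columns `reason` and `reads`.
#' @export
rejection_summary <- function(table) {
  attr(table, "rejections") %||%
    tibble::tibble(reason = character(), reads = integer())
}

# Translate a vector of nucleotide strings in a fixed frame (1, 2 or 3).
translate_frame <- function(nt, frame) {
  usable <- pmax(0L, floor((nchar(nt) - frame + 1L) / 3L) * 3L)
  out <- character(length(nt))
  ok <- usable >= 3L
  if (any(ok)) {
    sub <- substr(nt[ok], frame, frame + usable[ok] - 1L)
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(sub), no.init.codon = TRUE,
      if.fuzzy.codon = "X"))
  }
  out
}

#' Extract CDR sequences from merged amplicon reads
#'
#' Locates the scheme's invariant framework anchors in each read (exact
#' matching; the frameworks are invariant by library design), takes the
#' sequence between them as the CDR, and aggregates read counts per unique
#' CDR amino-acid sequence. Nucleotide reads are translated in the single
#' reading frame fixed by the left-anchor match; amino-acid input is accepted
#' directly. Reads failing any check are tallied by reason in the rejection
#' summary (see [rejection_summary()]): `ambiguous_base` (N in a nucleotide
#' read), `anchor_missing`, `anchor_ambiguous` (an anchor matches more than
#' once), `stop_codon`, `invalid_residue`, and `length_out_of_range`.
#'
#' @param reads Character vector of merged reads, an `XStringSet`, or a path
#'   to a FASTA/FASTQ file (qualities are ignored).
#' @param scheme A [framework_scheme()].
#' @param repertoire `"pre"` or `"post"`: which repertoire the reads belong to.
#' @param type `"auto"` (default) treats input composed solely of A/C/G/T/U/N
#'   as nucleotide, `"nt"` and `"aa"` force the interpretation.
#' @return A `cdr_counts` tibble with columns `region`, `aa_seq`, `length`,
#'   `count_pre`, `count_post`, `designed` (NA until [apply_whitelist()] is
#'   applied), carrying the rejection summary and total input read count as
#'   attributes.
#' @seealso [apply_whitelist()], [bind_count_tables()], [es_table()]
#' @export
extract_cdrs <- function(reads, scheme, repertoire = c("pre", "post"),
                         type = c("auto", "nt", "aa")) {
  repertoire <- match.arg(repertoire)
  type <- match.arg(type)
  stopifnot(inherits(scheme, "framework_scheme"))
  seqs <- as_sequence_vector(reads)
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  cdr <- rep(NA_character_, n)

  nt_like <- is_nt_string(seqs)
  as_nt <- switch(type,
    auto = all(nt_like) && n > 0,
    nt = TRUE,
    aa = FALSE
  )

  if (as_nt) {
    if (!all(nt_like)) {
      reason[!nt_like] <- "invalid_residue"
    }
    has_n <- grepl("N", seqs, fixed = TRUE) & nt_like
    reason[has_n] <- "ambiguous_base"
    todo <- is.na(reason)
    nts <- chartr("U", "T", seqs)
    prot <- matrix("", n, 3)
    for (f in 1:3) prot[todo, f] <- translate_frame(nts[todo], f)
    hits <- matrix(0L, n, 3)
    for (f in 1:3) hits[todo, f] <- stringr::str_count(prot[todo, f],
                                                       stringr::fixed(scheme$left_anchor))
    total_hits <- rowSums(hits)
    reason[todo & total_hits == 0] <- "anchor_missing"
    reason[todo & total_hits > 1] <- "anchor_ambiguous"
    todo <- is.na(reason)
    frame <- max.col(hits, ties.method = "first")
    protein <- rep(NA_character_, n)
    protein[todo] <- prot[cbind(which(todo), frame[todo])]
  } else {
    bad <- !is_aa_string(seqs, alphabet = c(aa_standard(), "*", "X"))
    reason[bad] <- "invalid_residue"
    protein <- seqs
  }

  todo <- is.na(reason)
  left_n <- right_n <- integer(n)
  left_n[todo] <- stringr::str_count(protein[todo], stringr::fixed(scheme$left_anchor))
  right_n[todo] <- stringr::str_count(protein[todo], stringr::fixed(scheme$right_anchor))
  reason[todo & (left_n == 0 | right_n == 0)] <- "anchor_missing"
  todo <- is.na(reason)
  reason[todo & (left_n > 1 | right_n > 1)] <- "anchor_ambiguous"
  todo <- is.na(reason)

  if (any(todo)) {
    lpos <- stringr::str_locate(protein[todo], stringr::fixed(scheme$left_anchor))
    rpos <- stringr::str_locate(protein[todo], stringr::fixed(scheme$right_anchor))
    start <- lpos[, "end"] + 1L
    end <- rpos[, "start"] - 1L
    ord_ok <- end >= start - 1L & rpos[, "start"] > lpos[, "end"]
    idx <- which(todo)
    reason[idx[!ord_ok]] <- "anchor_missing"
    keep <- idx[ord_ok]
    cdr[keep] <- substr(protein[keep], start[ord_ok], end[ord_ok])
  }

  todo <- is.na(reason)
  reason[todo & grepl("*", cdr, fixed = TRUE)] <- "stop_codon"
  todo <- is.na(reason)
  len <- ifelse(is.na(cdr), NA_integer_, nchar(cdr))
  out_of_range <- todo & (len < scheme$length_range[1] | len > scheme$length_range[2])
  reason[out_of_range] <- "length_out_of_range"
  todo <- is.na(reason)
  reason[todo & !is_aa_string(cdr, alphabet = aa_standard())] <- "invalid_residue"
  todo <- is.na(reason)

  counts <- table(cdr[todo])
  nm <- names(counts) %||% character(0)
  df <- tibble::tibble(
    region = rep(scheme$region_label, length(nm)),
    aa_seq = nm,
    length = nchar(nm),
    count = as.integer(counts)
  )
  df$count_pre <- if (repertoire == "pre") df$count else 0L
  df$count_post <- if (repertoire == "post") df$count else 0L
  df$count <- NULL
  df <- dplyr::arrange(df, .data$aa_seq)

  rej <- tibble::tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "reads") |>
    dplyr::arrange(.data$reason)
  new_cdr_counts(df, rejections = rej, total_reads = n)
}

#' Combine CDR count tables across repertoires
#'
#' Sums counts of identical CDR sequences across tables, typically one table
#' per repertoire as returned by [extract_cdrs()].
#'
#' @param ... `cdr_counts` tables for the same region.
#' @return A merged `cdr_counts` table; rejection summaries are concatenated.
#' @export
bind_count_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  regions <- unique(unlist(lapply(tabs, function(t) unique(t$region))))
  if (length(regions) > 1) abort("All tables must cover the same CDR region.")
  merged <- dplyr::bind_rows(lapply(tabs, tibble::as_tibble)) |>
    dplyr::group_by(.data$region, .data$aa_seq, .data$length) |>
    dplyr::summarise(count_pre = sum(.data$count_pre),
                     count_post = sum(.data$count_post),
                     .groups = "drop") |>
    dplyr::arrange(.data$aa_seq)
  rej <- dplyr::bind_rows(lapply(tabs, rejection_summary)) |>
    dplyr::group_by(.data$reason) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  new_cdr_counts(merged, rejections = rej,
                 total_reads = sum(vapply(tabs, function(t) attr(t, "total_reads") %||% 0, 0)))
}

#' Restrict a count table to the designed sequence whitelist
#'
#' Synthetic libraries contain a substantial fraction of reads whose CDR does
#' not match any designed sequence (parallel-synthesis errors); these are
#' excluded from enrichment analysis. Marks each CDR as designed or not and
#' keeps only the designed ones, recomputing repertoire totals.
#'
#' @param table A `cdr_counts` table.
#' @param whitelist Character vector of designed amino-acid sequences, or a
#'   path to a one-sequence-per-line text file / TSV whose first column holds
#'   the sequences.
#' @return The filtered `cdr_counts` table with `designed = TRUE` rows only.
#'   The attribute `retained_fraction` holds the fraction of reads kept.
#' @export
apply_whitelist <- function(table, whitelist) {
  stopifnot(inherits(table, "cdr_counts"))
  if (is.character(whitelist) && length(whitelist) == 1 && file.exists(whitelist)) {
    lines <- readLines(whitelist)
    whitelist <- toupper(trimws(vapply(strsplit(lines, "\t"), `[[`, "", 1)))
    whitelist <- whitelist[nzchar(whitelist)]
    if (length(whitelist) && whitelist[1] %in% c("AA_SEQ", "SEQUENCE", "SEQ")) {
      whitelist <- whitelist[-1]
    }
  }
  if (!length(whitelist)) abort("`whitelist` must be non-empty.")
  designed <- table$aa_seq %in% whitelist
  if (!any(designed)) {
    abort("no_designed_sequences: no CDR in the table matches the whitelist.")
  }
  total_reads_in <- sum(table$count_pre + table$count_post)
  out <- tibble::as_tibble(table)[designed, , drop = FALSE]
  out$designed <- TRUE
  res <- new_cdr_counts(out, rejections = rejection_summary(table),
                        total_reads = attr(table, "total_reads"))
  attr(res, "retained_fraction") <-
    sum(out$count_pre + out$count_post) / total_reads_in
  res
}

#' Write / read a CDR count table as TSV
#'
#' Columns: `region`, `aa_seq`, `length`, `count_pre`, `count_post`,
#' `designed`. The round trip reproduces the table exactly.
#'
#' @param table A `cdr_counts` table.
#' @param path Output (input) TSV path.
#' @return `write_count_table()` returns `table` invisibly;
#'   `read_count_table()` returns a `cdr_counts` tibble.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(table)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    aa_seq = readr::col_character(),
    length = readr::col_integer(),
    count_pre = readr::col_integer(),
    count_post = readr::col_integer(),
    designed = readr::col_logical()
  ))
  new_cdr_counts(df)
}
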