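# Shared builders for tests: a compact H3 extraction scheme and hand-rolled
# count tables.

h3_test_scheme <- function() {
  framework_scheme("H3", "TAVYYCAK", "WGQGTLVT", c(9L, 16L))
}

# Random designed-alphabet CDR sequences (unique), under a local seed.
random_cdrs <- function(n, length, seed = 1) {
  with_seed_test(seed, {
    out <- character(0)
    while (base::length(out) < n) {
      cand <- vapply(seq_len(2 * n), function(i) {
        paste(sample(aa_designed(), length, replace = TRUE), collapse = "")
      }, "")
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Build a cdr_counts table directly from vectors.
make_counts <- function(aa_seq, count_pre, count_post, region = "H3",
                        designed = TRUE) {
  tbl <- tibble::tibble(
    region = region, aa_seq = aa_seq, length = nchar(aa_seq),
    count_pre = as.integer(count_pre), count_post = as.integer(count_post),
    designed = designed
  )
  tmp <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, tmp)
  on.exit(unlink(tmp))
  read_count_table(tmp)
}
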