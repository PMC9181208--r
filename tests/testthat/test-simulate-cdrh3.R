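# Naive sliding-window motif matcher, the oracle for the compiled-regex
# implementation.
naive_motif_match <- function(seq, tokens) {
  chars <- strsplit(seq, "")[[1]]
  k <- length(tokens)
  if (length(chars) < k) return(FALSE)
  for (start in seq_len(length(chars) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!chars[start + j - 1] %in% tokens[[j]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

test_that("motif patterns match fixed, wildcard, and class tokens", {
  ng <- motif_rule("deamidation_NG", "NG")
  expect_true(match_motif("ARNGSY", ng))
  expect_false(match_motif("ARNSGY", ng))

  sequon <- motif_rule("n_glyc", "N[^P][ST]")
  expect_true(match_motif("ARNGSYW", sequon))   # N-G-S
  expect_false(match_motif("ARNPSY", sequon))   # proline blocks the sequon
  expect_true(match_motif("YNATR", sequon))     # N-A-T
  expect_false(match_motif("YNAAR", sequon))

  anyx <- motif_rule("pair", "DXG")
  expect_true(match_motif("ADWGY", anyx))
  expect_false(match_motif("ADGWY", anyx))
  expect_error(motif_rule("short", "N"), "at least 2")
})

test_that("regex matching agrees with a naive sliding-window oracle", {
  rules <- c(default_motif_rules(),
             list(motif_rule("probe", "G[AST]X[^GY]")))
  seqs <- random_cdrs(1000, 10, seed = 81)
  for (rule in rules) {
    got <- match_motif(seqs, rule)
    want <- vapply(seqs, naive_motif_match, TRUE, tokens = rule$tokens)
    expect_equal(got, unname(want))
  }
})

test_that("simulated CDR-H3 sets are unique, motif-free, Cys/Met-free, and seeded", {
  model <- default_cdrh3_frequencies(11)
  out <- simulate_cdrh3(model, 500, seed = 10)
  expect_length(out, 500)
  expect_false(anyDuplicated(out) > 0)
  expect_true(all(nchar(out) == 11))
  expect_false(any(grepl("[CM]", out)))
  for (rule in default_motif_rules()) {
    expect_false(any(match_motif(out, rule)))
  }

  again <- simulate_cdrh3(model, 500, seed = 10)
  expect_identical(as.character(out), as.character(again))
  other <- simulate_cdrh3(model, 500, seed = 11)
  expect_false(identical(as.character(out), as.character(other)))

  # under a concentrated model the sequence space is small, so draws from
  # different seeds overlap without being identical
  conc <- position_frequency_model(tibble::tibble(
    position = rep(1:9, each = 18),
    residue = rep(aa_designed(), 9),
    probability = rep(ifelse(aa_designed() %in% c("G", "Y"), 0.5, 0), 9)
  ))
  a <- simulate_cdrh3(conc, 100, rules = list(), seed = 1)
  b <- simulate_cdrh3(conc, 100, rules = list(), seed = 2)
  expect_false(identical(as.character(a), as.character(b)))
  expect_gt(length(intersect(a, b)), 0)
})

test_that("a degenerate one-residue model yields its single sequence and cannot give two", {
  freq <- tibble::tibble(
    position = rep(1:9, each = 18),
    residue = rep(aa_designed(), times = 9),
    probability = rep(as.numeric(aa_designed() == "G"), 9)
  )
  model <- position_frequency_model(freq)
  expect_equal(simulate_cdrh3(model, 1, rules = list(), seed = 1)[1],
               strrep("G", 9))
  expect_error(simulate_cdrh3(model, 2, rules = list(), seed = 1),
               "achieved 1")
})

test_that("accepted-sequence positional frequencies track the model", {
  model <- default_cdrh3_frequencies(9)

  # without motif rejection the sampler reproduces the table to sampling error
  pure <- simulate_cdrh3(model, 50000, rules = list(), seed = 13)
  chars <- matrix(unlist(strsplit(pure, "")), ncol = 9, byrow = TRUE)
  for (p in c(1, 5, 9)) {
    emp <- table(factor(chars[, p], levels = aa_designed())) / length(pure)
    expect_lt(max(abs(as.numeric(emp) - model$prob[p, ])), 0.01)
  }

  # motif rejection depletes the residues that seed liability motifs (N, D
  # and their partners); other residues stay close to the model
  out <- simulate_cdrh3(model, 50000, seed = 14)
  chars <- matrix(unlist(strsplit(out, "")), ncol = 9, byrow = TRUE)
  motif_res <- c("N", "D", "G", "S", "T", "P")
  for (p in c(1, 5, 9)) {
    emp <- table(factor(chars[, p], levels = aa_designed())) / length(out)
    dev <- abs(as.numeric(emp) - model$prob[p, ])
    expect_lt(max(dev[!aa_designed() %in% motif_res]), 0.025)
    expect_lt(max(dev), 0.06)
  }
})

test_that("frequency models validate probabilities and forbid Cys/Met", {
  bad <- tibble::tibble(position = rep(1:3, each = 2),
                        residue = rep(c("G", "C"), 3),
                        probability = rep(c(0.8, 0.2), 3))
  expect_error(position_frequency_model(bad), "Cys and Met")
  short <- tibble::tibble(position = 1:3, residue = "G",
                          probability = c(1, 0.9, 1))
  expect_error(position_frequency_model(short), "sum to 1")

  # TSV round trip
  model <- default_cdrh3_frequencies(9)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    position = rep(1:9, each = 18),
    residue = rep(colnames(model$prob), 9),
    probability = as.vector(t(model$prob))
  ), path)
  back <- read_frequency_model(path)
  expect_equal(back$prob, model$prob)
})
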