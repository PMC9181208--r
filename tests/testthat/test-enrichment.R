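# Spreadsheet-style reference evaluation of the ES formula, kept independent
# of compute_es(): frequencies first, then the log2 ratio and the count
# weight, with the same 0 -> 0.5 replacement.
es_reference <- function(n_pre, n_post, N_pre, N_post, med_pre, med_post) {
  if (n_pre == 0) n_pre <- 0.5
  if (n_post == 0) n_post <- 0.5
  f_pre <- n_pre / N_pre
  f_post <- n_post / N_post
  (log(f_post / f_pre) / log(2)) * ((n_post + n_pre) / (med_post + med_pre))
}

test_that("the enrichment score matches hand-evaluated cases exactly", {
  ctx <- es_context(1e6, 1e6, 10, 20)
  expect_equal(compute_es(10, 40, ctx), 10 / 3, tolerance = 1e-12)
  # equal frequencies null the log term whatever the medians
  expect_equal(compute_es(5, 5, es_context(1000, 1000, 3, 7)), 0)
  # swapping pre and post (counts, totals, medians) flips the sign
  ctx_sw <- es_context(1e6, 1e6, 20, 10)
  expect_equal(compute_es(40, 10, ctx_sw), -10 / 3, tolerance = 1e-12)
  # zero counts are pseudocounted and flagged upstream
  expect_equal(compute_es(0, 8, es_context(100, 100, 4, 4)),
               log2(8 / 0.5) * 8.5 / 8, tolerance = 1e-12)
  expect_error(compute_es(0, 0, ctx), "unobserved_sequence")
})

test_that("ES agrees with a spreadsheet-style oracle and is antisymmetric on random tuples", {
  with_seed_test(99, {
    for (i in 1:1000) {
      n <- sample(0:500, 2)
      if (all(n == 0)) n[1] <- 1
      N <- sample(1e4:1e6, 2)
      med <- sample(1:50, 2)
      ctx <- es_context(N[1], N[2], med[1], med[2])
      es <- compute_es(n[1], n[2], ctx)
      expect_equal(es, es_reference(n[1], n[2], N[1], N[2], med[1], med[2]),
                   tolerance = 1e-12)
      ctx_sw <- es_context(N[2], N[1], med[2], med[1])
      expect_equal(compute_es(n[2], n[1], ctx_sw), -es, tolerance = 1e-12)
    }
  })
})

test_that("es_table computes medians over the designed set and is scale-invariant", {
  tab <- make_counts(c("ARDYGGNSY", "ARDYGGNSW", "ARDYGGNSF"),
                     count_pre = c(10, 10, 10), count_post = c(10, 20, 5))
  et <- es_table(tab, totals = c(1000, 1000))  # equal library totals
  ctx <- attr(et, "context")
  expect_equal(ctx$med_pre, 10)
  expect_equal(ctx$med_post, 10)
  expect_equal(sign(et$es), c(0, 1, -1))
  expect_false(any(et$pseudocounted))

  # doubling all counts (totals and medians follow) leaves every ES unchanged
  tab2 <- make_counts(tab$aa_seq, tab$count_pre * 2, tab$count_post * 2)
  expect_equal(es_table(tab2, totals = c(2000, 2000))$es, et$es)

  # a single-sequence table has confidence weight exactly 1
  single <- es_table(make_counts("ARDYGGNSY", 30, 90))
  expect_equal(single$es, log2((90 / 90) / (30 / 30)) * 1)
  expect_equal(single$es, 0)
})

test_that("the fold histogram bins in 0.1 log10 steps and reports 20-fold tails", {
  # equal totals (1210 reads each) so the planted ratios are exact: 20, 1, 1/20
  tab <- make_counts(random_cdrs(3, 9, seed = 2),
                     count_pre = c(10, 1000, 200),
                     count_post = c(200, 1000, 10))
  et <- es_table(tab)
  h <- fold_histogram(et)
  expect_equal(sum(h$n), nrow(et))
  tails <- attr(h, "tail_counts")
  # ratio 20 -> log10 = 1.301 sits in the > 1.3 tail; ratio 1/20 below -1.3
  expect_equal(unname(tails["above"]), 1)
  expect_equal(unname(tails["below"]), 1)
  # ratio 1 falls in the bin containing zero
  bin_of_one <- h[h$bin_low <= 0 & h$bin_high > 0, ]
  expect_gte(bin_of_one$n, 1)
})

test_that("histogram counts equal a brute-force binning on planted ratios", {
  with_seed_test(4, {
    n <- 100
    cdrs <- random_cdrs(n, 10, seed = 12)
    pre <- sample(50:500, n, replace = TRUE)
    post <- sample(50:500, n, replace = TRUE)
    et <- es_table(make_counts(cdrs, pre, post))
    h <- fold_histogram(et)
    brute <- table(floor(round(et$log10_fold, 9) / 0.1))
    expect_equal(sum(h$n), n)
    for (b in names(brute)) {
      expect_equal(h$n[abs(h$bin_low - as.numeric(b) * 0.1) < 1e-9],
                   as.integer(brute[[b]]))
    }
  })
})

test_that("twofold splitting uses strict inequalities on the frequency ratio", {
  tab <- make_counts(random_cdrs(4, 9, seed = 3),
                     count_pre = c(100, 100, 100, 100),
                     count_post = c(250, 40, 100, 10))
  et <- es_table(tab)
  sets <- split_by_fold(et)
  ratio <- 10^et$log10_fold
  expect_setequal(sets$enriched$aa_seq, et$aa_seq[ratio > 2])
  expect_setequal(sets$depleted$aa_seq, et$aa_seq[ratio < 0.5])
  # ratio exactly 1 belongs to neither set
  expect_false(et$aa_seq[3] %in% c(sets$enriched$aa_seq, sets$depleted$aa_seq))
})

test_that("positional shifts recover planted frequency changes with z-test p-values", {
  # identical repertoires: all deltas zero, no significance
  cdrs <- random_cdrs(50, 9, seed = 21)
  cnt <- with_seed_test(22, sample(50:150, 50, replace = TRUE))
  same <- es_table(make_counts(cdrs, cnt, cnt))
  ps <- positional_shifts(same, 9)
  expect_true(all(abs(ps$delta) < 1e-12))
  expect_true(all(ps$p_value > 0.99))
  expect_equal(ps$position[1], "H95")
  # deltas cancel within a position for any input
  sums <- tapply(ps$delta, ps$position, sum)
  expect_true(all(abs(sums) < 1e-12))

  # planted shift: G at position 1 goes 10% -> 30% of 10,000 reads
  seqs <- c(paste0("G", substr(random_cdrs(1, 8, seed = 23), 1, 8)),
            paste0("A", substr(random_cdrs(1, 8, seed = 24), 1, 8)))
  tab <- make_counts(seqs, count_pre = c(1000, 9000), count_post = c(3000, 7000))
  ps <- positional_shifts(es_table(tab), 9)
  g1 <- ps[ps$position == "H95" & ps$residue == "G", ]
  expect_equal(g1$delta, 0.2)
  expect_lt(g1$p_value, 0.01)
  expect_equal(g1$stars, "**")
  # oracle: prop.test without continuity correction gives X-squared = z^2
  pt <- prop.test(c(1000, 3000), c(10000, 10000), correct = FALSE)
  expect_equal(g1$p_value, pt$p.value, tolerance = 1e-12)
  expect_equal(g1$z^2, unname(pt$statistic), tolerance = 1e-12)
})
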