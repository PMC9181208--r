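# Normal-equations ridge solve, the independent oracle for the QR-based fit.
ridge_normal_equations <- function(X, y, l2) {
  Xi <- cbind(1, X)
  P <- diag(c(0, rep(l2, ncol(X))))
  solve(crossprod(Xi) + P, crossprod(Xi, y))
}

test_that("one-hot featurization activates one indicator per position", {
  m <- featurize("AAA")
  expect_equal(sum(m), 3)
  expect_setequal(colnames(m)[m[1, ] == 1], c("1:A", "2:A", "3:A"))

  m2 <- featurize(c("ARDYGGNSY", "ARDYGGNSW"))
  expect_true(all(rowSums(m2) == 9))
  shared <- sum(m2[1, ] == 1 & m2[2, ] == 1)
  expect_equal(shared, 8)  # differ at exactly one position

  big <- featurize(random_cdrs(300, 9, seed = 9))
  expect_lte(ncol(big), 9 * 18)
})

test_that("the ridge fit equals a normal-equations solve on small instances", {
  with_seed_test(31, {
    seqs <- random_cdrs(200, 9, seed = 32)
    y <- rnorm(200)
    X <- featurize(seqs)
    keep <- apply(X, 2, function(col) length(unique(col)) > 1)
    X <- X[, keep, drop = FALSE]
    for (l2 in c(1e-6, 1e-2, 1)) {
      fit <- pandesign:::ridge_fit(X, y, l2)
      ref <- ridge_normal_equations(X, y, l2)
      expect_lt(abs(fit$intercept - ref[1, 1]), 1e-8)
      expect_lt(max(abs(fit$weights - ref[-1, 1])), 1e-8)
    }
  })
})

test_that("a constant target yields the constant intercept and null weights", {
  rec <- tibble::tibble(aa_seq = random_cdrs(120, 9, seed = 33), es = 4.2)
  m <- fit_es_model(rec, seed = 1)
  expect_equal(m$intercept, 4.2, tolerance = 1e-6)
  expect_true(all(abs(m$weights) < 1e-6))
})

test_that("planted positional effects are recovered from a linear ES response", {
  with_seed_test(41, {
    L <- 9
    seqs <- random_cdrs(5000, L, seed = 42)
    effects <- tibble::tibble(
      position = rep(seq_len(L), each = length(aa_designed())),
      residue = rep(aa_designed(), times = L),
      effect = rnorm(L * length(aa_designed()), 0, 0.2)
    )
    eff_mat <- matrix(effects$effect, nrow = length(aa_designed()))
    chars <- matrix(unlist(strsplit(seqs, "")), ncol = L, byrow = TRUE)
    y <- vapply(seq_len(5000), function(i) {
      sum(eff_mat[cbind(match(chars[i, ], aa_designed()), seq_len(L))])
    }, 0) + rnorm(5000, 0, 0.1)
    m <- fit_es_model(tibble::tibble(aa_seq = seqs, es = y), seed = 7)

    est <- tidy(m) |>
      dplyr::group_by(position) |>
      dplyr::mutate(centered = estimate - mean(estimate)) |>
      dplyr::ungroup()
    truth <- effects |>
      dplyr::group_by(position) |>
      dplyr::mutate(centered_true = effect - mean(effect)) |>
      dplyr::ungroup()
    j <- dplyr::inner_join(est, truth, by = c("position", "residue"))
    expect_equal(nrow(j), L * length(aa_designed()))
    expect_lt(max(abs(j$centered - j$centered_true)), 0.05)
    expect_gt(m$metrics$spearman, 0.9)
  })
})

test_that("the train/eval split is seeded and reproducible", {
  rec <- tibble::tibble(aa_seq = random_cdrs(200, 10, seed = 51),
                        es = with_seed_test(52, rnorm(200)))
  m1 <- fit_es_model(rec, seed = 5)
  m2 <- fit_es_model(rec, seed = 5)
  m3 <- fit_es_model(rec, seed = 6)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$eval$aa_seq, m2$eval$aa_seq)
  expect_false(identical(m1$eval$aa_seq, m3$eval$aa_seq))
  expect_equal(m1$metrics$n_train, 140)
  expect_equal(m1$metrics$n_eval, 60)
})

test_that("decile calibration matches a brute-force rank-and-average oracle", {
  # a perfect predictor walks the decile midpoints
  actual <- with_seed_test(61, rnorm(1000))
  dd <- decile_calibration(actual, actual)
  expect_equal(dd$decile, 1:10)
  expect_equal(dd$mean_pred_percentile, seq(5, 95, by = 10), tolerance = 1e-9)

  # uninformative predictions average near the 50th percentile in every decile
  dd_rand <- decile_calibration(actual, with_seed_test(62, rnorm(1000)))
  expect_true(all(abs(dd_rand$mean_pred_percentile - 50) < 15))

  # brute-force oracle on independent random pairs
  pred <- with_seed_test(63, rnorm(1000))
  dd2 <- decile_calibration(actual, pred)
  ord <- order(actual)
  sizes <- rep(100, 10)
  pct <- 100 * (rank(pred) - 0.5) / 1000
  start <- 1
  for (d in 1:10) {
    members <- ord[start:(start + sizes[d] - 1)]
    expect_equal(dd2$mean_pred_percentile[d], mean(pct[members]),
                 tolerance = 1e-9)
    expect_equal(dd2$sd_pred_percentile[d], sd(pct[members]), tolerance = 1e-9)
    start <- start + sizes[d]
  }

  expect_error(decile_calibration(rnorm(5), rnorm(5)), "At least 10")
})

test_that("screening keeps exactly the candidates with predicted ES above zero", {
  # hand-built model: score = weight of the first-position residue
  m <- structure(
    list(length = 9L, features = c("1:A", "1:D", "1:G"),
         weights = c("1:A" = 1, "1:D" = -1, "1:G" = 0),
         intercept = 0, l2 = 1e-6, train_fraction = 0.7, seed = 1,
         metrics = NULL, eval = NULL),
    class = "es_model"
  )
  tail8 <- "RDYGGNSY"
  cand <- paste0(c("A", "D", "G"), tail8)
  out <- screen_candidates(m, cand)
  expect_equal(out$pred_es, c(1, -1, 0))
  expect_equal(out$kept, c(TRUE, FALSE, FALSE))  # exactly zero is dropped
  kf <- attr(out, "kept_fraction")
  expect_equal(kf$kept_fraction, 1 / 3)
  expect_error(screen_candidates(m, "ARDYGGNSYY"), "No trained model")
})

test_that("models serialize to JSON and back without changing predictions", {
  rec <- tibble::tibble(aa_seq = random_cdrs(100, 9, seed = 71),
                        es = with_seed_test(72, rnorm(100)))
  m <- fit_es_model(rec, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_es_model(m, path)
  back <- read_es_model(path)
  probe <- random_cdrs(20, 9, seed = 73)
  expect_equal(predict(back, probe), predict(m, probe), tolerance = 1e-12)
  expect_equal(back$l2, m$l2)
})
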