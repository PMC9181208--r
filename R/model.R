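# Per-length linear models predicting the enrichment score from one-hot
# positional residue features, with a decile-rank calibration diagnostic and
# a predicted-ES screen for simulated candidate sequences.

#' One-hot positional residue features
#'
#' Encodes fixed-length amino-acid sequences as indicator features, one per
#' (position, residue) pair, named `"<position>:<residue>"`. Every sequence
#' activates exactly L features, one per position.
#'
#' @param aa_seq Character vector of equal-length sequences.
#' @param features Optional character vector of feature names to project
#'   onto (columns for unseen combinations are all zero); by default the
#'   features observed in `aa_seq`.
#' @return A 0/1 integer matrix with one row per sequence.
#' @export
featurize <- function(aa_seq, features = NULL) {
  if (length(aa_seq) == 0) abort("`aa_seq` must be non-empty.")
  L <- unique(nchar(aa_seq))
  if (length(L) != 1) abort("All sequences must have the same length.")
  chars <- matrix(unlist(strsplit(aa_seq, "")), ncol = L, byrow = TRUE)
  labels <- sprintf("%d:%s", rep(seq_len(L), each = nrow(chars)), as.vector(chars))
  if (is.null(features)) {
    features <- sort(unique(labels))
  }
  m <- matrix(0L, nrow = length(aa_seq), ncol = length(features),
              dimnames = list(NULL, features))
  idx <- match(labels, features)
  rows <- rep(seq_len(nrow(chars)), times = L)
  keep <- !is.na(idx)
  m[cbind(rows[keep], idx[keep])] <- 1L
  m
}

# Ridge fit with unpenalized intercept, via least squares on the design
# augmented with sqrt(l2) * I rows (QR solve; tolerates the one-hot
# collinearity with the intercept).
ridge_fit <- function(X, y, l2) {
  p <- ncol(X)
  Xa <- rbind(cbind(1, X), cbind(0, diag(sqrt(l2), p)))
  ya <- c(y, rep(0, p))
  beta <- qr.coef(qr(Xa), ya)
  beta[is.na(beta)] <- 0
  list(intercept = unname(beta[1]), weights = setNames(beta[-1], colnames(X)))
}

#' Fit a per-length ridge model of enrichment score on sequence
#'
#' Fits an L2-regularized linear regression of ES on one-hot positional
#' residue features for sequences of a single CDR-H3 length. The data are
#' split at random into a training fraction (default 70%) and a held-out
#' evaluation set (30%) used to report R-squared and Spearman correlation.
#' The regularization is mild (default 1e-6) — it serves to stabilize the
#' collinear one-hot design rather than to shrink the fit. Feature columns
#' constant across the training rows are dropped.
#'
#' @param records A tibble with columns `aa_seq` and `es` (e.g. an `es_tbl`
#'   restricted to one length); at least 50 rows.
#' @param l2 L2 penalty strength.
#' @param train_fraction Fraction of records used for training.
#' @param seed Integer seed for the uniform random split.
#' @return An object of class `es_model`: weights, intercept, the held-out
#'   metrics, and the evaluation records with their predictions.
#' @seealso [predict.es_model()], [decile_diagnostic()], [screen_candidates()]
#' @export
fit_es_model <- function(records, l2 = 1e-6, train_fraction = 0.7, seed = 1) {
  stopifnot(is.data.frame(records), all(c("aa_seq", "es") %in% names(records)))
  if (nrow(records) < 50) abort("At least 50 records are required to fit a model.")
  L <- unique(nchar(records$aa_seq))
  if (length(L) != 1) abort("All sequences must share one length; fit one model per length.")
  if (!(train_fraction > 0 && train_fraction < 1)) abort("`train_fraction` must be in (0, 1).")
  if (l2 < 0) abort("`l2` must be non-negative.")

  n <- nrow(records)
  train_idx <- with_seed(seed, sort(sample.int(n, size = round(train_fraction * n))))
  eval_idx <- setdiff(seq_len(n), train_idx)

  X <- featurize(records$aa_seq)
  Xtr <- X[train_idx, , drop = FALSE]
  keep <- apply(Xtr, 2, function(col) length(unique(col)) > 1)
  Xtr <- Xtr[, keep, drop = FALSE]
  fit <- ridge_fit(Xtr, records$es[train_idx], l2)

  model <- structure(
    list(length = L, features = colnames(Xtr), weights = fit$weights,
         intercept = fit$intercept, l2 = l2, train_fraction = train_fraction,
         seed = seed),
    class = "es_model"
  )
  eval_rec <- tibble::tibble(
    aa_seq = records$aa_seq[eval_idx],
    es = records$es[eval_idx]
  )
  eval_rec$pred <- predict(model, eval_rec$aa_seq)
  ss_res <- sum((eval_rec$es - eval_rec$pred)^2)
  ss_tot <- sum((eval_rec$es - mean(eval_rec$es))^2)
  degenerate <- ss_tot == 0 || sd(eval_rec$pred) == 0
  model$metrics <- list(
    n_train = length(train_idx),
    n_eval = length(eval_idx),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    spearman = if (degenerate) NA_real_ else
      cor(eval_rec$es, eval_rec$pred, method = "spearman")
  )
  model$eval <- eval_rec
  model
}

#' @export
print.es_model <- function(x, ...) {
  cat(sprintf("<es_model> CDR-H3 length %d: %d features, l2 = %g\n",
              x$length, length(x$features), x$l2))
  cat(sprintf("  held-out (n = %d): R2 = %.3f, Spearman = %.3f\n",
              x$metrics$n_eval, x$metrics$r2, x$metrics$spearman))
  invisible(x)
}

#' Predict enrichment scores for new sequences
#'
#' @param object An `es_model`.
#' @param newdata Character vector of sequences of the model's length, or a
#'   data frame with an `aa_seq` column.
#' @param ... Unused.
#' @return Numeric vector of predicted enrichment scores.
#' @export
predict.es_model <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$aa_seq else newdata
  if (any(nchar(seqs) != object$length)) {
    abort(sprintf("Sequences must have length %d for this model.", object$length))
  }
  X <- featurize(seqs, features = object$features)
  drop(X %*% object$weights) + object$intercept
}

#' @describeIn fit_es_model Tidy the fitted positional weights into a tibble
#'   with columns `position`, `residue`, `estimate`.
#' @param x An `es_model`.
#' @export
tidy.es_model <- function(x, ...) {
  parts <- strsplit(names(x$weights), ":", fixed = TRUE)
  tibble::tibble(
    position = as.integer(vapply(parts, `[[`, "", 1)),
    residue = vapply(parts, `[[`, "", 2),
    estimate = unname(x$weights)
  ) |> dplyr::arrange(.data$position, .data$residue)
}

#' @describeIn fit_es_model One-row model summary (length, split sizes,
#'   held-out R-squared and Spearman correlation).
#' @export
glance.es_model <- function(x, ...) {
  tibble::tibble(
    length = x$length, l2 = x$l2, n_train = x$metrics$n_train,
    n_eval = x$metrics$n_eval, r2 = x$metrics$r2,
    spearman = x$metrics$spearman
  )
}

#' Decile-rank calibration of predicted versus actual enrichment scores
#'
#' Ranks the evaluation records into deciles of actual ES (as evenly sized as
#' possible) and reports, within each decile, the mean and standard deviation
#' of the percentile rank of the predicted ES over the whole evaluation set.
#' A perfectly calibrated predictor yields mean percentiles near
#' 5, 15, ..., 95; an uninformative one yields means near 50 in every decile.
#'
#' @param model An `es_model`; its held-out evaluation records are used
#'   unless `eval_records` is supplied.
#' @param eval_records Optional tibble with columns `aa_seq` and `es`
#'   (at least 100 rows recommended, at least 10 required).
#' @return A tibble with 10 rows: `decile`, `mean_pred_percentile`,
#'   `sd_pred_percentile`, `n`.
#' @export
decile_diagnostic <- function(model, eval_records = NULL) {
  rec <- eval_records %||% model$eval
  if (is.null(rec$pred)) rec$pred <- predict(model, rec$aa_seq)
  decile_calibration(rec$es, rec$pred)
}

#' @rdname decile_diagnostic
#' @param actual,predicted Numeric vectors of actual and predicted scores.
#' @export
decile_calibration <- function(actual, predicted) {
  n <- length(actual)
  if (n < 10) abort("At least 10 records are required for a decile diagnostic.")
  pct <- 100 * (rank(predicted, ties.method = "average") - 0.5) / n
  tibble::tibble(
    decile = dplyr::ntile(actual, 10),
    pct = pct
  ) |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(
      mean_pred_percentile = mean(.data$pct),
      sd_pred_percentile = sd(.data$pct),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$decile)
}

#' Decile calibration plot
#'
#' @param diagnostic Output of [decile_diagnostic()].
#' @return A ggplot object.
#' @export
plot_decile_diagnostic <- function(diagnostic) {
  ggplot2::ggplot(diagnostic,
                  ggplot2::aes(x = .data$decile, y = .data$mean_pred_percentile)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_pred_percentile - .data$sd_pred_percentile,
      ymax = .data$mean_pred_percentile + .data$sd_pred_percentile
    ), width = 0.2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Decile of actual ES",
                  y = "Mean predicted-ES percentile rank")
}

#' @export
autoplot.es_model <- function(object, ...) {
  plot_decile_diagnostic(decile_diagnostic(object))
}

#' Fit one enrichment-score model per CDR-H3 length
#'
#' @param records An `es_tbl` spanning several lengths.
#' @param lengths Lengths to fit (default: all lengths with at least
#'   `min_records` rows).
#' @param min_records Minimum records per length.
#' @inheritParams fit_es_model
#' @return A named list of `es_model` objects keyed by length, of class
#'   `es_model_set`.
#' @export
fit_es_models <- function(records, lengths = NULL, l2 = 1e-6,
                          train_fraction = 0.7, seed = 1, min_records = 50) {
  counts <- table(records$length)
  if (is.null(lengths)) {
    lengths <- as.integer(names(counts)[counts >= min_records])
  }
  models <- lapply(lengths, function(L) {
    fit_es_model(records[records$length == L, , drop = FALSE],
                 l2 = l2, train_fraction = train_fraction, seed = seed + L)
  })
  structure(setNames(models, lengths), class = "es_model_set")
}

#' Screen candidate sequences by predicted enrichment score
#'
#' Scores each candidate with the model matching its length and keeps exactly
#' the candidates with predicted ES strictly greater than zero, i.e. the
#' sequences predicted to be enriched by panning.
#'
#' @param models An `es_model` or an `es_model_set`.
#' @param candidates Character vector of candidate sequences.
#' @return A tibble with columns `aa_seq`, `length`, `pred_es`, `kept`; the
#'   per-length kept fraction is attached as attribute `kept_fraction`.
#' @export
screen_candidates <- function(models, candidates) {
  if (inherits(models, "es_model")) {
    models <- structure(setNames(list(models), models$length),
                        class = "es_model_set")
  }
  lens <- nchar(candidates)
  missing <- setdiff(unique(lens), as.integer(names(models)))
  if (length(missing)) {
    abort(sprintf("No trained model for candidate length(s): %s",
                  paste(missing, collapse = ", ")))
  }
  pred <- numeric(length(candidates))
  for (L in unique(lens)) {
    sel <- lens == L
    pred[sel] <- predict(models[[as.character(L)]], candidates[sel])
  }
  out <- tibble::tibble(
    aa_seq = candidates, length = lens, pred_es = pred, kept = pred > 0
  )
  attr(out, "kept_fraction") <- out |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(kept_fraction = mean(.data$kept), .groups = "drop")
  out
}

#' Serialize / restore an enrichment-score model as JSON
#'
#' Weights are keyed `"position:residue"`; metrics and the evaluation split
#' are not serialized.
#'
#' @param model An `es_model`.
#' @param path JSON file path.
#' @return `read_es_model()` returns an `es_model` (without held-out
#'   records); `write_es_model()` returns `model` invisibly.
#' @export
write_es_model <- function(model, path) {
  obj <- list(
    length = model$length,
    intercept = model$intercept,
    l2 = model$l2,
    train_fraction = model$train_fraction,
    seed = model$seed,
    weights = as.list(model$weights)
  )
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("The jsonlite package is required to serialize models.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_es_model
#' @export
read_es_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(length = as.integer(obj$length),
         features = names(obj$weights),
         weights = unlist(obj$weights),
         intercept = obj$intercept, l2 = obj$l2,
         train_fraction = obj$train_fraction, seed = obj$seed,
         metrics = NULL, eval = NULL),
    class = "es_model"
  )
}
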