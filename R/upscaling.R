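#' Collinearity screen on candidate predictors
#'
#' Computes pairwise Pearson correlations among candidate predictor columns
#' and, for every pair with |r| at or above the cutoff, drops the
#' lower-priority feature. Priority is declared by the caller (live coral
#' cover highest by default, since it is the variable the mapped product
#' provides); constant features have undefined correlations and are dropped
#' with a warning.
#'
#' @param features Data frame of numeric candidate predictors.
#' @param priority Character vector of column names, highest priority
#'   first; unlisted columns rank below listed ones in input order.
#' @param cutoff Absolute-correlation threshold (default 0.7).
#' @return List with `retained` (column names), `dropped`, and
#'   `correlations` (the full correlation matrix).
#' @export
collinearity_screen <- function(features, priority = names(features),
                                cutoff = 0.7) {
  stopifnot(is.data.frame(features), ncol(features) >= 2)
  nm <- names(features)
  constant <- vapply(features, function(x) stats::sd(x) == 0, logical(1))
  dropped <- character(0)
  if (any(constant)) {
    warning("constant feature(s) dropped: ",
            paste(nm[constant], collapse = ", "), call. = FALSE)
    dropped <- nm[constant]
  }
  rank_of <- function(x) {
    r <- match(x, priority)
    ifelse(is.na(r), length(priority) + match(x, nm), r)
  }
  cors <- suppressWarnings(stats::cor(features))
  active <- setdiff(nm, dropped)
  repeat {
    sub <- cors[active, active, drop = FALSE]
    diag(sub) <- 0
    worst <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1, ]
    if (max(abs(sub)) < cutoff) break
    pair <- c(active[worst[1]], active[worst[2]])
    loser <- pair[which.max(rank_of(pair))]
    dropped <- c(dropped, loser)
    active <- setdiff(active, loser)
    if (length(active) < 2) break
  }
  list(retained = active, dropped = dropped, correlations = cors)
}

#' Flag outliers by Cook's distance
#'
#' Fits OLS of `y` on all columns of `X` and flags observations whose
#' Cook's distance exceeds three times the mean Cook's distance. Flagged
#' rows are excluded from downstream model fitting, never silently deleted.
#'
#' @param y Response vector.
#' @param X Data frame of predictors.
#' @param multiplier Flag threshold as a multiple of the mean distance
#'   (default 3).
#' @return Logical vector of flags (TRUE = outlier), with the distances as
#'   attribute `"cooks"`.
#' @export
cooks_outlier_filter <- function(y, X, multiplier = 3) {
  stopifnot(length(y) == nrow(X))
  if (length(y) <= ncol(X) + 1)
    stop("cooks_outlier_filter: need n > p + 1", call. = FALSE)
  if (length(y) == ncol(X) + 2)
    warning("n = p + 2: Cook's distances are unstable at this size",
            call. = FALSE)
  fit <- stats::lm(y ~ ., data = cbind(data.frame(y = y), X))
  if (any(is.na(stats::coef(fit))))
    stop("cooks_outlier_filter: singular design", call. = FALSE)
  d <- stats::cooks.distance(fit)
  flags <- d > multiplier * mean(d)
  attr(flags, "cooks") <- unname(d)
  unname_keep_attr <- flags
  unname_keep_attr
}

#' Optimal PLSR component count by cross-validation
#'
#' Partial-least-squares regression of the response on the candidate
#' predictors with seeded k-fold cross-validation; returns the component
#' count minimizing CV prediction error (optionally the most parsimonious
#' count within one standard error of the minimum). The PLS fits are
#' delegated to \pkg{mixOmics}; the fold loop and error accounting are
#' local, so the selection is deterministic given the seed. A flat CV curve
#' (no component reduces error by more than 1% of the null error) triggers
#' a warning that the response looks like noise.
#'
#' @param y Response vector.
#' @param X Data frame of at least 2 numeric predictors.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param max_comp Largest component count to consider (default `ncol(X)`).
#' @param one_se Use the 1-SE rule (default FALSE).
#' @return Integer component count, with the per-component CV mean squared
#'   errors (including the 0-component null model) as attribute `"cv_mse"`.
#' @export
plsr_component_selection <- function(y, X, folds = 10, seed,
                                     max_comp = ncol(X), one_se = FALSE) {
  stopifnot(ncol(X) >= 2, length(y) == nrow(X))
  if (missing(seed)) stop("plsr_component_selection: seed required",
                          call. = FALSE)
  if (!requireNamespace("mixOmics", quietly = TRUE))
    stop("plsr_component_selection() requires the 'mixOmics' package",
         call. = FALSE)
  n <- length(y)
  folds <- min(folds, n)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  max_comp <- min(max_comp, ncol(X))
  press <- matrix(NA_real_, folds, max_comp + 1)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    press[f, 1] <- sum((y[te] - mean(y[tr]))^2)  # null model
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = max_comp,
                         mode = "regression", scale = TRUE)
    pred <- stats::predict(fit, X[te, , drop = FALSE])$predict
    for (k in seq_len(max_comp))
      press[f, k + 1] <- sum((y[te] - pred[, 1, k])^2)
  }
  cv_mse <- colSums(press) / n
  names(cv_mse) <- 0:max_comp
  best <- which.min(cv_mse) - 1L
  if (one_se && best > 0) {
    fold_mse <- sweep(press, 1, tabulate(fold_id, folds), "/")
    se_best <- stats::sd(fold_mse[, best + 1]) / sqrt(folds)
    best <- min(which(cv_mse <= cv_mse[best + 1] + se_best)) - 1L
  }
  if (min(cv_mse[-1]) > cv_mse[1] * 0.99)
    warning("flat CV curve: no PLS component explains the response; ",
            "it may be noise", call. = FALSE)
  structure(as.integer(best), cv_mse = cv_mse)
}

#' Train/test model selection for the cover-to-production regression
#'
#' The upscaling model-selection procedure: the non-outlier data are split
#' 70:30 into training and testing once (seeded); each candidate predictor
#' set is fitted by OLS on the training split, predictors with coefficient
#' p >= `alpha` are dropped and the model refitted; candidates are scored
#' by RMSE on the test split, the lowest-RMSE model wins, and its
#' coefficients are refitted on all non-outlier data. Test rows never touch
#' coefficient estimation before selection.
#'
#' @param data Data frame of transect records with the response column
#'   `net` and every candidate predictor; typically
#'   `compute_budget()` output renamed via [as_scaling_dataset()].
#' @param candidates List of character vectors of predictor names, e.g.
#'   `list(c("lcc","rugosity","depth"), c("lcc","rugosity"), "lcc")`.
#' @param split_seed Integer seed for the 70:30 partition.
#' @param outlier_flags Optional logical vector from
#'   [cooks_outlier_filter()]; flagged rows are excluded everywhere.
#' @param train_prop Training fraction (default 0.7).
#' @param alpha Significance level for predictor dropping (default 0.05).
#' @return A `scaling_model`: final `fit` (lm on all non-outlier data),
#'   `predictors`, `coefficients`, `metrics` (per-candidate tibble of test
#'   RMSE and train/test/full R2), `split_seed`, `train_idx`.
#' @export
fit_and_select <- function(data, candidates, split_seed,
                           outlier_flags = NULL, train_prop = 0.7,
                           alpha = 0.05) {
  stopifnot(is.data.frame(data), "net" %in% names(data))
  if (length(candidates) == 0)
    stop("fit_and_select: empty candidate list", call. = FALSE)
  if (!is.null(outlier_flags)) data <- data[!outlier_flags, , drop = FALSE]
  n <- nrow(data)
  set.seed(split_seed)
  train_idx <- sort(sample.int(n, round(train_prop * n)))
  train <- data[train_idx, , drop = FALSE]
  test <- data[-train_idx, , drop = FALSE]

  r2 <- function(fit, newdata) {
    pred <- stats::predict(fit, newdata)
    1 - sum((newdata$net - pred)^2) / sum((newdata$net - mean(newdata$net))^2)
  }
  eval_candidate <- function(preds) {
    repeat {
      fml <- stats::reformulate(preds, response = "net")
      fit <- stats::lm(fml, data = train)
      pv <- summary(fit)$coefficients[-1, 4]
      if (all(pv < alpha) || length(preds) == 1) break
      preds <- setdiff(preds, names(which.max(pv)))
    }
    pred_test <- stats::predict(fit, test)
    fit_full <- stats::lm(stats::reformulate(preds, response = "net"),
                          data = data)
    tibble::tibble(
      model = paste(preds, collapse = " + "),
      predictors = list(preds),
      rmse = sqrt(mean((test$net - pred_test)^2)),
      r2_train = summary(fit)$r.squared,
      r2_test = r2(fit, test),
      r2_full = summary(fit_full)$r.squared
    )
  }
  metrics <- dplyr::bind_rows(lapply(candidates, eval_candidate))
  best <- which.min(metrics$rmse)
  final_preds <- metrics$predictors[[best]]
  final_fit <- stats::lm(stats::reformulate(final_preds, response = "net"),
                         data = data)
  structure(
    list(fit = final_fit, predictors = final_preds,
         coefficients = stats::coef(final_fit),
         metrics = dplyr::select(metrics, -"predictors"),
         split_seed = split_seed, train_idx = train_idx, n = n),
    class = "scaling_model"
  )
}

#' @export
print.scaling_model <- function(x, ...) {
  cat("<scaling_model> net production ~",
      paste(x$predictors, collapse = " + "), "\n")
  cf <- x$coefficients
  cat("  ", paste(sprintf("%s = %.5f", names(cf), cf), collapse = "; "),
      "\n")
  cat(sprintf("  selected by test RMSE over %d candidates (seed %d, n = %d)\n",
              nrow(x$metrics), x$split_seed, x$n))
  invisible(x)
}

#' Reshape budget output into the scaling dataset
#'
#' Extracts and renames the predictor columns the upscaling procedure uses
#' from a [compute_budget()] result.
#'
#' @param budget A `budget_result` tibble.
#' @return Tibble with `net`, `lcc`, `rugosity`, `depth`,
#'   `algal_substrate`.
#' @export
as_scaling_dataset <- function(budget) {
  tibble::tibble(
    net = budget$net, lcc = budget$lcc_percent, rugosity = budget$rugosity,
    depth = budget$depth_m, algal_substrate = budget$algal_substrate_percent
  )
}

#' Predict net production (and accretion) over a cover raster
#'
#' Applies a fitted cover-to-production regression pixelwise to a percent
#' live-coral-cover raster. Input values outside [0, 100] are clamped (the
#' count is reported via attribute `"n_clamped"`); nodata cells propagate
#' untouched; the output georeferencing is identical to the input. When
#' `accretion = TRUE` a second raster converts the prediction to mm y-1.
#'
#' @param model A `scaling_model` whose only predictor is `lcc`, or any
#'   object usable by `predict(model, data.frame(lcc = ...))`.
#' @param lcc_raster A [raster_grid()] of percent cover.
#' @param accretion Also return the accretion conversion (default TRUE).
#' @return List with `net` (raster, kg CaCO3 m-2 y-1), optionally
#'   `accretion` (mm y-1), and `summary` (mean prediction, share of
#'   positive pixels, clamp count).
#' @export
predict_raster <- function(model, lcc_raster, accretion = TRUE) {
  stopifnot(inherits(lcc_raster, "raster_grid"))
  v <- lcc_raster$values
  valid <- !is.na(v)
  n_clamped <- sum(v[valid] < 0 | v[valid] > 100)
  v[valid] <- pmin(pmax(v[valid], 0), 100)
  pred <- v
  fit <- if (inherits(model, "scaling_model")) model$fit else model
  pred[valid] <- stats::predict(fit, data.frame(lcc = v[valid]))
  out_net <- raster_grid(pred, lcc_raster$xllcorner, lcc_raster$yllcorner,
                         lcc_raster$cellsize, lcc_raster$nodata,
                         lcc_raster$crs)
  res <- list(
    net = out_net,
    summary = list(mean_net = mean(pred[valid]),
                   prop_positive = mean(pred[valid] > 0),
                   n_clamped = n_clamped)
  )
  if (accretion) {
    acc <- pred
    acc[valid] <- vertical_accretion(pred[valid])
    res$accretion <- raster_grid(acc, lcc_raster$xllcorner,
                                 lcc_raster$yllcorner, lcc_raster$cellsize,
                                 lcc_raster$nodata, lcc_raster$crs)
  }
  res
}
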