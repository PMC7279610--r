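# Exhaustive all-possible-subsets OLS of the Shannon response on per-band
# texture predictors, one group per (GLCM statistic, window size).
# With p candidate predictors a group holds 2^p - 1 models; models are
# ranked by Gaussian-likelihood AIC, with adjusted R^2 and in-sample RMSE
# reported alongside.

#' Ordinary least squares fit (intercept always included)
#'
#' @param X Numeric matrix of predictors (n x k), no intercept column.
#' @param y Numeric response vector.
#' @return List: `coefficients` (intercept first), `rss`, `fitted`,
#'   `residuals`, `rank`, `degenerate` (`TRUE` when the design is
#'   rank-deficient).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  degenerate <- fit$rank < ncol(Xi)
  res <- fit$residuals
  list(coefficients = fit$coefficients, rss = sum(res^2),
       fitted = fit$fitted.values, residuals = res,
       rank = fit$rank, degenerate = degenerate)
}

#' Gaussian-likelihood AIC from residual sum of squares
#'
#' Full-likelihood convention: `n*log(2*pi) + n*log(rss/n) + n + 2*(k + 2)`,
#' counting the intercept and the error variance among the parameters. The
#' additive constants are shared by all models with the same `n`, so rankings
#' are invariant to the convention. `rss = 0` returns `-Inf` (ranked best)
#' with a warning.
#'
#' @param rss Residual sum of squares.
#' @param n Sample size.
#' @param k Number of predictors (excluding intercept).
#' @return AIC value.
#' @export
aic_gaussian <- function(rss, n, k) {
  if (rss <= 0) {
    warning("rss = 0: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 2)
}

#' Adjusted R-squared and in-sample RMSE
#'
#' `adj_r2 = 1 - (1 - R2) * (n - 1) / (n - k - 1)` with `R2 = 1 - rss/tss`;
#' `rmse = sqrt(rss / n)` (in-sample, denominator n).
#'
#' @param rss Residual sum of squares.
#' @param tss Total sum of squares (about the mean).
#' @param n Sample size.
#' @param k Number of predictors.
#' @return Scalar.
#' @export
adj_r2 <- function(rss, tss, n, k) {
  if (tss <= 0) stop_texdiv("tss must be positive", class = "texdiv_validation_error")
  if (n <= k + 1) return(NA_real_)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' @rdname adj_r2
#' @export
rmse <- function(rss, n) sqrt(rss / n)

#' Exhaustive all-subsets regression within one predictor group
#'
#' Fits every non-empty subset of the candidate predictor columns (2^p - 1
#' models), computes AIC, adjusted R^2 and RMSE for each, and identifies the
#' best model overall and the best model per predictor count (smallest AIC;
#' ties broken by smaller k, then lexicographic predictor names).
#' Rank-deficient subsets are flagged degenerate and excluded from ranking.
#'
#' @param features Data frame containing `shannon` and the predictor columns.
#' @param predictors Character vector of predictor column names (p <= 20).
#' @param group Optional list/character tag (e.g. statistic + window) carried
#'   into the report.
#' @return Object of class `subset_report`: `models` data frame (one row per
#'   subset: `model_id`, `bitmask`, `predictors`, `k`, `rss`, `aic`,
#'   `adj_r2`, `rmse`, `degenerate`), `best_overall` (row index),
#'   `best_per_k` (named row indices), `n`, `group`, `coefficients` list.
#' @export
all_subsets <- function(features, predictors, group = NULL) {
  keep <- stats::complete.cases(features[, c("shannon", predictors)])
  dat <- features[keep, , drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors)
  if (p < 1) stop_texdiv("need at least one predictor", class = "texdiv_parameter_error")
  if (p > 20) stop_texdiv("too many predictors for exhaustive enumeration",
                          class = "texdiv_parameter_error")
  if (n < p + 2) {
    stop_texdiv("sample too small for the largest subset (n < p + 2)",
                class = "texdiv_sample_size_error")
  }
  y <- dat$shannon
  X <- as.matrix(dat[, predictors, drop = FALSE])
  tss <- sum((y - mean(y))^2)

  n_models <- 2L^p - 1L
  bitmask <- seq_len(n_models)
  rss_v <- aic_v <- adj_v <- rmse_v <- numeric(n_models)
  k_v <- integer(n_models)
  deg_v <- logical(n_models)
  pred_str <- character(n_models)
  coefs <- vector("list", n_models)
  for (m in bitmask) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    k <- length(sel)
    fit <- fit_ols(X[, sel, drop = FALSE], y)
    k_v[m] <- k
    rss_v[m] <- fit$rss
    deg_v[m] <- fit$degenerate
    aic_v[m] <- if (fit$degenerate) NA_real_ else
      suppressWarnings(aic_gaussian(fit$rss, n, k))
    adj_v[m] <- adj_r2(fit$rss, tss, n, k)
    rmse_v[m] <- rmse(fit$rss, n)
    pred_str[m] <- paste(sort(predictors[sel]), collapse = "+")
    coefs[[m]] <- fit$coefficients
  }
  if (any(deg_v)) {
    warning(sprintf("%d rank-deficient subset(s) excluded from ranking", sum(deg_v)))
  }
  models <- data.frame(
    model_id = bitmask, bitmask = bitmask, predictors = pred_str, k = k_v,
    rss = rss_v, aic = aic_v, adj_r2 = adj_v, rmse = rmse_v,
    degenerate = deg_v, stringsAsFactors = FALSE
  )
  rankable <- which(!deg_v)
  ord <- rankable[order(aic_v[rankable], k_v[rankable], pred_str[rankable])]
  best_overall <- ord[1]
  best_per_k <- vapply(sort(unique(k_v[rankable])), function(kk) {
    cand <- rankable[k_v[rankable] == kk]
    cand[order(aic_v[cand], pred_str[cand])][1]
  }, integer(1))
  names(best_per_k) <- sort(unique(k_v[rankable]))
  structure(list(models = models, best_overall = best_overall,
                 best_per_k = best_per_k, n = n, group = group,
                 predictors = predictors, coefficients = coefs,
                 tss = tss,
                 plot_ids = if ("plot_id" %in% names(dat)) dat$plot_id else NULL,
                 data = dat[, c(intersect("plot_id", names(dat)), "shannon",
                                predictors)]),
            class = "subset_report")
}

#' @export
print.subset_report <- function(x, ...) {
  b <- x$models[x$best_overall, ]
  tag <- if (is.null(x$group)) "" else paste0(" [", paste(unlist(x$group), collapse = ", "), "]")
  cat(sprintf("subset_report%s: %d models, n = %d\n", tag, nrow(x$models), x$n))
  cat(sprintf("  best AIC %.2f: {%s} (k=%d, adjR2=%.3f, RMSE=%.3f)\n",
              b$aic, b$predictors, b$k, b$adj_r2, b$rmse))
  invisible(x)
}

#' All-subsets regression across every (statistic, window) group
#'
#' Runs [all_subsets()] once per GLCM statistic x window size group of a
#' feature matrix, using the 7 per-band columns of that group as candidate
#' predictors. Predictors in a group are referred to by their band names.
#'
#' @param features A `plot_features` data frame.
#' @param statistics,windows Subsets of statistics/windows; default all
#'   present.
#' @return Named list of `subset_report` (names `"<statistic>_w<window>"`),
#'   class `subset_report_set`. Groups skipped for sample-size reasons are
#'   recorded in the `"errors"` attribute.
#' @export
all_subsets_by_group <- function(features, statistics = NULL, windows = NULL) {
  fc <- feature_columns(features)
  if (is.null(statistics)) statistics <- intersect(GLCM_STATS, unique(fc$statistic))
  if (is.null(windows)) windows <- sort(unique(fc$window))
  reports <- list()
  errors <- list()
  for (s in statistics) {
    for (w in windows) {
      sel <- fc[fc$statistic == s & fc$window == w, ]
      if (nrow(sel) == 0L) next
      sel <- sel[order(match(sel$band, WV2_BANDS)), ]
      dat <- features[, c("plot_id", "shannon", sel$column)]
      names(dat)[-(1:2)] <- sel$band
      tag <- paste0(s, "_w", w)
      rep_try <- tryCatch(
        all_subsets(dat, predictors = sel$band,
                    group = list(statistic = s, window = w)),
        texdiv_sample_size_error = function(e) e
      )
      if (inherits(rep_try, "error")) errors[[tag]] <- conditionMessage(rep_try)
      else reports[[tag]] <- rep_try
    }
  }
  attr(reports, "errors") <- errors
  class(reports) <- "subset_report_set"
  reports
}

#' Flatten a report set into one data frame / best-model summary
#'
#' `report_table` returns one row per fitted model across all groups;
#' `best_model_table` mirrors the usual "best model per statistic x window"
#' summary layout (predictor bands + smallest AIC per group).
#'
#' @param reports A `subset_report_set`.
#' @return Data frame.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(tag) {
    r <- reports[[tag]]
    cbind(data.frame(group = tag,
                     statistic = r$group$statistic,
                     window = r$group$window,
                     stringsAsFactors = FALSE),
          r$models)
  }))
}

#' @rdname report_table
#' @export
best_model_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(tag) {
    r <- reports[[tag]]
    b <- r$models[r$best_overall, ]
    data.frame(statistic = r$group$statistic, window = r$group$window,
               predictors = b$predictors, k = b$k, aic = b$aic,
               adj_r2 = b$adj_r2, rmse = b$rmse, stringsAsFactors = FALSE)
  }))
}
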