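# Residual-correlation comparison of competing models. Beyond scalar fit
# statistics, correlating per-plot estimation errors shows whether competing
# models mis-estimate the same plots in the same direction.

#' Residuals of a fitted subset model
#'
#' Recomputes observed-minus-fitted Shannon values for one model of a
#' [all_subsets()] report, aligned to the plots used in the fit.
#'
#' @param report A `subset_report`.
#' @param model_id Row index (`models$model_id`); default the best-AIC model.
#' @return Numeric vector of residuals with `plot_id` names when available,
#'   plus attribute `tag` describing the model.
#' @export
model_residuals <- function(report, model_id = NULL) {
  stopifnot(inherits(report, "subset_report"))
  if (is.null(model_id)) model_id <- report$models$model_id[report$best_overall]
  row <- which(report$models$model_id == model_id)
  if (length(row) != 1L) {
    stop_texdiv("unknown model_id", class = "texdiv_alignment_error")
  }
  sel <- which(bitwAnd(report$models$bitmask[row],
                       bitwShiftL(1L, seq_along(report$predictors) - 1L)) != 0L)
  X <- as.matrix(report$data[, report$predictors[sel], drop = FALSE])
  y <- report$data$shannon
  beta <- report$coefficients[[row]]
  fitted <- cbind(1, X) %*% beta[!is.na(beta)]
  res <- as.numeric(y - fitted)
  if (!is.null(report$plot_ids)) names(res) <- report$plot_ids
  attr(res, "tag") <- list(group = report$group,
                           predictors = report$models$predictors[row],
                           k = report$models$k[row])
  res
}

#' Pearson correlation between two error vectors
#'
#' @param a,b Residual vectors over the same plots (aligned by `plot_id`
#'   names when present).
#' @return Pearson r, or `NA` when either vector is constant or fewer than 3
#'   common plots exist.
#' @export
error_correlation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) < 3L || length(a) != length(b)) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Three-category residual-correlation comparison suite
#'
#' Given the per-group all-subsets reports, selects a reference model (by
#' default the smallest-AIC model across all groups) and correlates its
#' per-plot errors against: (1) the best model per predictor count within the
#' reference group; (2) the best model of the same statistic at the other
#' window sizes; (3) the best model of each other GLCM statistic (at that
#' statistic's best window).
#'
#' @param reports A `subset_report_set` from [all_subsets_by_group()].
#' @param reference `"auto"` (global best AIC) or a group tag such as
#'   `"entropy_w5"`.
#' @return List of class `comparison_suite`: `reference` (tag), `table`
#'   (long-format data frame: `category`, `model_a`, `model_b`, `r`,
#'   `n_plots`).
#' @export
comparison_suite <- function(reports, reference = "auto") {
  stopifnot(inherits(reports, "subset_report_set"), length(reports) > 0)
  best_aics <- vapply(reports, function(r) r$models$aic[r$best_overall], numeric(1))
  ref_tag <- if (identical(reference, "auto")) names(which.min(best_aics)) else reference
  if (!ref_tag %in% names(reports)) {
    stop_texdiv("reference group '", ref_tag, "' not found",
                class = "texdiv_alignment_error")
  }
  ref_rep <- reports[[ref_tag]]
  ref_res <- model_residuals(ref_rep)
  ref_stat <- ref_rep$group$statistic
  ref_win <- ref_rep$group$window
  ref_name <- sprintf("%s_w%d_k%d", ref_stat, ref_win,
                      ref_rep$models$k[ref_rep$best_overall])

  rows <- list()
  add_row <- function(category, name, res) {
    r <- error_correlation(ref_res, res)
    n <- length(intersect(names(ref_res) %||% seq_along(ref_res),
                          names(res) %||% seq_along(res)))
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, model_a = ref_name, model_b = name, r = r,
      n_plots = n, stringsAsFactors = FALSE)
  }

  # (1) across predictor counts within the reference group
  for (kk in names(ref_rep$best_per_k)) {
    idx <- ref_rep$best_per_k[[kk]]
    add_row("predictor-count",
            sprintf("%s_w%d_k%s", ref_stat, ref_win, kk),
            model_residuals(ref_rep, ref_rep$models$model_id[idx]))
  }
  # (2) same statistic, other windows
  for (tag in names(reports)) {
    g <- reports[[tag]]$group
    if (g$statistic == ref_stat && g$window != ref_win) {
      add_row("window", sprintf("%s_w%d_best", ref_stat, g$window),
              model_residuals(reports[[tag]]))
    }
  }
  # (3) other statistics at their best window
  other_stats <- setdiff(unique(vapply(reports, function(r) r$group$statistic,
                                       character(1))), ref_stat)
  for (s in other_stats) {
    tags <- names(reports)[vapply(reports, function(r) r$group$statistic == s,
                                  logical(1))]
    best_tag <- tags[which.min(best_aics[tags])]
    add_row("glcm", sprintf("%s_best", s), model_residuals(reports[[best_tag]]))
  }

  structure(list(reference = ref_tag, table = do.call(rbind, rows)),
            class = "comparison_suite")
}

#' @export
print.comparison_suite <- function(x, ...) {
  cat("comparison_suite (reference:", x$reference, ")\n")
  for (cat_name in unique(x$table$category)) {
    sub <- x$table[x$table$category == cat_name, ]
    cat(sprintf("  %-15s mean r = %.3f (n models = %d)\n", cat_name,
                mean(sub$r, na.rm = TRUE), nrow(sub)))
  }
  invisible(x)
}
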