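# Zonal aggregation of texture planes over circular field plots.

#' Per-plot texture predictor matrix joined to the Shannon response
#'
#' For each plot, selects the pixels whose centers fall inside the disc
#' (Euclidean distance to the plot center <= radius) and are non-`NA` in the
#' texture plane, applies the aggregation (mean by default), and joins the
#' plot's Shannon index. Plots with zero valid pixels in every plane are
#' dropped with a warning; per-plane missingness is preserved as `NA`.
#'
#' @param stack A [texture_stack()].
#' @param plots Plot table ([generate_plots()] / [read_plots()]).
#' @param diversity Per-plot diversity table ([diversity_table()]).
#' @param agg Aggregation: `"mean"` (default) or `"median"`.
#' @return Data frame of class `plot_features`: `plot_id`, `shannon`,
#'   `n_woody_px`, then one column per predictor named
#'   `<band>_<statistic>_w<window>`.
#' @export
extract_plot_features <- function(stack, plots, diversity, agg = c("mean", "median")) {
  stopifnot(inherits(stack, "texture_stack"))
  agg <- match.arg(agg)
  agg_fun <- if (agg == "mean") mean else stats::median
  if (!all(plots$plot_id %in% diversity$plot_id)) {
    plots <- plots[plots$plot_id %in% diversity$plot_id, ]
  }
  if (nrow(plots) == 0L) {
    stop_texdiv("no plots overlap the diversity table",
                class = "texdiv_alignment_error")
  }
  d <- dim(stack$values[[1]][[1]])[1:2]
  centers <- list(
    x = stack$origin[1] + (seq_len(d[2]) - 0.5) * stack$pixel_size,
    y = stack$origin[2] - (seq_len(d[1]) - 0.5) * stack$pixel_size
  )
  idx_list <- lapply(seq_len(nrow(plots)), function(i) {
    disc_pixel_index(centers, plots$x[i], plots$y[i], plots$radius_m[i])
  })
  if (any(vapply(idx_list, nrow, integer(1)) == 0L)) {
    stop_texdiv("plot disc falls outside the raster: check alignment",
                class = "texdiv_alignment_error")
  }

  cols <- list()
  n_valid_px <- matrix(0L, nrow(plots), 0)
  for (b in names(stack$values)) {
    for (w in names(stack$values[[b]])) {
      arr <- stack$values[[b]][[w]]
      # linear index per statistic plane
      for (s_i in seq_along(stack$statistics)) {
        plane <- arr[, , s_i]
        vals <- vapply(idx_list, function(idx) {
          v <- plane[idx]
          v <- v[!is.na(v)]
          if (length(v) == 0L) NA_real_ else agg_fun(v)
        }, numeric(1))
        cols[[paste0(b, "_", stack$statistics[s_i], "_", w)]] <- vals
      }
    }
  }
  n_px <- vapply(seq_len(nrow(plots)), function(i) {
    plane <- stack$values[[1]][[1]][, , 1]
    sum(!is.na(plane[idx_list[[i]]]))
  }, integer(1))

  out <- data.frame(plot_id = plots$plot_id, stringsAsFactors = FALSE)
  out$shannon <- diversity$shannon[match(plots$plot_id, diversity$plot_id)]
  out$n_woody_px <- n_px
  out <- cbind(out, as.data.frame(cols, optional = TRUE))
  empty <- rowSums(!is.na(out[, -(1:3), drop = FALSE])) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d plot(s) with no valid texture pixels", sum(empty)))
    out <- out[!empty, ]
  }
  rownames(out) <- NULL
  class(out) <- c("plot_features", "data.frame")
  out
}

#' Parse predictor column names of a feature matrix
#'
#' @param features A `plot_features` data frame.
#' @return Data frame `column`, `band`, `statistic`, `window`.
#' @export
feature_columns <- function(features) {
  cols <- setdiff(names(features), c("plot_id", "shannon", "n_woody_px"))
  m <- regmatches(cols, regexec("^([A-Za-z0-9]+)_([a-z_]+)_w(\\d+)$", cols))
  data.frame(
    column = cols,
    band = vapply(m, `[`, character(1), 2),
    statistic = vapply(m, `[`, character(1), 3),
    window = as.integer(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}
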