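# Woody vegetation extraction: NDVI-style index on the NIR2/Red pair,
# averaged over image segments, thresholded at 0.4 (inclusive).

#' WorldView-2 improved vegetation index (WV-VI)
#'
#' Per-pixel normalised difference of the second near-infrared band against
#' the red band, (NIR2 - Red) / (NIR2 + Red). Woody canopy retains a strong
#' NIR plateau even in the dry season, so the index separates woody crowns
#' from senescent grass and bare soil.
#'
#' @param scn A [scene()] with `NIR2` and `Red` bands.
#' @return Matrix in \[-1, 1\]; `NA` where the denominator is zero or inputs
#'   are nodata.
#' @export
wv_vi <- function(scn) {
  stopifnot(inherits(scn, "texdiv_scene"))
  if (!all(c("NIR2", "Red") %in% names(scn$bands))) {
    stop_texdiv("scene must contain NIR2 and Red bands",
                class = "texdiv_configuration_error")
  }
  nir2 <- scn$bands$NIR2; red <- scn$bands$Red
  den <- nir2 + red
  vi <- (nir2 - red) / den
  vi[den == 0] <- NA_real_
  vi[scn$nodata_mask] <- NA_real_
  vi
}

#' Segment a multi-band scene into spectrally homogeneous regions
#'
#' Deterministic segmentation stand-in: pixels are clustered in the 7-band
#' spectral space by k-means (Lloyd iterations, centers initialised at evenly
#' spaced quantiles of the first principal component, so no random state),
#' then each spectral cluster is split into spatially connected components.
#' A single `scale` knob sets the number of spectral clusters; larger scale
#' means finer spectral splitting, hence smaller segments.
#'
#' @param scn A [scene()].
#' @param scale Number of spectral clusters (>= 1).
#' @param iter_max Lloyd iteration cap.
#' @return Integer matrix of segment ids (1..n_segments); `NA` at nodata.
#' @export
segment_scene <- function(scn, scale = 8L, iter_max = 100L) {
  stopifnot(inherits(scn, "texdiv_scene"))
  d <- dim(scn)
  valid <- !scn$nodata_mask
  X <- vapply(scn$bands, function(b) as.vector(b), numeric(d[1] * d[2]))
  vidx <- which(as.vector(valid))
  Xv <- X[vidx, , drop = FALSE]
  ux <- unique(Xv)
  k <- max(1L, min(as.integer(scale), nrow(ux)))
  if (k == 1L) {
    cl <- rep(1L, length(vidx))
  } else {
    pc1 <- Xv %*% stats::prcomp(Xv, center = TRUE, scale. = FALSE)$rotation[, 1]
    qs <- stats::quantile(pc1, probs = (seq_len(k) - 0.5) / k, type = 1)
    ctr_idx <- vapply(qs, function(q) which.min(abs(pc1 - q)), integer(1))
    centers <- Xv[ctr_idx, , drop = FALSE]
    centers <- centers[!duplicated(centers), , drop = FALSE]
    cl <- if (nrow(centers) == 1L) {
      rep(1L, length(vidx))
    } else {
      # Lloyd with a fixed iteration cap: deterministic given the data; the
      # cap (not convergence) bounds runtime, assignments are stable enough
      # for segment averaging well before it
      suppressWarnings(stats::kmeans(Xv, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")$cluster)
    }
  }
  cluster_grid <- matrix(NA_integer_, d[1], d[2])
  cluster_grid[vidx] <- cl

  # connected components (8-neighbour) within each spectral cluster
  seg <- matrix(NA_integer_, d[1], d[2])
  offset <- 0L
  for (c_id in sort(unique(cl))) {
    bin <- !is.na(cluster_grid) & cluster_grid == c_id
    lab <- EBImage::bwlabel(bin)
    lab <- matrix(as.integer(lab), d[1], d[2])
    n_lab <- max(lab)
    seg[lab > 0] <- lab[lab > 0] + offset
    offset <- offset + n_lab
  }
  seg
}

#' Build the woody mask from segment-averaged WV-VI
#'
#' Averages the vegetation index over each segment and marks every pixel of a
#' segment woody when the segment mean meets the threshold (inclusive, so a
#' mean exactly at the threshold is woody).
#'
#' @param scn A [scene()].
#' @param segment_ids Integer matrix from [segment_scene()].
#' @param threshold Segment-mean WV-VI cutoff in \[-1, 1\]; default 0.4.
#' @return Object of class `woody_mask`: list with logical `mask`,
#'   `segment_ids`, `threshold_used`, and the per-segment mean index
#'   `segment_mean_vi`.
#' @export
build_woody_mask <- function(scn, segment_ids = NULL, threshold = 0.4) {
  stopifnot(inherits(scn, "texdiv_scene"))
  if (threshold < -1 || threshold > 1) {
    stop_texdiv("'threshold' must lie in [-1, 1]",
                class = "texdiv_parameter_error")
  }
  if (is.null(segment_ids)) segment_ids <- segment_scene(scn)
  vi <- wv_vi(scn)
  ok <- !is.na(segment_ids) & !is.na(vi)
  seg_mean <- tapply(vi[ok], segment_ids[ok], mean)
  woody_ids <- as.integer(names(seg_mean))[seg_mean >= threshold]
  mask <- matrix(FALSE, nrow(vi), ncol(vi))
  mask[!is.na(segment_ids) & segment_ids %in% woody_ids] <- TRUE
  mask[scn$nodata_mask] <- FALSE
  structure(list(mask = mask, segment_ids = segment_ids,
                 threshold_used = threshold,
                 segment_mean_vi = seg_mean),
            class = "woody_mask")
}

#' @export
print.woody_mask <- function(x, ...) {
  cat(sprintf("woody_mask: %d/%d px woody (%.1f%%), %d segments, threshold %.2f\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask),
              length(x$segment_mean_vi), x$threshold_used))
  invisible(x)
}

#' Precision and recall of a mask against a reference woody layer
#'
#' @param mask Logical matrix (predicted woody).
#' @param truth Logical matrix (reference woody layer).
#' @return Named numeric: `precision`, `recall`.
#' @export
mask_accuracy <- function(mask, truth) {
  tp <- sum(mask & truth)
  c(precision = tp / max(sum(mask), 1L),
    recall = tp / max(sum(truth), 1L))
}
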