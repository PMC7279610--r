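# Gray-level co-occurrence matrix (GLCM) texture.
#
# The co-occurrence matrix g counts how often quantized gray-level pairs
# occur at unit offset in the four directions 0, 45, 90 and 135 degrees
# within a moving window; pairs are accumulated symmetrically (each ordered
# pair and its reverse) into a single matrix and normalised to sum 1. Eight
# Haralick statistics summarise each matrix.

#' Quantize a reflectance band into gray levels
#'
#' Linear binning into `ng` equal-width levels over a fixed (by default
#' global per-band) range; a value at the range maximum maps to level
#' `ng - 1`. A global range keeps level semantics comparable between windows.
#'
#' @param band Numeric matrix.
#' @param ng Number of gray levels (>= 2).
#' @param range Length-2 numeric, quantization range; defaults to the finite
#'   range of `band`.
#' @return Integer matrix of levels in `0..(ng-1)` (`NA` preserved), with
#'   attributes `ng` and `range`.
#' @export
quantize <- function(band, ng = 64L, range = NULL) {
  if (ng < 2) stop_texdiv("'ng' must be >= 2", class = "texdiv_parameter_error")
  if (is.null(range)) {
    range <- suppressWarnings(base::range(band, na.rm = TRUE, finite = TRUE))
  }
  if (!is.finite(range[1]) || !is.finite(range[2]) || range[2] <= range[1]) {
    warning("degenerate quantization range; all pixels mapped to level 0")
    lev <- band
    lev[!is.na(lev)] <- 0L
    storage.mode(lev) <- "integer"
  } else {
    lev <- floor((band - range[1]) / (range[2] - range[1]) * ng)
    lev[lev < 0] <- 0
    lev[lev > ng - 1] <- ng - 1L
    storage.mode(lev) <- "integer"
  }
  attr(lev, "ng") <- as.integer(ng)
  attr(lev, "range") <- range
  lev
}

#' Dequantize gray levels back to bin-center values
#'
#' @param levels Integer matrix from [quantize()].
#' @return Numeric matrix of bin centers.
#' @export
dequantize <- function(levels) {
  ng <- attr(levels, "ng"); rng <- attr(levels, "range")
  rng[1] + (levels + 0.5) / ng * (rng[2] - rng[1])
}

# unit offsets for the four directions (row, col), 0/45/90/135 degrees
GLCM_OFFSETS <- cbind(dr = c(0L, -1L, -1L, -1L), dc = c(1L, 1L, 0L, -1L))

#' Symmetric co-occurrence matrix of a quantized window
#'
#' Accumulates each ordered gray-level pair and its reverse across the four
#' unit-distance directions, skipping pairs that touch an invalid pixel, and
#' normalises by the total ordered-pair count.
#'
#' @param window Integer matrix of gray levels (`NA` allowed).
#' @param valid Logical matrix; `FALSE` marks pixels excluded from pairing.
#' @param ng Number of gray levels.
#' @param directions Subset of `1:4` selecting offsets among 0, 45, 90 and
#'   135 degrees; all four by default.
#' @return List of class `glcm_matrix`: `g` (ng x ng, sums to 1 when pairs
#'   exist), `ng`, `n_pairs` (unordered contributing pairs).
#' @export
cooccurrence <- function(window, valid = NULL,
                         ng = max(window, na.rm = TRUE) + 1L,
                         directions = 1:4) {
  if (is.null(valid)) valid <- !is.na(window)
  valid <- valid & !is.na(window)
  nr <- nrow(window); nc <- ncol(window)
  g <- matrix(0, ng, ng)
  n_pairs <- 0L
  for (o in directions) {
    dr <- GLCM_OFFSETS[o, 1]; dc <- GLCM_OFFSETS[o, 2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    for (i in r1) for (j in c1) {
      if (valid[i, j] && valid[i + dr, j + dc]) {
        a <- window[i, j] + 1L
        b <- window[i + dr, j + dc] + 1L
        g[a, b] <- g[a, b] + 1
        g[b, a] <- g[b, a] + 1
        n_pairs <- n_pairs + 1L
      }
    }
  }
  if (n_pairs > 0L) g <- g / sum(g)
  structure(list(g = g, ng = as.integer(ng), n_pairs = n_pairs),
            class = "glcm_matrix")
}

#' Eight Haralick statistics of a co-occurrence matrix
#'
#' With `g` the normalised symmetric GLCM over levels `0..ng-1`, computes
#' entropy \eqn{-\sum g \ln g} (with \eqn{0 \ln 0 = 0}), second (angular)
#' moment \eqn{\sum g^2}, contrast \eqn{\sum (i-j)^2 g}, dissimilarity
#' \eqn{\sum |i-j| g}, homogeneity \eqn{\sum g/(1+(i-j)^2)}, GLCM mean
#' \eqn{\mu = \sum_i i\, p_i} of the (symmetric) marginal, variance
#' \eqn{\sigma^2 = \sum (i-\mu)^2 g} and correlation
#' \eqn{\sum (i-\mu)(j-\mu) g / \sigma^2} (`NA` when \eqn{\sigma^2 = 0}).
#'
#' @param m A `glcm_matrix` from [cooccurrence()], or a normalised symmetric
#'   matrix.
#' @return Named numeric vector of the eight statistics.
#' @export
glcm_statistics <- function(m) {
  g <- if (inherits(m, "glcm_matrix")) m$g else m
  if (inherits(m, "glcm_matrix") && m$n_pairs == 0L) {
    return(stats::setNames(rep(NA_real_, 8L), GLCM_STATS))
  }
  if (abs(sum(g) - 1) > 1e-8) {
    stop_texdiv("co-occurrence matrix must be normalised to sum 1",
                class = "texdiv_validation_error")
  }
  ng <- nrow(g)
  lev <- seq_len(ng) - 1
  I <- matrix(lev, ng, ng)
  J <- t(I)
  pos <- g > 0
  entropy <- -sum(g[pos] * log(g[pos]))
  second_moment <- sum(g^2)
  contrast <- sum((I - J)^2 * g)
  dissimilarity <- sum(abs(I - J) * g)
  homogeneity <- sum(g / (1 + (I - J)^2))
  p_i <- rowSums(g)
  mu <- sum(lev * p_i)
  sigma2 <- sum((lev - mu)^2 * p_i)
  correlation <- if (sigma2 > 0) sum((I - mu) * (J - mu) * g) / sigma2 else NA_real_
  c(entropy = entropy, second_moment = second_moment, contrast = contrast,
    correlation = correlation, variance = sigma2, homogeneity = homogeneity,
    mean = mu, dissimilarity = dissimilarity)
}

#' Moving-window GLCM texture stack
#'
#' For every woody center pixel, each requested odd window size and each
#' spectral band, builds the symmetric four-direction co-occurrence matrix of
#' the window (pixels that are non-woody, nodata, or outside the raster are
#' invalid and excluded from pairing) and computes the eight Haralick
#' statistics. Centers with fewer than `min_pairs` contributing pairs, and
#' all non-woody centers, are `NA`.
#'
#' @param scn A [scene()].
#' @param mask Logical matrix (e.g. `build_woody_mask(...)$mask`) restricting
#'   both centers and pairable pixels; a `woody_mask` object is also accepted.
#' @param ng Gray levels for quantization (global per-band range).
#' @param window_sizes Odd window edge lengths; default `c(3, 5, 7)`.
#' @param min_pairs Minimum unordered pair count for a valid center.
#' @param bands Band subset; default all.
#' @return Object of class `texture_stack`: nested list
#'   `values[[band]][[paste0("w", size)]]` of 8-statistic arrays
#'   (`dim = c(nrow, ncol, 8)`), plus geometry metadata.
#' @export
texture_stack <- function(scn, mask, ng = 64L, window_sizes = c(3L, 5L, 7L),
                          min_pairs = 4L, bands = NULL) {
  stopifnot(inherits(scn, "texdiv_scene"))
  if (inherits(mask, "woody_mask")) mask <- mask$mask
  if (!is.logical(mask) || !identical(dim(mask), dim(scn))) {
    stop_texdiv("'mask' must be a logical matrix aligned to the scene",
                class = "texdiv_parameter_error")
  }
  if (any(window_sizes %% 2 == 0) || any(window_sizes < 3)) {
    stop_texdiv("window sizes must be odd and >= 3",
                class = "texdiv_parameter_error")
  }
  if (!any(mask)) warning("empty woody mask: texture stack contains no valid centers")
  if (is.null(bands)) bands <- names(scn$bands)
  valid <- mask & !scn$nodata_mask
  values <- vector("list", length(bands))
  names(values) <- bands
  for (b in bands) {
    lev <- quantize(scn$bands[[b]], ng = ng)
    lev[!valid] <- NA_integer_
    per_win <- vector("list", length(window_sizes))
    names(per_win) <- paste0("w", window_sizes)
    for (w in seq_along(window_sizes)) {
      arr <- glcm_window_stack(lev, valid, as.integer(window_sizes[w]),
                               as.integer(ng), as.integer(min_pairs))
      dimnames(arr) <- list(NULL, NULL, GLCM_STATS)
      per_win[[w]] <- arr
    }
    values[[b]] <- per_win
  }
  structure(list(values = values, window_sizes = as.integer(window_sizes),
                 statistics = GLCM_STATS, ng = as.integer(ng),
                 min_pairs = as.integer(min_pairs),
                 pixel_size = scn$pixel_size, origin = scn$origin),
            class = "texture_stack")
}

#' @export
print.texture_stack <- function(x, ...) {
  cat(sprintf("texture_stack: %d bands x %d statistics x windows {%s}, Ng=%d\n",
              length(x$values), length(x$statistics),
              paste(x$window_sizes, collapse = ","), x$ng))
  invisible(x)
}
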