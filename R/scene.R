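#' Multi-band reflectance scene
#'
#' A `texdiv_scene` holds co-registered reflectance bands as numeric matrices
#' (rows = image rows, north at row 1), an affine pixel-to-world transform
#' (upper-left corner origin, square pixels), and a nodata mask. Reflectance
#' is unitless surface reflectance in \[0, 1\].
#'
#' @param bands Named list of equal-dimension numeric matrices.
#' @param pixel_size Pixel edge length in metres.
#' @param origin Numeric length-2, world coordinates (x, y) of the upper-left
#'   corner of pixel \[1, 1\]; y increases northward.
#' @param nodata_mask Logical matrix, `TRUE` where data are missing; defaults
#'   to all `FALSE`.
#' @param latent Optional list of generator ground-truth layers (kept for
#'   validation against synthetic scenes; `NULL` for real imagery).
#' @return An object of class `texdiv_scene`.
#' @export
scene <- function(bands, pixel_size = 0.5, origin = c(0, 0),
                  nodata_mask = NULL, latent = NULL) {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands))) {
    stop_texdiv("'bands' must be a non-empty named list of matrices",
                class = "texdiv_parameter_error")
  }
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_texdiv("all bands must share the same dimensions",
                class = "texdiv_parameter_error")
  }
  if (pixel_size <= 0) {
    stop_texdiv("'pixel_size' must be positive", class = "texdiv_parameter_error")
  }
  nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]])
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nr, nc)
  structure(
    list(bands = bands, pixel_size = pixel_size, origin = as.numeric(origin),
         nodata_mask = nodata_mask, latent = latent),
    class = "texdiv_scene"
  )
}

#' @export
print.texdiv_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("texdiv_scene: %d x %d px, %d bands (%s), %.2g m/px\n",
              d[1], d[2], length(x$bands),
              paste(names(x$bands), collapse = ", "), x$pixel_size))
  invisible(x)
}

#' @export
dim.texdiv_scene <- function(x) dim(x$bands[[1]])

#' Pixel-center world coordinates
#'
#' Returns the world x (easting) of each column and world y (northing) of
#' each row at pixel centers, consistent with the scene's affine transform.
#'
#' @param scn A `texdiv_scene`.
#' @return List with numeric vectors `x` (per column) and `y` (per row).
#' @export
pixel_centers <- function(scn) {
  d <- dim(scn)
  list(
    x = scn$origin[1] + (seq_len(d[2]) - 0.5) * scn$pixel_size,
    y = scn$origin[2] - (seq_len(d[1]) - 0.5) * scn$pixel_size
  )
}

#' Write / read a scene as multi-sample float TIFF plus JSON sidecar
#'
#' The raster payload is stored as a 32-bit float multi-sample TIFF; the
#' georeferencing (pixel size, origin, band order) travels in a JSON sidecar
#' `<path>.json` so the pair round-trips losslessly without a GeoTIFF driver.
#' Values must lie in \[0, 1\] (reflectance); the nodata mask is stored as an
#' extra final sample.
#'
#' @param scn A `texdiv_scene`.
#' @param path Output TIFF path.
#' @return `write_scene` returns `path` invisibly; `read_scene` a
#'   `texdiv_scene`.
#' @export
write_scene <- function(scn, path) {
  pages <- c(unname(scn$bands), list(scn$nodata_mask * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size = scn$pixel_size, origin = scn$origin,
               bands = names(scn$bands), nodata_page = length(scn$bands) + 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bands <- pages[seq_along(meta$bands)]
  names(bands) <- meta$bands
  scene(bands, pixel_size = meta$pixel_size, origin = meta$origin,
        nodata_mask = pages[[meta$nodata_page]] > 0.5)
}

#' Write / read a single-band grid (mask, segment ids, texture plane)
#'
#' Integer or logical grids are stored as float TIFF with a JSON sidecar
#' recording the grid kind and transform.
#'
#' @param grid Numeric/integer/logical matrix.
#' @param path Output TIFF path.
#' @param pixel_size,origin Georeferencing, as in [scene()].
#' @param kind Free-text label stored in the sidecar.
#' @return `write_grid` returns `path` invisibly; `read_grid` a matrix with
#'   attributes `pixel_size`, `origin`, `kind`.
#' @export
write_grid <- function(grid, path, pixel_size = 0.5, origin = c(0, 0),
                       kind = "grid") {
  g <- grid * 1
  ok <- is.finite(g)
  lo <- if (any(ok)) min(g[ok]) else 0
  hi <- if (any(ok)) max(g[ok]) else 0
  span <- if (hi > lo) hi - lo else 1
  enc <- (g - lo) / span        # TIFF payload constrained to [0, 1]
  enc[!ok] <- 0
  tiff::writeTIFF(list(enc, ok * 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size = pixel_size, origin = origin,
                            kind = kind, offset = lo, scale = span),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  g <- pages[[1]] * meta$scale + meta$offset
  g[pages[[2]] < 0.5] <- NA_real_
  attr(g, "pixel_size") <- meta$pixel_size
  attr(g, "origin") <- meta$origin
  attr(g, "kind") <- meta$kind
  g
}
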