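# Synthetic savanna scene simulator.
#
# Emulates the structure the analysis assumes: patchy woody cover over a
# bare/dry-grass background, seven co-registered reflectance bands with a
# clear NIR2-vs-Red contrast between classes, and within-canopy texture whose
# local roughness varies with a smooth latent diversity surface. All
# randomness flows from one integer seed.

#' Parameters of the synthetic scene generator
#'
#' Defaults emulate a dry-season savanna viewed by a 7-band, 0.5 m
#' pan-sharpened multispectral sensor. `texture_coupling` links each band's
#' within-canopy noise amplitude (roughness) to the latent diversity surface:
#' roughness = `base_roughness` + `texture_coupling` x normalised diversity.
#' By default the Yellow, Red and NIR2 bands are coupled, so dispersion-type
#' texture statistics of those bands carry the diversity signal.
#'
#' @param width_px,height_px Scene dimensions in pixels.
#' @param pixel_size_m Pixel edge length, metres.
#' @param woody_fraction Fraction of pixels that are woody canopy, in (0, 1).
#' @param patch_scale_px Gaussian correlation length of the woody patch
#'   field, pixels.
#' @param diversity_scale_px Correlation length of the latent diversity
#'   surface, pixels.
#' @param diversity_range Range the latent Shannon-scale surface is rescaled
#'   to (nats).
#' @param texture_coupling Named or unnamed length-7 numeric, per-band
#'   roughness gain per unit normalised diversity (reflectance units).
#' @param base_roughness Per-band baseline canopy roughness (recycled to 7).
#' @param noise_sd Additive sensor noise s.d. applied to every pixel.
#' @param seed Integer seed; every stochastic layer derives from it.
#' @return List of class `scene_params`.
#' @export
scene_params <- function(width_px = 512L, height_px = 512L,
                         pixel_size_m = 0.5, woody_fraction = 0.4,
                         patch_scale_px = 12, diversity_scale_px = 48,
                         diversity_range = c(0.15, 2.2),
                         texture_coupling = c(Blue = 0, Green = 0,
                                              Yellow = 0.02, Red = 0.02,
                                              RedEdge = 0, NIR1 = 0,
                                              NIR2 = 0.02),
                         base_roughness = 0.01,
                         noise_sd = 0.004, seed = 1L) {
  if (width_px < 8 || height_px < 8) {
    stop_texdiv("scene dimensions must be at least 8x8 px",
                class = "texdiv_parameter_error")
  }
  if (woody_fraction <= 0 || woody_fraction >= 1) {
    stop_texdiv("'woody_fraction' must lie strictly inside (0, 1)",
                class = "texdiv_parameter_error")
  }
  if (pixel_size_m <= 0 || patch_scale_px <= 0 || noise_sd < 0) {
    stop_texdiv("invalid scale or noise parameter",
                class = "texdiv_parameter_error")
  }
  tc <- rep_len(as.numeric(texture_coupling), 7L)
  names(tc) <- WV2_BANDS
  if (!is.null(names(texture_coupling))) {
    tc[] <- 0
    tc[names(texture_coupling)] <- as.numeric(texture_coupling)
  }
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_m = pixel_size_m, woody_fraction = woody_fraction,
    patch_scale_px = patch_scale_px, diversity_scale_px = diversity_scale_px,
    diversity_range = diversity_range, texture_coupling = tc,
    base_roughness = stats::setNames(rep_len(base_roughness, 7L), WV2_BANDS),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scene_params")
}

# Dry-season class spectra (surface reflectance). Canopy keeps the strong
# NIR2 plateau; background (senescent grass / bare soil) has raised
# visible/red reflectance, giving low NIR2-vs-Red contrast.
WOODY_MEAN <- c(Blue = 0.06, Green = 0.09, Yellow = 0.10, Red = 0.08,
                RedEdge = 0.22, NIR1 = 0.35, NIR2 = 0.40)
BG_MEAN    <- c(Blue = 0.10, Green = 0.14, Yellow = 0.18, Red = 0.20,
                RedEdge = 0.24, NIR1 = 0.26, NIR2 = 0.28)

# Smooth Gaussian random field: white noise convolved with a Gaussian kernel
# via FFT (circular), standardised to zero mean / unit sd.
gaussian_field <- function(nr, nc, scale_px) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-dr^2 / (2 * scale_px^2)), exp(-dc^2 / (2 * scale_px^2)))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k / sum(k)), inverse = TRUE)) /
    (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

rescale01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Generate a synthetic savanna scene
#'
#' Builds the seven reflectance bands from (1) a smoothed, quantile-
#' thresholded random field defining woody patches at exactly the requested
#' cover fraction, (2) a latent diversity surface on the Shannon scale, and
#' (3) per-band canopy texture: reflectance = class mean + smooth per-band
#' patch modulation + roughness x white noise + sensor noise, where
#' roughness is an affine function of a latent component (see
#' [scene_params()]). Deterministic given `params$seed`.
#'
#' Each band with non-zero `texture_coupling` is tied to its *own*
#' independent smooth component field; the diversity surface combines these
#' observable components (80% of its variance) with one additional component
#' that no band expresses (20%). Two consequences mirror field conditions:
#' recovering the diversity surface from texture requires *all* coupled
#' bands (the designated subset is identifiable), and even a perfect texture
#' model cannot explain all diversity variance, as in real surveys where
#' canopy texture is only a partial proxy for floristic diversity.
#'
#' Ground-truth layers are attached in `$latent`: `woody` (logical),
#' `diversity` (latent Shannon surface), per-band `roughness` grids, and the
#' component fields.
#'
#' @param params A [scene_params()] object.
#' @return A [scene()] with `$latent` populated.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$height_px; nc <- params$width_px
  with_seed(params$seed, {
    patch_f <- gaussian_field(nr, nc, params$patch_scale_px)
    woody <- patch_f >= stats::quantile(patch_f, 1 - params$woody_fraction)

    coupled <- names(which(params$texture_coupling != 0))
    components <- lapply(coupled, function(b)
      gaussian_field(nr, nc, params$diversity_scale_px))
    names(components) <- coupled
    # unobservable diversity component no band expresses, so texture can
    # never explain all diversity variance (as in real surveys, where canopy
    # texture is only a partial proxy for floristic diversity)
    hidden <- gaussian_field(nr, nc, params$diversity_scale_px)
    obs_share <- if (length(coupled) > 0) 0.8 else 0
    div_raw <- if (length(coupled) > 0) {
      obs <- Reduce(`+`, components) / length(components)
      obs <- obs / stats::sd(obs)
      sqrt(obs_share) * obs + sqrt(1 - obs_share) * hidden
    } else {
      hidden
    }
    dr <- params$diversity_range
    diversity <- dr[1] + rescale01(div_raw) * (dr[2] - dr[1])

    bands <- vector("list", 7L)
    names(bands) <- WV2_BANDS
    roughness <- vector("list", 7L)
    names(roughness) <- WV2_BANDS
    for (b in WV2_BANDS) {
      mod <- gaussian_field(nr, nc, params$patch_scale_px) # per-band patch modulation
      drive <- if (b %in% coupled) rescale01(components[[b]]) else 0
      rough <- params$base_roughness[[b]] + params$texture_coupling[[b]] * drive
      base <- ifelse(woody,
                     WOODY_MEAN[[b]] + 0.02 * mod,
                     BG_MEAN[[b]] + 0.015 * mod)
      tex <- matrix(stats::rnorm(nr * nc), nr, nc)
      v <- base + ifelse(woody, rough, 0.003) * tex
      if (params$noise_sd > 0) {
        v <- v + stats::rnorm(nr * nc, sd = params$noise_sd)
      }
      bands[[b]] <- pmin(pmax(v, 0), 1)
      roughness[[b]] <- ifelse(woody, rough, 0)
    }
    scene(bands, pixel_size = params$pixel_size_m, origin = c(0, nr * params$pixel_size_m),
          latent = list(woody = woody, diversity = diversity,
                        roughness = roughness, components = components,
                        params = params))
  })
}

#' Plot sampling design
#'
#' Survey design: a regular grid of candidate plot centers at `spacing_m`
#' intervals, circular plots of `radius_m`. Candidates whose disc contains no
#' woody pixel can be dropped, mirroring field protocols that skip points
#' without woody plants in their vicinity.
#'
#' @param n_points Maximum number of candidate points (grid truncated to this).
#' @param spacing_m Grid spacing, metres.
#' @param radius_m Plot radius, metres.
#' @param drop_empty Drop plots with zero woody pixels in the disc?
#' @return List of class `plot_design`.
#' @export
plot_design <- function(n_points = 240L, spacing_m = 170, radius_m = 20,
                        drop_empty = TRUE) {
  if (radius_m <= 0 || spacing_m <= 0) {
    stop_texdiv("'radius_m' and 'spacing_m' must be positive",
                class = "texdiv_parameter_error")
  }
  structure(list(n_points = as.integer(n_points), spacing_m = spacing_m,
                 radius_m = radius_m, drop_empty = isTRUE(drop_empty)),
            class = "plot_design")
}

#' Lay out survey plots over a scene
#'
#' Generates the regular grid of candidate centers clipped so every disc lies
#' inside the scene extent, counts woody pixels (from the scene's ground
#' truth when present, otherwise from a supplied mask) inside each disc, and
#' optionally drops empty plots.
#'
#' @param design A [plot_design()].
#' @param scn A [scene()].
#' @param woody Optional logical matrix overriding the truth layer.
#' @return Data frame: `plot_id`, `x`, `y` (world metres), `radius_m`,
#'   `n_woody_px`, plus attribute `n_candidates`.
#' @export
generate_plots <- function(design, scn, woody = NULL) {
  stopifnot(inherits(design, "plot_design"), inherits(scn, "texdiv_scene"))
  if (is.null(woody)) woody <- scn$latent$woody
  if (is.null(woody)) {
    stop_texdiv("no woody layer: supply 'woody' or use a synthetic scene",
                class = "texdiv_parameter_error")
  }
  d <- dim(scn)
  ext_x <- d[2] * scn$pixel_size; ext_y <- d[1] * scn$pixel_size
  r <- design$radius_m; s <- design$spacing_m
  if (2 * r >= ext_x || 2 * r >= ext_y || s > max(ext_x, ext_y)) {
    if (ext_x < s && ext_y < s) {
      stop_texdiv("plot spacing exceeds scene extent",
                  class = "texdiv_empty_design_error")
    }
  }
  xs <- seq(scn$origin[1] + r, scn$origin[1] + ext_x - r, by = s)
  ys <- seq(scn$origin[2] - r, scn$origin[2] - ext_y + r, by = -s)
  if (length(xs) == 0L || length(ys) == 0L) {
    stop_texdiv("no plot fits inside the scene extent",
                class = "texdiv_empty_design_error")
  }
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > design$n_points) grid <- grid[seq_len(design$n_points), ]

  cc <- pixel_centers(scn)
  n_woody <- vapply(seq_len(nrow(grid)), function(i) {
    idx <- disc_pixel_index(cc, grid$x[i], grid$y[i], r)
    sum(woody[idx])
  }, numeric(1))
  plots <- data.frame(
    plot_id = sprintf("P%03d", seq_len(nrow(grid))),
    x = grid$x, y = grid$y, radius_m = r, n_woody_px = n_woody,
    stringsAsFactors = FALSE
  )
  n_cand <- nrow(plots)
  if (design$drop_empty) plots <- plots[plots$n_woody_px > 0, ]
  rownames(plots) <- NULL
  attr(plots, "n_candidates") <- n_cand
  plots
}

# matrix index of pixel centers within Euclidean distance <= r of (x0, y0)
disc_pixel_index <- function(centers, x0, y0, r) {
  jx <- which(abs(centers$x - x0) <= r)
  iy <- which(abs(centers$y - y0) <= r)
  if (length(jx) == 0L || length(iy) == 0L) {
    return(matrix(integer(), 0, 2))
  }
  g <- expand.grid(i = iy, j = jx, KEEP.OUT.ATTRS = FALSE)
  keep <- (centers$x[g$j] - x0)^2 + (centers$y[g$i] - y0)^2 <= r^2
  cbind(g$i[keep], g$j[keep])
}

#' Simulate per-plot species counts coupled to a latent diversity value
#'
#' For each plot, a target Shannon value is the plot-mean latent diversity
#' plus Gaussian noise (`shannon_noise_sd`), truncated to the feasible range.
#' The per-plot community is then drawn from a global pool of `pool_size`
#' species: effective richness `s = ceiling(exp(H))`, geometric rank-
#' abundance profile whose decay is solved so the profile's Shannon index
#' equals the target, and stem counts multinomial with `stems_lambda` mean
#' total stems. Species identities are drawn from the pool with geometric
#' global weights, so the union over plots never exceeds the pool.
#'
#' @param plots Data frame from [generate_plots()].
#' @param latent_diversity Numeric vector of per-plot latent Shannon values
#'   (e.g. plot-mean of the scene's `latent$diversity` layer).
#' @param seed Integer seed.
#' @param pool_size Global species pool size.
#' @param shannon_noise_sd S.d. of the latent-to-target Gaussian noise (nats).
#' @param stems_lambda Poisson mean of total stems per plot (floored at the
#'   plot's effective richness).
#' @return Long-format data frame `plot_id`, `species`, `count` with the
#'   per-plot target values attached as attribute `targets`.
#' @export
generate_species_counts <- function(plots, latent_diversity, seed = 1L,
                                    pool_size = 26L, shannon_noise_sd = 0.21,
                                    stems_lambda = 30) {
  if (nrow(plots) == 0L) {
    return(data.frame(plot_id = character(), species = character(),
                      count = integer()))
  }
  stopifnot(length(latent_diversity) == nrow(plots))
  with_seed(seed, {
    pool <- sprintf("sp%02d", seq_len(pool_size))
    pool_w <- 0.85^(seq_len(pool_size) - 1)  # common vs rare species
    rows <- vector("list", nrow(plots))
    targets <- numeric(nrow(plots))
    for (i in seq_len(nrow(plots))) {
      h <- latent_diversity[i] + stats::rnorm(1, sd = shannon_noise_sd)
      h <- min(max(h, 0), log(pool_size) - 1e-6)
      targets[i] <- h
      s <- if (h < 0.02) 1L else min(pool_size, as.integer(ceiling(exp(h))))
      p <- geometric_profile(s, h)
      n_stems <- max(s, stats::rpois(1, stems_lambda))
      cnt <- as.vector(stats::rmultinom(1, n_stems, p))
      sp <- sample(pool, s, prob = pool_w)
      keep <- cnt > 0
      rows[[i]] <- data.frame(plot_id = plots$plot_id[i], species = sp[keep],
                              count = cnt[keep], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "targets") <- data.frame(plot_id = plots$plot_id,
                                       target_shannon = targets)
    out
  })
}

# geometric rank-abundance profile over s species whose Shannon index equals
# target_h (solved for the decay ratio; r = 1 gives the ln(s) maximum)
geometric_profile <- function(s, target_h) {
  if (s == 1L) return(1)
  target_h <- min(target_h, log(s) - 1e-9)
  ent <- function(r) {
    p <- r^(seq_len(s) - 1); p <- p / sum(p)
    -sum(p * log(p))
  }
  if (target_h <= 0) return(c(1 - 1e-12, rep(1e-12 / (s - 1), s - 1)))
  r <- stats::uniroot(function(r) ent(r) - target_h,
                      lower = 1e-6, upper = 1 - 1e-12, tol = 1e-10)$root
  p <- r^(seq_len(s) - 1)
  p / sum(p)
}

#' Plot-mean of a scene layer within each plot disc
#'
#' Utility used to read the latent diversity surface (or any grid aligned to
#' the scene) at plot level.
#'
#' @param scn A [scene()].
#' @param plots Data frame from [generate_plots()].
#' @param layer Matrix aligned to the scene.
#' @param woody_only Restrict to woody pixels (ground truth) when available.
#' @return Numeric vector, one value per plot row.
#' @export
plot_layer_mean <- function(scn, plots, layer, woody_only = TRUE) {
  cc <- pixel_centers(scn)
  woody <- scn$latent$woody
  vapply(seq_len(nrow(plots)), function(i) {
    idx <- disc_pixel_index(cc, plots$x[i], plots$y[i], plots$radius_m[i])
    if (woody_only && !is.null(woody)) idx <- idx[woody[idx], , drop = FALSE]
    if (nrow(idx) == 0L) return(NA_real_)
    mean(layer[idx])
  }, numeric(1))
}

#' Write plots as GeoJSON / CSV
#'
#' @param plots Plot table from [generate_plots()].
#' @param path Output path (`.geojson` or `.csv` chosen by extension).
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  if (grepl("\\.geojson$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(plots)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(plots$x[i], plots$y[i])),
           properties = list(plot_id = plots$plot_id[i],
                             radius_m = plots$radius_m[i],
                             n_woody_px = plots$n_woody_px[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(plots, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_plots
#' @param path Input path.
#' @export
read_plots <- function(path) {
  if (grepl("\\.geojson$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(gj$features, function(f) {
      data.frame(plot_id = f$properties$plot_id,
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 radius_m = f$properties$radius_m,
                 n_woody_px = f$properties$n_woody_px %||% NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
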