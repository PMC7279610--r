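# Independent oracles, deliberately written with different algorithms than
# the package code paths they check.

# Brute-force double-loop Haralick statistics from a normalised GLCM.
# Elementwise loops over all Ng^2 cells; no vectorisation, no marginals.
oracle_glcm_stats <- function(g) {
  ng <- nrow(g)
  entropy <- 0; second <- 0; contrast <- 0; dissim <- 0; homog <- 0
  mu <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    p <- g[i, j]
    li <- i - 1; lj <- j - 1
    if (p > 0) entropy <- entropy - p * log(p)
    second <- second + p * p
    contrast <- contrast + (li - lj)^2 * p
    dissim <- dissim + abs(li - lj) * p
    homog <- homog + p / (1 + (li - lj)^2)
    mu <- mu + li * p
  }
  sigma2 <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    sigma2 <- sigma2 + (i - 1 - mu)^2 * g[i, j]
  }
  corr_num <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    corr_num <- corr_num + (i - 1 - mu) * (j - 1 - mu) * g[i, j]
  }
  c(entropy = entropy, second_moment = second, contrast = contrast,
    correlation = if (sigma2 > 0) corr_num / sigma2 else NA_real_,
    variance = sigma2, homogeneity = homog, mean = mu,
    dissimilarity = dissim)
}

# Brute-force symmetric co-occurrence counts by explicit offset loops.
oracle_cooccurrence <- function(window, valid = NULL, ng, directions = 1:4) {
  if (is.null(valid)) valid <- !is.na(window)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))[directions]
  g <- matrix(0, ng, ng)
  np <- 0L
  for (o in offs) {
    for (i in seq_len(nrow(window))) for (j in seq_len(ncol(window))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > nrow(window) || j2 < 1 || j2 > ncol(window)) next
      if (!isTRUE(valid[i, j]) || !isTRUE(valid[i2, j2])) next
      if (is.na(window[i, j]) || is.na(window[i2, j2])) next
      a <- window[i, j] + 1L; b <- window[i2, j2] + 1L
      g[a, b] <- g[a, b] + 1
      g[b, a] <- g[b, a] + 1
      np <- np + 1L
    }
  }
  if (np > 0) g <- g / sum(g)
  list(g = g, n_pairs = np)
}

# Independent all-subsets enumerator: utils::combn over predictor sets,
# stats::lm for fitting, stats::AIC for scoring.
oracle_all_subsets <- function(dat, predictors) {
  sets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(sets, function(s) {
    f <- stats::as.formula(paste("shannon ~", paste(s, collapse = "+")))
    stats::AIC(stats::lm(f, data = dat))
  }, numeric(1))
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "+"), character(1))
  data.frame(predictors = keys, k = lengths(sets), aic = aics,
             stringsAsFactors = FALSE)
}

# Normal-equations OLS solver (solve(t(X) X) route, distinct from lm.fit's QR).
oracle_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  res <- y - Xi %*% beta
  list(coefficients = as.numeric(beta), rss = sum(res^2))
}

# Random normalised symmetric GLCM for property tests.
random_sym_glcm <- function(ng) {
  m <- matrix(stats::rexp(ng * ng), ng, ng)
  m <- m + t(m)
  m / sum(m)
}

# Small fully-woody constant scene helper.
constant_scene <- function(n = 24, value = 0.3, pixel_size = 0.5) {
  bands <- lapply(wv2_bands(), function(b) matrix(value, n, n))
  names(bands) <- wv2_bands()
  scene(bands, pixel_size = pixel_size, origin = c(0, n * pixel_size))
}
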