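test_that("quantize bins reflectance linearly with inclusive upper edge", {
  m <- matrix(c(0.2, 0.8), 1, 2)
  q <- quantize(m, ng = 2L, range = c(0, 1))
  expect_equal(as.vector(q), c(0L, 1L))
  q4 <- quantize(matrix(1.0), ng = 4L, range = c(0, 1))
  expect_equal(as.vector(q4), 3L)
  expect_equal(as.vector(quantize(matrix(0.0), ng = 4L, range = c(0, 1))), 0L)
})

test_that("quantize/dequantize error is bounded by half a bin width", {
  ng <- 16L
  vals <- matrix(seq(0, 1, length.out = 1001), 1)
  q <- quantize(vals, ng = ng, range = c(0, 1))
  back <- dequantize(q)
  expect_lte(max(abs(back - vals)), 0.5 / ng + 1e-12)
})

test_that("quantize warns on a degenerate range and maps all to level 0", {
  m <- matrix(0.5, 3, 3)
  expect_warning(q <- quantize(m, ng = 8L), "degenerate")
  expect_true(all(q == 0L))
})

test_that("cooccurrence of a constant window is a single diagonal cell", {
  w <- matrix(2L, 3, 3)
  m <- cooccurrence(w, ng = 4L)
  expect_equal(m$g[3, 3], 1)
  expect_equal(sum(m$g), 1)
  expect_equal(m$n_pairs, 20L)  # 6+6 rook + 4+4 diagonal unordered pairs
})

test_that("cooccurrence matches the spec'd two-pixel-column example at 0 degrees", {
  w <- rbind(c(0L, 1L), c(0L, 1L))
  m <- cooccurrence(w, ng = 2L, directions = 1L)
  expect_equal(m$g[1, 2], 0.5)
  expect_equal(m$g[2, 1], 0.5)
  expect_equal(m$g[1, 1] + m$g[2, 2], 0)
})

test_that("cooccurrence is normalised, symmetric, and matches a brute-force loop", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(3:7, 1)
      ng <- sample(2:6, 1)
      w <- matrix(sample(0:(ng - 1), n * n, replace = TRUE), n, n)
      valid <- matrix(stats::runif(n * n) > 0.2, n, n)
      m <- cooccurrence(w, valid, ng = ng)
      o <- oracle_cooccurrence(w, valid, ng = ng)
      expect_equal(m$g, o$g, tolerance = 1e-14)
      expect_equal(m$n_pairs, o$n_pairs)
      if (m$n_pairs > 0) {
        expect_equal(sum(m$g), 1, tolerance = 1e-12)
        expect_equal(m$g, t(m$g))
      }
    }
  })
})

test_that("glcm_statistics handles the degenerate single-cell matrix", {
  m <- cooccurrence(matrix(3L, 3, 3), ng = 8L)
  s <- glcm_statistics(m)
  expect_equal(unname(s["entropy"]), 0)
  expect_equal(unname(s["second_moment"]), 1)
  expect_equal(unname(s["contrast"]), 0)
  expect_equal(unname(s["dissimilarity"]), 0)
  expect_equal(unname(s["homogeneity"]), 1)
  expect_equal(unname(s["variance"]), 0)
  expect_equal(unname(s["mean"]), 3)
  expect_true(is.na(s["correlation"]))
})

test_that("glcm_statistics of the uniform 2-level matrix hits the entropy maximum", {
  g <- matrix(0.25, 2, 2)
  s <- glcm_statistics(g)
  expect_equal(unname(s["entropy"]), log(4))
  expect_equal(unname(s["second_moment"]), 0.25)
})

test_that("glcm_statistics rejects non-normalised matrices", {
  expect_error(glcm_statistics(matrix(1, 2, 2)),
               class = "texdiv_validation_error")
})

test_that("statistics agree with the elementwise double-loop oracle", {
  withr::with_seed(21, {
    for (i in 1:30) {
      g <- random_sym_glcm(sample(2:6, 1))
      expect_equal(glcm_statistics(g), oracle_glcm_stats(g), tolerance = 1e-12)
    }
  })
})

test_that("texture_stack of a constant fully-woody scene is zero-entropy", {
  scn <- constant_scene(16)
  mask <- matrix(TRUE, 16, 16)
  # constant bands trigger the degenerate-quantization warning by design
  st <- suppressWarnings(texture_stack(scn, mask, ng = 8L, window_sizes = c(3L, 5L)))
  for (w in c("w3", "w5")) {
    ent <- st$values$Red[[w]][, , "entropy"]
    expect_true(all(ent == 0))
    expect_true(all(st$values$Red[[w]][, , "second_moment"] == 1))
  }
})

test_that("an isolated woody pixel yields nodata (no valid pairs)", {
  scn <- constant_scene(9)
  mask <- matrix(FALSE, 9, 9)
  mask[5, 5] <- TRUE
  st <- suppressWarnings(texture_stack(scn, mask, ng = 8L, window_sizes = 3L))
  expect_true(is.na(st$values$Red$w3[5, 5, "entropy"]))
})

test_that("non-woody centers are nodata everywhere", {
  scn <- constant_scene(12)
  mask <- matrix(TRUE, 12, 12)
  mask[, 1:6] <- FALSE
  st <- suppressWarnings(texture_stack(scn, mask, ng = 8L, window_sizes = 3L))
  ent <- st$values$NIR2$w3[, , "entropy"]
  expect_true(all(is.na(ent[, 1:6])))
  expect_false(anyNA(ent[3:10, 8:11]))
})

test_that("moving-window statistics match per-center recomputation on textured data", {
  withr::with_seed(31, {
    n <- 20; ng <- 8L
    band <- matrix(stats::runif(n * n), n, n)
    bands <- lapply(wv2_bands(), function(b) band)
    names(bands) <- wv2_bands()
    scn <- scene(bands, pixel_size = 0.5, origin = c(0, n * 0.5))
    mask <- matrix(stats::runif(n * n) > 0.25, n, n)
    st <- texture_stack(scn, mask, ng = ng, window_sizes = 5L, min_pairs = 4L)
    lev <- quantize(band, ng = ng)
    lev[!mask] <- NA_integer_
    centers <- which(mask, arr.ind = TRUE)
    centers <- centers[sample(nrow(centers), 10), , drop = FALSE]
    for (ci in seq_len(nrow(centers))) {
      i <- centers[ci, 1]; j <- centers[ci, 2]
      ri <- max(1, i - 2):min(n, i + 2)
      rj <- max(1, j - 2):min(n, j + 2)
      m <- cooccurrence(lev[ri, rj, drop = FALSE], mask[ri, rj, drop = FALSE],
                        ng = ng)
      ref <- if (m$n_pairs >= 4L) glcm_statistics(m) else
        stats::setNames(rep(NA_real_, 8), glcm_stat_names())
      got <- st$values$Blue$w5[i, j, ]
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("statistic ranges hold on random textured stacks", {
  withr::with_seed(41, {
    n <- 24; ng <- 16L
    band <- matrix(stats::runif(n * n), n, n)
    bands <- lapply(wv2_bands(), function(b)
      pmin(pmax(band + stats::rnorm(n * n, sd = 0.05), 0), 1))
    names(bands) <- wv2_bands()
    scn <- scene(bands, pixel_size = 0.5, origin = c(0, n * 0.5))
    st <- texture_stack(scn, matrix(TRUE, n, n), ng = ng,
                        window_sizes = c(3L, 5L, 7L))
    for (b in c("Blue", "NIR2")) for (w in c("w3", "w5", "w7")) {
      a <- st$values[[b]][[w]]
      ent <- a[, , "entropy"]; sm <- a[, , "second_moment"]
      hom <- a[, , "homogeneity"]; con <- a[, , "contrast"]
      va <- a[, , "variance"]; co <- a[, , "correlation"]
      expect_true(all(ent >= 0 & ent <= log(as.numeric(ng)^2), na.rm = TRUE))
      expect_true(all(sm >= 1 / ng^2 & sm <= 1, na.rm = TRUE))
      expect_true(all(hom > 0 & hom <= 1, na.rm = TRUE))
      expect_true(all(con >= 0 & va >= 0, na.rm = TRUE))
      expect_true(all(co >= -1 - 1e-9 & co <= 1 + 1e-9, na.rm = TRUE))
    }
    # window sizes measure related but distinct texture
    e3 <- st$values$Blue$w3[, , "entropy"]
    e5 <- st$values$Blue$w5[, , "entropy"]
    ok <- !is.na(e3) & !is.na(e5)
    expect_lt(stats::cor(e3[ok], e5[ok]), 1)
    expect_gt(stats::cor(e3[ok], e5[ok]), 0)
  })
})

test_that("within-window shuffling does not decrease expected entropy", {
  withr::with_seed(51, {
    # smooth gradient window: highly ordered pair structure
    w <- matrix(rep(0:6, each = 7), 7, 7)
    base <- glcm_statistics(cooccurrence(w, ng = 7L))["entropy"]
    sh <- replicate(60, {
      ws <- matrix(sample(as.vector(w)), 7, 7)
      glcm_statistics(cooccurrence(ws, ng = 7L))["entropy"]
    })
    expect_gte(mean(sh), base)
  })
})
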