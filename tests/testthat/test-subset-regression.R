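test_that("fit_ols recovers a noise-free line exactly", {
  x <- 1:10
  y <- 2 * x + 1
  f <- fit_ols(matrix(x, ncol = 1), y)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)
})

test_that("fit_ols gives zero slope when y is orthogonal to centered x", {
  x <- c(-1, 0, 1)
  y <- c(1, -2, 1)  # sum(x * y) = 0, mean-centered x
  f <- fit_ols(matrix(x, ncol = 1), y)
  expect_equal(unname(f$coefficients[2]), 0, tolerance = 1e-12)
  expect_equal(f$rss, sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("fit_ols matches a normal-equations solver on random designs", {
  withr::with_seed(3, {
    for (i in 1:10) {
      X <- matrix(stats::rnorm(30 * 3), 30, 3)
      y <- stats::rnorm(30)
      f <- fit_ols(X, y)
      o <- oracle_ols(X, y)
      expect_equal(unname(f$coefficients), o$coefficients, tolerance = 1e-8)
      expect_equal(f$rss, o$rss, tolerance = 1e-8)
    }
  })
})

test_that("fit_ols flags rank-deficient designs as degenerate", {
  X <- cbind(1:10, 2 * (1:10))
  f <- fit_ols(X, stats::rnorm(10))
  expect_true(f$degenerate)
})

test_that("aic_gaussian follows the closed form and its monotonicities", {
  expect_equal(aic_gaussian(10, 50, 2), 69.4219576988, tolerance = 1e-9)
  # monotone in rss at fixed k
  expect_lt(aic_gaussian(5, 100, 3), aic_gaussian(6, 100, 3))
  # penalty arithmetic: +1 predictor at equal rss costs exactly 2
  expect_equal(aic_gaussian(7, 100, 3) - aic_gaussian(7, 100, 2), 2)
  expect_warning(v <- aic_gaussian(0, 10, 1), "perfect fit")
  expect_identical(v, -Inf)
})

test_that("aic_gaussian equals stats::AIC on fitted linear models", {
  withr::with_seed(8, {
    for (k in 1:3) {
      X <- matrix(stats::rnorm(40 * k), 40, k)
      y <- stats::rnorm(40)
      f <- fit_ols(X, y)
      lmfit <- stats::lm(y ~ X)
      expect_equal(aic_gaussian(f$rss, 40, k), stats::AIC(lmfit),
                   tolerance = 1e-9)
    }
  })
})

test_that("adj_r2 and rmse follow their formulas at the boundary cases", {
  expect_equal(adj_r2(0, 10, 50, 3), 1)
  expect_equal(rmse(0, 50), 0)
  # rss = tss with one predictor: adjusted R2 goes negative
  expect_equal(adj_r2(10, 10, 100, 1), 1 - 99 / 98, tolerance = 1e-12)
  expect_equal(rmse(10, 100), sqrt(0.1))
  expect_error(adj_r2(1, 0, 10, 1), class = "texdiv_validation_error")
})

test_that("all_subsets enumerates exactly 2^p - 1 models", {
  withr::with_seed(10, {
    n <- 40
    X <- matrix(stats::rnorm(n * 7), n, 7)
    colnames(X) <- wv2_bands()
    dat <- data.frame(shannon = stats::rnorm(n), X)
    rep7 <- all_subsets(dat, wv2_bands())
    expect_equal(nrow(rep7$models), 127L)
    expect_equal(sort(unique(rep7$models$k)), 1:7)
    expect_equal(sum(choose(7, 1:7)), 127)
    rep1 <- all_subsets(dat, "Blue")
    expect_equal(nrow(rep1$models), 1L)
    expect_equal(rep1$best_overall, 1L)
  })
})

test_that("best-per-k residual sums are non-increasing in k", {
  withr::with_seed(12, {
    n <- 60
    X <- matrix(stats::rnorm(n * 6), n, 6)
    colnames(X) <- wv2_bands()[1:6]
    dat <- data.frame(shannon = X[, 1] + 0.5 * X[, 3] + stats::rnorm(n), X)
    rep <- all_subsets(dat, colnames(X))
    best_rss <- vapply(rep$best_per_k, function(i) {
      min(rep$models$rss[rep$models$k == rep$models$k[i]])
    }, numeric(1))
    expect_true(all(diff(best_rss) <= 1e-10))
  })
})

test_that("ranking matches the independent lm/AIC enumerator for p <= 4", {
  withr::with_seed(14, {
    for (p in 2:4) {
      n <- 35
      X <- matrix(stats::rnorm(n * p), n, p)
      colnames(X) <- wv2_bands()[seq_len(p)]
      dat <- data.frame(shannon = X %*% stats::runif(p) + stats::rnorm(n), X)
      rep <- all_subsets(dat, colnames(X))
      orc <- oracle_all_subsets(dat, colnames(X))
      expect_equal(nrow(rep$models), nrow(orc))
      m <- merge(rep$models, orc, by = "predictors")
      # identical AIC values model-for-model, hence identical ordering
      expect_equal(m$aic.x, m$aic.y, tolerance = 1e-8)
      best_oracle <- orc$predictors[which.min(orc$aic)]
      expect_equal(rep$models$predictors[rep$best_overall], best_oracle)
    }
  })
})

test_that("AIC ties break deterministically toward smaller simpler models", {
  # duplicated predictor columns create exact AIC ties
  n <- 30
  withr::with_seed(16, {
    x <- stats::rnorm(n)
    dat <- data.frame(shannon = x + stats::rnorm(n, sd = 0.1),
                      Blue = x, Green = x)
    rep <- suppressWarnings(all_subsets(dat, c("Blue", "Green")))
    best <- rep$models[rep$best_overall, ]
    expect_equal(best$k, 1L)
    expect_equal(best$predictors, "Blue")  # lexicographic among k = 1 ties
  })
})

test_that("the generating bands are always part of the selected model", {
  withr::with_seed(20, {
    true_bands <- c("Yellow", "Red", "NIR2")
    hits <- vapply(1:10, function(i) {
      n <- 200
      X <- matrix(stats::rnorm(n * 7), n, 7)
      colnames(X) <- wv2_bands()
      sig <- rowSums(X[, true_bands])
      dat <- data.frame(shannon = sig + stats::rnorm(n, sd = stats::sd(sig)), X)
      rep <- all_subsets(dat, wv2_bands())
      best <- strsplit(rep$models$predictors[rep$best_overall], "+",
                       fixed = TRUE)[[1]]
      all(true_bands %in% best)
    }, logical(1))
    expect_true(all(hits))
  })
})

test_that("groups are fitted per statistic and window with band predictors", {
  withr::with_seed(22, {
    n <- 30
    cols <- list(plot_id = sprintf("P%02d", 1:n), shannon = stats::rnorm(n))
    for (b in wv2_bands()) for (s in c("entropy", "mean")) for (w in c(3, 5)) {
      cols[[paste0(b, "_", s, "_w", w)]] <- stats::rnorm(n)
    }
    f <- as.data.frame(cols)
    class(f) <- c("plot_features", "data.frame")
    reps <- all_subsets_by_group(f)
    expect_equal(length(reps), 4L)  # 2 statistics x 2 windows
    expect_true(all(vapply(reps, function(r) nrow(r$models) == 127L,
                           logical(1))))
    expect_equal(sort(unique(names(reps))),
                 sort(c("entropy_w3", "entropy_w5", "mean_w3", "mean_w5")))
  })
})

test_that("too-small samples are skipped with an error record", {
  withr::with_seed(24, {
    n <- 7  # < p + 2 for p = 7
    cols <- list(plot_id = sprintf("P%02d", 1:n), shannon = stats::rnorm(n))
    for (b in wv2_bands()) cols[[paste0(b, "_entropy_w3")]] <- stats::rnorm(n)
    f <- as.data.frame(cols)
    class(f) <- c("plot_features", "data.frame")
    reps <- all_subsets_by_group(f)
    expect_equal(length(reps), 0L)
    expect_true("entropy_w3" %in% names(attr(reps, "errors")))
  })
})
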