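test_that("normal log-likelihood matches closed forms", {
  expect_equal(loglik_unimodal(c(0, 0, 2, 2), 1, 1), -5.67576, tolerance = 1e-5)
  # pdf peak equals 1 when sigma2 = 1/(2*pi)
  expect_equal(loglik_unimodal(0.3, 0.3, 1 / (2 * pi)), 0)
  x <- rnorm(9)
  expect_equal(loglik_unimodal(c(x, x), 0.2, 1.3),
               2 * loglik_unimodal(x, 0.2, 1.3))
  expect_error(loglik_unimodal(numeric(0), 0, 1), "empty")
  expect_error(loglik_unimodal(x, 0, 0), "positive")
})

test_that("unimodal ML fit uses divisor-n variance", {
  f <- fit_unimodal(c(0, 0, 2, 2))
  expect_equal(f$mu, 1)
  expect_equal(f$sigma2, 1)
  expect_equal(f$logLik, -5.67576, tolerance = 1e-5)
  expect_equal(f$k, 2L)
  expect_equal(f$sd_unbiased, sd(c(0, 0, 2, 2)))
  expect_error(fit_unimodal(rep(2, 5)), "degenerate")
  expect_error(fit_unimodal(c(1, 2)), "at least 3")
})

test_that("AICc formula, including the small-sample infinity", {
  expect_equal(compute_aicc(0, 2, 100), 4 + 12 / 97)
  # five parameters on six specimens cannot be corrected
  expect_equal(compute_aicc(16.1, 5, 6), Inf)
  # arithmetic of the published fibula tc-to-dc row
  aicc_bi <- compute_aicc(21.1, 5, 8)
  aicc_uni <- compute_aicc(18.3, 2, 8)
  expect_equal(aicc_bi, -2.2)
  expect_equal(aicc_uni, -30.2)
  expect_equal(aicc_bi - aicc_uni, 28.0)
})

test_that("Akaike weights normalize and handle infinities", {
  w <- akaike_weights(c(2.44, 0))
  expect_equal(round(w$weights, 2), c(0.23, 0.77))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_equal(min(w$daicc), 0)
  expect_equal(akaike_weights(c(5, 5))$weights, c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, Inf))$weights, c(1, 0))
})

test_that("mixture EM recovers generating parameters at n = 400", {
  p <- jcp_dv_published_fit()
  set.seed(42)
  x <- rmix(400, p$a, p$mu1, p$sd1, p$mu2, p$sd2)
  fit <- fit_bimodal(x, seed = 7)
  expect_lt(abs(fit$mu1 - p$mu1), 0.01)
  expect_lt(abs(fit$mu2 - p$mu2), 0.01)
  expect_lt(abs(fit$a - p$a), 0.07)
  expect_lt(abs(fit$sd1 - p$sd1) / p$sd1, 0.2)
  expect_lt(abs(fit$sd2 - p$sd2) / p$sd2, 0.2)
  expect_equal(fit$k, 5L)
})

test_that("mixture fit never falls below the nested unimodal fit", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(6:40, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                rmix(n, 0.5, -1, 0.5, 1, 0.5),
                exp(rnorm(n)))
    uni <- fit_unimodal(x)
    bi <- suppressWarnings(fit_bimodal(x, seed = i, n_restarts = 5))
    expect_gte(bi$logLik, uni$logLik - 1e-6)
    expect_lte(bi$mu1, bi$mu2)
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(8)
  x <- rmix(30, 0.4, 0, 0.3, 2, 0.5)
  fit <- fit_bimodal(x, seed = 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("comparison is shift-equivariant", {
  set.seed(12)
  x <- rmix(24, 0.5, 2.1, 0.05, 2.4, 0.07)
  c0 <- compare_models(x, seed = 4)
  c1 <- compare_models(x + 3, seed = 4)
  expect_equal(c1$uni$mu, c0$uni$mu + 3, tolerance = 1e-8)
  expect_equal(c1$bi$mu1, c0$bi$mu1 + 3, tolerance = 1e-6)
  expect_equal(c1$bi$mu2, c0$bi$mu2 + 3, tolerance = 1e-6)
  expect_equal(c1$bi$logLik, c0$bi$logLik, tolerance = 1e-6)
  expect_equal(c1$daicc_uni, c0$daicc_uni, tolerance = 1e-6)
  expect_equal(c1$w_bi, c0$w_bi, tolerance = 1e-6)
})

test_that("optimizer matches a dense grid-search oracle on small vectors", {
  set.seed(77)
  cases <- list(
    rmix(10, 0.5, 0, 0.4, 2, 0.4),
    rnorm(12),
    rmix(9, 0.3, 1, 0.2, 1.8, 0.5)
  )
  for (x in cases) {
    floor_sd <- max(1e-4, 0.05 * sd(x))
    fit <- suppressWarnings(fit_bimodal(x, seed = 2, sd_floor = floor_sd))
    oracle <- grid_best_loglik(x, floor_sd)
    expect_gte(fit$logLik, oracle - 1e-3)
  }
})

test_that("EM log-likelihood agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(99)
  x <- rmix(120, 0.5, 2.1, 0.05, 2.45, 0.08)
  fit <- fit_bimodal(x, seed = 5)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$logLik, mc$loglik, tolerance = 1e-4)
})

test_that("compare_models reports weights that sum to one and one zero delta", {
  set.seed(21)
  x <- rnorm(20, 2, 0.1)
  cmp <- compare_models(x, seed = 1)
  expect_equal(cmp$w_uni + cmp$w_bi, 1, tolerance = 1e-12)
  expect_equal(min(cmp$daicc_uni, cmp$daicc_bi), 0)
})
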