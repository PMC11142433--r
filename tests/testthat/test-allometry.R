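test_that("OLS summary matches closed forms on an exact line", {
  x <- 1:5
  f <- suppressWarnings(fit_line(x, 2 * x + 1))  # lm warns on exact fits
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2_raw, 1)
  expect_equal(f$r2_adjusted, 1)
  expect_error(fit_line(rep(1, 4), rnorm(4)), "zero variance")
  expect_error(fit_line(1:2, 1:2), "at least 3")
})

test_that("adjusted R2 follows 1 - (1 - R2)(n-1)/(n-2) and can be negative", {
  set.seed(10)
  x <- rnorm(9)
  y <- rnorm(9)  # unrelated: adjusted R2 typically negative
  f <- fit_line(x, y)
  expect_equal(f$r2_adjusted,
               1 - (1 - f$r2_raw) * (f$n - 1) / (f$n - 2), tolerance = 1e-12)
  expect_lte(f$r2_adjusted, f$r2_raw)
  set.seed(14)
  negs <- replicate(20, fit_line(rnorm(7), rnorm(7))$r2_adjusted)
  expect_true(any(negs < 0))  # returned unclamped
})

test_that("r2 and p are invariant under affine transforms of x and y", {
  set.seed(11)
  x <- rnorm(12); y <- 0.8 * x + rnorm(12, sd = 0.5)
  f0 <- fit_line(x, y)
  f1 <- fit_line(3 * x - 2, -0.5 * y + 7)
  expect_equal(f1$r2_raw, f0$r2_raw, tolerance = 1e-12)
  expect_equal(f1$r2_adjusted, f0$r2_adjusted, tolerance = 1e-12)
  expect_equal(f1$p_value, f0$p_value, tolerance = 1e-10)
})

test_that("slope p-value agrees with the cor.test oracle", {
  set.seed(12)
  x <- rnorm(10); y <- x + rnorm(10)
  expect_equal(fit_line(x, y)$p_value, cor.test(x, y)$p.value,
               tolerance = 1e-10)
})

test_that("log-scale CV matches the published component arithmetic", {
  expect_equal(cv_log(mu = 2, sd = 0.2)$cv, 0.1)
  expect_equal(cv_log(x = rep(1.5, 5))$cv, 0)
  expect_error(cv_log(mu = -2, sd = 0.2), "non-positive")
  p <- jcp_dv_published_fit()
  cv_small <- cv_log(mu = p$mu1, sd = p$sd1)$cv
  cv_large <- cv_log(mu = p$mu2, sd = p$sd2)$cv
  expect_lt(abs(cv_small - 0.0159), 0.0005)
  expect_lt(abs(cv_large - 0.0274), 0.0005)
  # the large morph is about 1.7 times as variable even after size
  expect_equal(cv_large / cv_small, 1.7, tolerance = 0.05)
  # scale caveat: multiplying mm by 10 shifts the log10 mean and the CV
  expect_false(isTRUE(all.equal(cv_log(mu = p$mu1 + 1, sd = p$sd1)$cv,
                                cv_small)))
})

test_that("per-morph associations split complete pairs by label", {
  cfg <- synthetic_config(seed = 40L)
  tab <- generate_population(cfg)
  truth <- true_morphs(tab)
  morphs <- tibble::tibble(specimen_id = truth$specimen_id,
                           label = truth$morph)
  res <- group_associations(tab, "maxilla", "jcp_DV", "ttc", morphs)
  expect_equal(res$group, c("small", "large", "pooled"))
  expect_true(all(res$available))
  # ttc is allometrically coupled to jcp_DV: strong pooled association
  expect_gt(res$r2_adjusted[res$group == "pooled"], 0.7)
  expect_equal(res$n[res$group == "pooled"],
               res$n[res$group == "small"] + res$n[res$group == "large"])
  # groups below 3 pairs are marked unavailable, not fitted
  few <- morphs
  few$label[few$label == "small"] <- "ambiguous"
  few$label[which(few$label == "large")[-(1:2)]] <- "ambiguous"
  res2 <- group_associations(tab, "maxilla", "jcp_DV", "ttc", few)
  expect_false(res2$available[res2$group == "large"])
  expect_true(is.na(res2$r2_adjusted[res2$group == "large"]))
})

test_that("identical x and y within groups give perfect raw R2", {
  morphs <- tibble::tibble(specimen_id = as.character(1:8),
                           label = rep(c("small", "large"), each = 4))
  df <- data.frame(specimen_id = as.character(1:8), element = "maxilla",
                   side = "left", jcp_DV = c(101:104, 201:204))
  df$ttc <- df$jcp_DV
  tab <- measurement_table(df)
  res <- suppressWarnings(  # lm warns on exact fits
    group_associations(tab, "maxilla", "jcp_DV", "ttc", morphs))
  expect_true(all(abs(res$r2_raw - 1) < 1e-12))
})
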