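test_that("scaled PCA standardizes columns and reports variance fractions", {
  set.seed(1)
  z <- rnorm(30)
  m <- cbind(a = 3 * z + 5, b = -0.2 * z + 100)
  p <- pca_scaled(m)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  # column permutation leaves explained fractions unchanged
  m3 <- cbind(m, c = rnorm(30))
  expect_equal(pca_scaled(m3)$explained,
               pca_scaled(m3[, c(2, 3, 1)])$explained, tolerance = 1e-10)
  # per-column affine rescaling is absorbed by standardization
  m3b <- m3
  m3b[, 1] <- m3b[, 1] * 7 + 2
  m3b[, 3] <- m3b[, 3] * 0.01 - 90
  expect_equal(pca_scaled(m3b)$explained, pca_scaled(m3)$explained,
               tolerance = 1e-8)
  # components orthonormal
  rot <- pca_scaled(m3)$loadings
  expect_equal(crossprod(rot), diag(ncol(m3)), tolerance = 1e-10,
               ignore_attr = TRUE)
  m3[, 2] <- 4
  expect_error(pca_scaled(m3), "zero-variance")
})

test_that("two-group k-means separates well-separated blobs, reproducibly", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(40, 5, 0.2), ncol = 2))
  blob <- rep(1:2, each = 20)
  cl <- kmeans_two(pts, seed = 9)
  expect_equal(concordance(cl$labels, blob), 1.0)
  cl2 <- kmeans_two(pts, seed = 9)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$centers, cl2$centers)
  expect_error(kmeans_two(matrix(1, 4, 2)), "distinct")
})

test_that("concordance is permutation-maximal and at least one half", {
  lab <- rep(c("x", "y"), 10)
  expect_equal(concordance(lab, lab), 1.0)
  inv <- ifelse(lab == "x", "y", "x")
  expect_equal(concordance(lab, inv), 1.0)
  expect_error(concordance(lab, lab[-1]), "length")
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:2, 15, replace = TRUE)
    b <- sample(1:2, 15, replace = TRUE)
    expect_gte(concordance(a, b), 0.5)
  }
})

test_that("convex-hull overlap detects intersection, containment, disjointness", {
  sq <- function(cx, cy, h) cbind(c(cx - h, cx + h, cx + h, cx - h),
                                  c(cy - h, cy - h, cy + h, cy + h))
  expect_true(hulls_overlap(sq(0, 0, 1), sq(1, 1, 1)))    # partial overlap
  expect_true(hulls_overlap(sq(0, 0, 3), sq(0, 0, 0.5)))  # containment
  expect_false(hulls_overlap(sq(0, 0, 1), sq(5, 5, 1)))   # disjoint
  # degenerate hulls: single point inside / outside
  expect_true(hulls_overlap(sq(0, 0, 1), cbind(0.2, 0.3)))
  expect_false(hulls_overlap(sq(0, 0, 1), cbind(9, 9)))
})

test_that("maxilla PCA + k-means clusters match the jcp-DV classification", {
  cfg <- synthetic_config(seed = 20L)
  tab <- generate_population(cfg)
  rr <- subset_rerun(tab, "maxilla", c("jcp_DV", "jpp_ML", "jpm_AP"),
                     seed = 5)
  lab <- jcp_morph_labels(tab, rr$specimen_id)
  keep <- lab != "ambiguous"
  expect_equal(concordance(rr$clusters$labels[keep], lab[keep]), 1.0)
})

test_that("subset reruns mirror the per-element overlap judgments", {
  # tiny complete-case samples (9 premaxillae, 8 fibulae) make any one
  # draw noisy; the structural claims are about the average over
  # populations. Cluster-morph concordance carries the "do the clusters
  # reflect dimorphism" content; the separation gap carries "is there
  # visual daylight between the clusters".
  one <- function(tab, el, codes) {
    rr <- subset_rerun(tab, el, codes, seed = 5)
    truth <- true_morphs(tab)
    m <- truth$morph[match(rr$specimen_id, truth$specimen_id)]
    c(conc = concordance(rr$clusters$labels, m), sep = rr$separation)
  }
  deltas <- sapply(31:40, function(s) {
    tab <- generate_population(synthetic_config(seed = s))
    pmx_all <- one(tab, "premaxilla", element_codes("premaxilla"))
    pmx_sub <- one(tab, "premaxilla",
                   setdiff(element_codes("premaxilla"),
                           c("pg_ML", "pg_depth")))
    q_mmc <- one(tab, "quadrate", c("mmc_AP", "mmc_ML", "mmc_DV"))
    q_all <- one(tab, "quadrate", element_codes("quadrate"))
    f_all <- one(tab, "fibula", element_codes("fibula"))
    f_sub <- one(tab, "fibula",
                 setdiff(element_codes("fibula"), "tc_to_dc"))
    c(
      # premaxilla: dropping the palatal-groove noise re-aligns clusters
      # with the morphs
      pmx = pmx_sub[["conc"]] - pmx_all[["conc"]],
      # quadrate: medial-condyle lengths alone track the morphs best
      q = q_mmc[["conc"]] - q_all[["conc"]],
      # fibula: clusters lose their gap without tc_to_dc
      f = f_all[["sep"]] - f_sub[["sep"]]
    )
  })
  expect_gt(mean(deltas["pmx", ]), 0)
  expect_gt(mean(deltas["q", ]), 0)
  expect_gt(mean(deltas["f", ]), 0)
})
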