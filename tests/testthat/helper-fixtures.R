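# Shared fixtures and independent oracles for the test suite.

# A small hand-built maxilla table: 3 specimens, one broken through the
# caniniform (missing jcp_DV).
tiny_maxilla_df <- function() {
  data.frame(
    specimen_id = c("A", "B", "C"),
    element = "maxilla",
    side = c("left", "right", "left"),
    jcp_DV = c(131, NA, 240),
    jpp_ML = c(62, 60, 88),
    jpm_AP = c(135, 128, 150)
  )
}

# Draw from a two-component normal mixture on the log10 scale.
rmix <- function(n, a, mu1, sd1, mu2, sd2) {
  small <- stats::runif(n) < a
  ifelse(small, stats::rnorm(n, mu1, sd1), stats::rnorm(n, mu2, sd2))
}

# Classify specimens by caniniform (jcp DV) length under the published
# mixture parameters; returns small/large/ambiguous per id.
jcp_morph_labels <- function(tab, ids, tau = 0.9) {
  p <- jcp_dv_published_fit()
  fit <- structure(list(mu1 = p$mu1, mu2 = p$mu2, sd1 = p$sd1,
                        sd2 = p$sd2, a = p$a), class = "bimodal_fit")
  sub <- tab[match(ids, tab$specimen_id), ]
  assign_morphs(fit, log10(sub$jcp_DV), tau = tau, specimen_id = ids)$label
}

# Independent grid-search oracle for the mixture log-likelihood: best
# achievable log-likelihood over a dense grid of (mu1, mu2, sd1, sd2, a).
# Deliberately brute-force and separate from the EM code path.
grid_best_loglik <- function(x, sd_floor) {
  mus <- seq(min(x), max(x), length.out = 16)
  sds <- unique(pmax(seq(0.2, 1.5, length.out = 7) * stats::sd(x), sd_floor))
  as <- seq(0.05, 0.95, length.out = 10)
  dens <- list()
  k <- 0
  idx <- expand.grid(mi = seq_along(mus), si = seq_along(sds))
  dmat <- matrix(0, nrow = length(x), ncol = nrow(idx))
  for (j in seq_len(nrow(idx))) {
    dmat[, j] <- stats::dnorm(x, mus[idx$mi[j]], sds[idx$si[j]])
  }
  best <- -Inf
  for (j1 in seq_len(nrow(idx))) {
    for (j2 in seq_len(nrow(idx))) {
      if (mus[idx$mi[j1]] > mus[idx$mi[j2]]) next
      d1 <- dmat[, j1]; d2 <- dmat[, j2]
      for (a in as) {
        ll <- sum(log(a * d1 + (1 - a) * d2))
        if (ll > best) best <- ll
      }
    }
  }
  best
}
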