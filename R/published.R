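#' Published model-selection summary for the Placerias Quarry survey
#'
#' The published survey of the *Placerias* Quarry sample reports, for each
#' of the 25 measurements, the sample size, the log-likelihood, AICc
#' difference and Akaike weight of the unimodal normal (2 parameters) and
#' of the two-component mixture (5 parameters). The raw per-specimen
#' measurements are deposited separately and are not bundled here; this
#' table carries the printed summary values, which serve as inputs for
#' consistency checks (AICc/weight arithmetic) and to calibrate the
#' synthetic generator's per-measurement sample sizes.
#'
#' Weights are stored as printed strings (`"<0.001"`, `">0.999"`
#' saturation) alongside a numeric reading.
#'
#' @return Tibble with columns `element`, `code`, `n`, `daicc_uni`,
#'   `w_uni_printed`, `loglik_uni`, `daicc_bi`, `w_bi_printed`,
#'   `loglik_bi`.
#' @export
published_survey <- function() {
  rows <- list(
    list("maxilla", "jcp_DV", 16, 2.44, "0.23", 8.6, 0, "0.77", 15.4),
    list("maxilla", "jpm_AP", 23, 0, "0.89", 38.0, 4.1, "0.11", 40.4),
    list("maxilla", "jpp_ML", 28, 4.7, "0.09", 38.8, 0, "0.91", 45.2),
    list("maxilla", "td", 19, 0, "0.53", 25.7, 0.2, "0.47", 30.5),
    list("maxilla", "ad", 20, 0, "0.95", 11.8, 6, "0.05", 13.7),
    list("maxilla", "ttc", 14, 0, "0.99", -2.6, 8.5, "0.01", -0.7),
    list("premaxilla", "at_to_np", 7, 0, ">0.999", 10.6, 57.0, "<0.001", 13.6),
    list("premaxilla", "at_to_mxs", 8, 0, ">0.999", 8.7, 31.3, "<0.001", 9.9),
    list("premaxilla", "pg_ML", 7, 0, ">0.999", 6.1, 62.4, "<0.001", 6.3),
    list("premaxilla", "mxs_to_np", 9, 0, ">0.999", 11.4, 19.4, "<0.001", 13.7),
    list("premaxilla", "AP", 6, 0, ">0.999", 9.7, Inf, "<0.001", 16.1),
    list("premaxilla", "mxs_ML", 7, 0, ">0.999", 9.5, 58.6, "<0.001", 11.7),
    list("premaxilla", "pg_depth", 8, 0, ">0.999", 8.5, 29.6, "<0.001", 10.5),
    list("premaxilla", "np_ML", 8, 0, ">0.999", 10.7, 28.2, "<0.001", 13.4),
    list("quadrate", "mmc_AP", 40, 0, "0.9", 64.2, 4.4, "0.1", 65.7),
    list("quadrate", "mmc_ML", 42, 0, "0.86", 54.5, 3.6, "0.14", 56.4),
    list("quadrate", "mmc_DV", 41, 0, "0.51", 63.8, 0.1, "0.49", 67.5),
    list("quadrate", "lmc_AP", 31, 0, "0.69", 40.8, 1.6, "0.31", 44),
    list("quadrate", "lmc_ML", 29, 0, "0.96", 40.9, 6.6, "0.04", 41.7),
    list("quadrate", "lmc_DV", 29, 0, "0.85", 38.2, 3.5, "0.15", 40.5),
    list("fibula", "tc_to_fc", 14, 0, "0.98", 26, 7.6, "0.02", 28.4),
    list("fibula", "dc_tip_to_tip", 12, 0, "0.98", 19.2, 7.8, "0.02", 22.6),
    list("fibula", "pc_DV", 14, 0, "0.97", 21.3, 6.8, "0.03", 24.1),
    list("fibula", "tc_to_dc", 8, 0, ">0.999", 18.3, 28, "<0.001", 21.1),
    list("fibula", "ms_DV", 12, 0, "0.82", 21.1, 3.1, "0.18", 26.8)
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(element = r[[1]], code = r[[2]], n = as.integer(r[[3]]),
                   daicc_uni = r[[4]], w_uni_printed = r[[5]],
                   loglik_uni = r[[6]], daicc_bi = r[[7]],
                   w_bi_printed = r[[8]], loglik_bi = r[[9]])
  }))
}

#' Published mixture parameters for caniniform length (jcp DV)
#'
#' The fitted two-component mixture for the jugal-caniniform process
#' dorsoventral length of the 16 complete maxillae: equal mixture weight,
#' small-morph mean 2.1159 (log10 mm) with SD 0.034, large-morph mean
#' 2.37596 with SD 0.064. These parameters define the dimorphic study
#' conditions the synthetic generator reproduces by default.
#'
#' @return List with `a`, `mu1`, `sd1`, `mu2`, `sd2` (log10 scale).
#' @export
jcp_dv_published_fit <- function() {
  list(a = 0.5, mu1 = 2.1159, sd1 = 0.034, mu2 = 2.37596, sd2 = 0.064)
}
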