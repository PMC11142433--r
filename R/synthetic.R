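#' Trait specifications for the synthetic generator
#'
#' A synthetic population is described trait-by-trait on the log10 scale:
#' `trait_dimorphic()` draws from one of two normals according to the
#' specimen's morph; `trait_monomorphic()` ignores morph; `trait_coupled()`
#' derives a trait from another trait of the same specimen by a linear
#' (allometric) relation with Gaussian residual noise, so within-morph
#' correlation structure is preserved.
#'
#' @param mu,sd Mean and SD (log10 mm) of a monomorphic trait.
#' @param mu1,sd1,mu2,sd2 Small- and large-morph parameters of a dimorphic
#'   trait (log10 mm), `mu1 <= mu2`.
#' @param parent Code of the trait this one is coupled to (same element).
#' @param slope,intercept,resid_sd Linear coupling on the log10 scale.
#' @return A trait specification list with a `type` field.
#' @name trait_spec
NULL

#' @rdname trait_spec
#' @export
trait_dimorphic <- function(mu1, sd1, mu2, sd2) {
  stopifnot(mu1 <= mu2, sd1 > 0, sd2 > 0)
  list(type = "dimorphic", mu1 = mu1, sd1 = sd1, mu2 = mu2, sd2 = sd2)
}

#' @rdname trait_spec
#' @export
trait_monomorphic <- function(mu, sd) {
  stopifnot(sd > 0)
  list(type = "monomorphic", mu = mu, sd = sd)
}

#' @rdname trait_spec
#' @export
trait_coupled <- function(parent, slope, intercept, resid_sd) {
  stopifnot(resid_sd > 0)
  list(type = "coupled", parent = parent, slope = slope,
       intercept = intercept, resid_sd = resid_sd)
}

# Default trait structure, chosen once to emulate the qualitative
# structure of the quarry sample: caniniform length (jcp_DV) carries the
# published dimorphic mixture; jpp_ML and the tooth-related lengths are
# allometrically coupled to it; jpm_AP (a proxy for absolute skull size)
# and tooth diameter are monomorphic. Premaxilla lengths are weakly
# dimorphic except the palatal-groove pair, which is uninformative noise.
# Quadrate medial-condyle lengths are moderately dimorphic, the lateral
# condyle monomorphic. Fibula lengths track one weakly dimorphic size
# axis, with the tibial-to-distal-condyle length separating strongly
# (the diaphysis is disproportionately long in the largest individuals).
default_traits <- function() {
  jcp <- jcp_dv_published_fit()
  list(
    maxilla = list(
      jcp_DV = trait_dimorphic(jcp$mu1, jcp$sd1, jcp$mu2, jcp$sd2),
      jpp_ML = trait_coupled("jcp_DV", 0.55, 0.63, 0.025),
      jpm_AP = trait_monomorphic(2.13, 0.07),
      td = trait_monomorphic(1.19, 0.035),
      ad = trait_coupled("jcp_DV", 0.5, 0.6, 0.08),
      ttc = trait_coupled("jcp_DV", 1.1, -0.35, 0.045)
    ),
    premaxilla = list(
      at_to_np = trait_dimorphic(2.42, 0.05, 2.49, 0.05),
      at_to_mxs = trait_dimorphic(2.18, 0.05, 2.25, 0.05),
      pg_ML = trait_monomorphic(1.60, 0.06),
      mxs_to_np = trait_dimorphic(2.26, 0.05, 2.33, 0.05),
      AP = trait_dimorphic(2.47, 0.05, 2.54, 0.05),
      mxs_ML = trait_dimorphic(1.95, 0.05, 2.02, 0.05),
      pg_depth = trait_monomorphic(1.30, 0.07),
      np_ML = trait_dimorphic(1.70, 0.05, 1.77, 0.05)
    ),
    quadrate = list(
      # medial condyle: a moderately dimorphic module
      mmc_AP = trait_dimorphic(1.72, 0.05, 1.81, 0.05),
      mmc_ML = trait_dimorphic(1.80, 0.05, 1.89, 0.05),
      mmc_DV = trait_dimorphic(1.55, 0.05, 1.64, 0.05),
      # lateral condyle: an internally correlated monomorphic module
      lmc_AP = trait_monomorphic(1.68, 0.06),
      lmc_ML = trait_coupled("lmc_AP", 1, 0.08, 0.03),
      lmc_DV = trait_coupled("lmc_AP", 1, -0.18, 0.03)
    ),
    fibula = list(
      tc_to_fc = trait_dimorphic(2.42, 0.04, 2.48, 0.04),
      dc_tip_to_tip = trait_coupled("tc_to_fc", 1, -0.55, 0.03),
      pc_DV = trait_coupled("tc_to_fc", 1, -0.62, 0.03),
      tc_to_dc = trait_dimorphic(2.26, 0.03, 2.46, 0.03),
      ms_DV = trait_coupled("tc_to_fc", 1.3, -1.45, 0.04)
    )
  )
}

#' Synthetic-population configuration
#'
#' Bundles everything [generate_population()] needs: per-element sample
#' sizes (defaults are the quarry sample's 36 maxillae, 29 premaxillae,
#' 44 quadrates, 17 fibulae), the morph mixture weight (default 0.5, the
#' published 1:1 ratio), the trait structure, the breakage model and the
#' seed.
#'
#' Breakage combines an intact fraction per element (specimens complete
#' for every measurement, as a fraction of articulated well-preserved
#' fossils are) with independent per-cell loss on the remaining
#' specimens. Per-measurement loss rates are derived from target
#' per-measurement sample sizes — by default the published survey's
#' per-measurement n — via
#' `rate = 1 - (target/n - intact)/(1 - intact)`, clamped to \[0, 1\].
#'
#' @param n Named integer vector of specimens per element.
#' @param mixture_weight Probability a specimen is the small morph.
#' @param traits Trait structure as from [default_traits()].
#' @param intact_fraction Named fraction of fully intact specimens per
#'   element.
#' @param target_n Tibble with `element`, `code`, `n` giving target
#'   complete counts per measurement (default [published_survey()]), or
#'   `NULL` for no missingness.
#' @param round_mm Round generated values to the nearest mm (the
#'   measurement error of the calipers/tape)? Default `FALSE`.
#' @param seed Integer seed.
#' @return A `"synthetic_config"` list, validated.
#' @export
synthetic_config <- function(n = c(maxilla = 36L, premaxilla = 29L,
                                   quadrate = 44L, fibula = 17L),
                             mixture_weight = 0.5,
                             traits = default_traits(),
                             intact_fraction = c(maxilla = 0.3,
                                                 premaxilla = 9 / 29,
                                                 quadrate = 26 / 44,
                                                 fibula = 8 / 17),
                             target_n = published_survey()[, c("element", "code", "n")],
                             round_mm = FALSE,
                             seed = 1L) {
  stopifnot(mixture_weight >= 0, mixture_weight <= 1,
            all(n >= 0), all(intact_fraction >= 0 & intact_fraction <= 1))
  catalog <- measurement_catalog()
  for (el in names(traits)) {
    codes <- names(traits[[el]])
    bad <- setdiff(codes, element_codes(el, catalog))
    if (length(bad) > 0) {
      stop("trait code(s) not in catalog for ", el, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # coupled parents must exist and be acyclic (parents must be
    # resolvable in declaration order)
    seen <- character(0)
    for (code in codes) {
      tr <- traits[[el]][[code]]
      if (tr$type == "coupled") {
        if (!tr$parent %in% seen) {
          stop("coupled trait ", code, " (", el, ") declared before its ",
               "parent ", tr$parent, call. = FALSE)
        }
      }
      seen <- c(seen, code)
    }
  }
  structure(list(n = n, mixture_weight = mixture_weight, traits = traits,
                 intact_fraction = intact_fraction, target_n = target_n,
                 round_mm = round_mm, seed = as.integer(seed)),
            class = "synthetic_config")
}

miss_rate <- function(config, element, code) {
  if (is.null(config$target_n)) return(0)
  t <- config$target_n
  hit <- t$n[t$element == element & t$code == code]
  if (length(hit) == 0) return(0)
  n <- config$n[[element]]
  f <- config$intact_fraction[[element]]
  keep <- (hit / n - f) / (1 - f)
  1 - min(max(keep, 0), 1)
}

#' Generate a synthetic measurement table
#'
#' Draws a morph for each specimen with probability
#' (`mixture_weight`, 1 - `mixture_weight`), generates every trait on the
#' log10 scale according to its specification (coupled traits use the
#' parent's latent value even if that cell is later lost to breakage),
#' back-transforms to mm, applies the breakage model, and attaches
#' plausible nominal tooth characters to maxillae. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A validated measurement table; the true morph of every
#'   specimen-element is attached as `attr(, "morph")` (a tibble with
#'   `specimen_id`, `element`, `morph`).
#' @export
generate_population <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  catalog <- measurement_catalog()
  all_rows <- list()
  truth <- list()
  for (el in names(config$traits)) {
    n <- config$n[[el]]
    if (n == 0) next
    ids <- sprintf("SYN-%s-%03d", toupper(substr(el, 1, 3)), seq_len(n))
    morph <- ifelse(stats::runif(n) < config$mixture_weight,
                    "small", "large")
    side <- if (el == "premaxilla") rep("fused", n) else
      sample(c("left", "right"), n, replace = TRUE)
    latent <- list()
    for (code in names(config$traits[[el]])) {
      tr <- config$traits[[el]][[code]]
      latent[[code]] <- switch(
        tr$type,
        dimorphic = ifelse(morph == "small",
                           stats::rnorm(n, tr$mu1, tr$sd1),
                           stats::rnorm(n, tr$mu2, tr$sd2)),
        monomorphic = stats::rnorm(n, tr$mu, tr$sd),
        coupled = tr$slope * latent[[tr$parent]] + tr$intercept +
          stats::rnorm(n, 0, tr$resid_sd))
    }
    # exact number of fully intact specimens (the study conditions state
    # these counts), at random positions
    n_intact <- round(config$intact_fraction[[el]] * n)
    intact <- seq_len(n) %in% sample.int(n, n_intact)
    df <- tibble::tibble(specimen_id = ids, element = el, side = side)
    for (code in names(latent)) {
      mm <- 10^latent[[code]]
      if (config$round_mm) mm <- pmax(round(mm), 1)
      lost <- !intact &
        stats::runif(n) < miss_rate(config, el, code)
      mm[lost] <- NA_real_
      df[[code]] <- mm
    }
    if (el == "maxilla") {
      # tooth characters: a few specimens never erupted a socket, some
      # sockets lost their tooth post-mortem, rare proximal eruption
      assessable <- stats::runif(n) < 0.9
      socket <- ifelse(!assessable, "indeterminate",
                       ifelse(stats::runif(n) < 0.12, "no", "yes"))
      tooth <- ifelse(socket != "yes", ifelse(socket == "no", "no",
                                              "indeterminate"),
                      ifelse(stats::runif(n) < 0.7, "yes", "no"))
      erupt <- ifelse(tooth == "yes",
                      ifelse(stats::runif(n) < 0.15, "yes", "no"),
                      "indeterminate")
      df$tooth_present <- tooth
      df$socket_present <- socket
      df$proximal_eruption <- erupt
    }
    all_rows[[el]] <- df
    truth[[el]] <- tibble::tibble(specimen_id = ids, element = el,
                                  morph = morph)
  }
  tab <- measurement_table(dplyr::bind_rows(all_rows), catalog)
  attr(tab, "morph") <- dplyr::bind_rows(truth)
  tab
}

#' True morphs of a synthetic table
#'
#' @param table A table from [generate_population()].
#' @return Tibble with `specimen_id`, `element`, `morph`.
#' @export
true_morphs <- function(table) {
  m <- attr(table, "morph")
  if (is.null(m)) stop("table carries no morph truth", call. = FALSE)
  m
}

#' Detection-rate experiment: bimodal AICc wins under each truth
#'
#' Draws `n_reps` datasets of size `n_per_dataset` from (i) a dimorphic
#' truth (by default the published caniniform mixture) and (ii) a
#' monomorphic truth with the same overall mean and variance
#' (moment-matched single normal), runs the AICc comparison on each, and
#' reports the fraction of replicates where the mixture wins. With small
#' samples the three extra parameters of the mixture carry a heavy AICc
#' penalty, so real dimorphism can go undetected; the monomorphic arm
#' doubles as a type-I-error check. One master seed is split into
#' per-replicate substreams shared by both arms.
#'
#' @param n_per_dataset Specimens per replicate dataset.
#' @param n_reps Number of replicates per arm (>= 100 recommended).
#' @param seed Master seed.
#' @param dimorphic Mixture truth: list with `a`, `mu1`, `sd1`, `mu2`,
#'   `sd2`; default [jcp_dv_published_fit()].
#' @param n_restarts Random restarts per mixture fit (smaller than the
#'   fitting default: thousands of fits are run).
#' @return List: `win_dimorphic`, `win_monomorphic` (fractions in \[0,1\]),
#'   `n_per_dataset`, `n_reps`.
#' @export
power_experiment <- function(n_per_dataset = 16L, n_reps = 500L, seed = 1L,
                             dimorphic = jcp_dv_published_fit(),
                             n_restarts = 10L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  # moment-matched unimodal truth
  a <- dimorphic$a
  m0 <- a * dimorphic$mu1 + (1 - a) * dimorphic$mu2
  v0 <- a * (dimorphic$sd1^2 + (dimorphic$mu1 - m0)^2) +
    (1 - a) * (dimorphic$sd2^2 + (dimorphic$mu2 - m0)^2)
  bi_wins <- function(x, s) {
    cmp <- compare_models(x, seed = s, n_restarts = n_restarts)
    cmp$winner == "bimodal"
  }
  win_di <- win_mono <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    morph <- stats::runif(n_per_dataset) < a
    x_di <- ifelse(morph,
                   stats::rnorm(n_per_dataset, dimorphic$mu1, dimorphic$sd1),
                   stats::rnorm(n_per_dataset, dimorphic$mu2, dimorphic$sd2))
    x_mono <- stats::rnorm(n_per_dataset, m0, sqrt(v0))
    win_di[r] <- bi_wins(x_di, rep_seeds[r])
    win_mono[r] <- bi_wins(x_mono, rep_seeds[r])
  }
  list(win_dimorphic = mean(win_di), win_monomorphic = mean(win_mono),
       n_per_dataset = n_per_dataset, n_reps = n_reps)
}
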