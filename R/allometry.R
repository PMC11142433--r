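#' Ordinary least-squares association between two log10 measurements
#'
#' Fits `y ~ x` by OLS and reports the adjusted coefficient of
#' determination as the headline statistic (adjusted R2 can go negative
#' for uninformative fits, which is reported as-is, not clamped), with the
#' raw R2 beside it and the two-sided p-value of the slope (equivalently
#' the regression F-test with one predictor).
#'
#' @param x,y Paired numeric vectors (log10 mm), no missing values,
#'   `n >= 3`.
#' @return A list: `n`, `slope`, `intercept`, `r2_raw`, `r2_adjusted`,
#'   `p_value`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(n = n,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2_raw = sm$r.squared,
       r2_adjusted = sm$adj.r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' Coefficient of variation on the log10 scale
#'
#' CV = sd/mean computed on log10 values, matching how within-morph
#' variability is contrasted between mixture components. Note the scale
#' dependence: multiplying raw mm by 10 shifts the log10 mean by 1 and
#' changes this CV, so the scale must always be reported with the value.
#' Either a data vector or a fitted component's (mu, sd) may be supplied.
#'
#' @param x Numeric vector of log10 values, or `NULL` if `mu`/`sd` given.
#' @param mu,sd Component mean and SD on the log10 scale (used when `x`
#'   is `NULL`).
#' @param label Optional group label carried through.
#' @return A list: `label`, `mean_log10`, `sd_log10`, `cv`.
#' @export
cv_log <- function(x = NULL, mu = NULL, sd = NULL, label = NA_character_) {
  if (!is.null(x)) {
    mu <- mean(x)
    sd <- stats::sd(x)
    if (length(x) == 1 || sd == 0) sd <- 0
  }
  if (is.null(mu) || is.null(sd)) {
    stop("supply either x or both mu and sd", call. = FALSE)
  }
  if (mu <= 0) stop("CV undefined for non-positive mean", call. = FALSE)
  list(label = label, mean_log10 = mu, sd_log10 = sd, cv = sd / mu)
}

#' Per-morph and pooled associations between two measurements
#'
#' Restricts an element's records to pairwise-complete cases for two
#' measurement codes, splits them by an externally supplied morph
#' labelling (from [assign_morphs()]), and fits [fit_line()] within each
#' morph and pooled. Groups with fewer than 3 pairs are marked
#' unavailable rather than fitted.
#'
#' @param table A measurement table.
#' @param element Element name.
#' @param code_x,code_y Measurement codes (x = predictor).
#' @param morphs Tibble with `specimen_id` and `label`
#'   (small/large/ambiguous); ambiguous specimens enter only the pooled
#'   fit.
#' @return Tibble with one row per group (`small`, `large`, `pooled`):
#'   `group`, `n`, `available`, `slope`, `intercept`, `r2_raw`,
#'   `r2_adjusted`, `p_value`.
#' @export
group_associations <- function(table, element, code_x, code_y, morphs) {
  cc <- complete_cases(table, element, c(code_x, code_y))
  x <- log10_values(cc, element, code_x)
  y <- log10_values(cc, element, code_y)
  lab <- morphs$label[match(cc$specimen_id, morphs$specimen_id)]
  one <- function(group, idx) {
    if (sum(idx) < 3) {
      return(tibble::tibble(group = group, n = sum(idx), available = FALSE,
                            slope = NA_real_, intercept = NA_real_,
                            r2_raw = NA_real_, r2_adjusted = NA_real_,
                            p_value = NA_real_))
    }
    f <- fit_line(x[idx], y[idx])
    tibble::tibble(group = group, n = f$n, available = TRUE,
                   slope = f$slope, intercept = f$intercept,
                   r2_raw = f$r2_raw, r2_adjusted = f$r2_adjusted,
                   p_value = f$p_value)
  }
  dplyr::bind_rows(
    one("small", !is.na(lab) & lab == "small"),
    one("large", !is.na(lab) & lab == "large"),
    one("pooled", rep(TRUE, length(x)))
  )
}
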