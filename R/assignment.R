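#' Posterior responsibility of the large component
#'
#' Probability that a value arose from the larger-mean component of a
#' fitted two-component mixture:
#' `(1-a) N(x; mu2, sigma2_2) / [a N(x; mu1, sigma1_2) + (1-a) N(x; mu2, sigma2_2)]`.
#'
#' @param fit A `"bimodal_fit"`.
#' @param x Numeric vector of log10 values.
#' @return Vector of posterior probabilities in \[0, 1\].
#' @export
posterior_responsibility <- function(fit, x) {
  stopifnot(inherits(fit, "bimodal_fit"))
  l1 <- log(max(fit$a, .Machine$double.xmin)) +
    stats::dnorm(x, fit$mu1, fit$sd1, log = TRUE)
  l2 <- log(max(1 - fit$a, .Machine$double.xmin)) +
    stats::dnorm(x, fit$mu2, fit$sd2, log = TRUE)
  1 / (1 + exp(l1 - l2))
}

#' Assign specimens to morphs with an ambiguity zone
#'
#' Two mixture components can overlap substantially, and specimens in the
#' overlap region cannot be attributed to either morph. A specimen is
#' labelled `large` only when its posterior responsibility for the large
#' component is at least `tau`, `small` only when it is at most `1 - tau`,
#' and `ambiguous` otherwise.
#'
#' @param fit A `"bimodal_fit"`.
#' @param x Numeric vector of log10 values.
#' @param tau Assignment threshold, in (0.5, 1\]; default 0.9.
#' @param specimen_id Optional identifiers (recycled `seq_along(x)` names
#'   otherwise).
#' @return A tibble with `specimen_id`, `x`, `value_mm`, `gamma`, `label`,
#'   carrying `tau` and label counts as attributes.
#' @export
assign_morphs <- function(fit, x, tau = 0.9, specimen_id = NULL) {
  stopifnot(tau > 0.5, tau <= 1)
  if (is.null(specimen_id)) specimen_id <- as.character(seq_along(x))
  gamma <- posterior_responsibility(fit, x)
  label <- ifelse(gamma >= tau, "large",
                  ifelse(gamma <= 1 - tau, "small", "ambiguous"))
  out <- tibble::tibble(specimen_id = as.character(specimen_id),
                        x = x, value_mm = 10^x,
                        gamma = gamma, label = label)
  attr(out, "tau") <- tau
  attr(out, "counts") <- c(small = sum(label == "small"),
                           large = sum(label == "large"),
                           ambiguous = sum(label == "ambiguous"))
  out
}

#' Majority-vote morph consensus across measurements
#'
#' Optional utility beyond the per-measurement rule: given several
#' per-measurement assignments of the same specimens, each specimen takes
#' the majority label among its non-ambiguous votes; ties or all-ambiguous
#' records stay `ambiguous`.
#'
#' @param ... Assignment tibbles from [assign_morphs()], sharing
#'   `specimen_id`.
#' @return Tibble with `specimen_id`, `n_votes`, `label`.
#' @export
morph_consensus <- function(...) {
  all <- dplyr::bind_rows(lapply(list(...), function(a) {
    a[, c("specimen_id", "label")]
  }))
  all <- all[all$label != "ambiguous", , drop = FALSE]
  ids <- unique(all$specimen_id)
  out <- lapply(ids, function(id) {
    v <- all$label[all$specimen_id == id]
    lab <- if (sum(v == "small") > sum(v == "large")) "small"
           else if (sum(v == "large") > sum(v == "small")) "large"
           else "ambiguous"
    tibble::tibble(specimen_id = id, n_votes = length(v), label = lab)
  })
  dplyr::bind_rows(out)
}
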