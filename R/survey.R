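#' Run the full per-measurement model-selection survey
#'
#' For every measurement in the catalog: extract the element's complete
#' cases for that single measurement, log10-transform, and compare the
#' unimodal normal against the two-component mixture by AICc.
#' Measurements with fewer than `min_n` complete specimens are emitted
#' with `status = "skipped"` rather than dropped, so a full-catalog table
#' always yields 25 rows.
#'
#' @param table A validated measurement table.
#' @param seed Seed for the mixture fits' random restarts.
#' @param min_n Minimum complete-case count to fit (default 3).
#' @param ... Passed to [fit_bimodal()] (e.g. `n_restarts`).
#' @return An object of class `"survey_report"`: a tibble with one row
#'   per catalog measurement (`element`, `code`, `n`, `status`,
#'   `loglik_uni`, `aicc_uni`, `daicc_uni`, `w_uni`, `loglik_bi`,
#'   `aicc_bi`, `daicc_bi`, `w_bi`, `winner`, and the fitted mixture
#'   parameters `a`, `mu1`, `mu2`, `sd1`, `sd2`), with the seed attached
#'   as an attribute.
#' @export
run_survey <- function(table, seed = 1L, min_n = 3L, ...) {
  catalog <- measurement_catalog()
  rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    el <- catalog$element[i]; code <- catalog$code[i]
    cc <- complete_cases(table, el, code)
    n <- nrow(cc)
    empty <- tibble::tibble(
      element = el, code = code, n = n, status = "skipped",
      loglik_uni = NA_real_, aicc_uni = NA_real_, daicc_uni = NA_real_,
      w_uni = NA_real_, loglik_bi = NA_real_, aicc_bi = NA_real_,
      daicc_bi = NA_real_, w_bi = NA_real_, winner = NA_character_,
      a = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
      sd1 = NA_real_, sd2 = NA_real_)
    if (n < min_n) {
      rows[[i]] <- empty
      next
    }
    x <- log10_values(cc, el, code)
    if (stats::sd(x) == 0) {
      rows[[i]] <- empty
      next
    }
    cmp <- suppressWarnings(compare_models(x, seed = seed, ...))
    rows[[i]] <- tibble::tibble(
      element = el, code = code, n = n, status = "fitted",
      loglik_uni = cmp$uni$logLik, aicc_uni = cmp$aicc_uni,
      daicc_uni = cmp$daicc_uni, w_uni = cmp$w_uni,
      loglik_bi = cmp$bi$logLik, aicc_bi = cmp$aicc_bi,
      daicc_bi = cmp$daicc_bi, w_bi = cmp$w_bi,
      winner = cmp$winner,
      a = cmp$bi$a, mu1 = cmp$bi$mu1, mu2 = cmp$bi$mu2,
      sd1 = cmp$bi$sd1, sd2 = cmp$bi$sd2)
  }
  out <- dplyr::bind_rows(rows)
  if (all(out$status == "skipped")) {
    warning("no measurement had enough complete cases to fit",
            call. = FALSE)
  }
  attr(out, "seed") <- seed
  class(out) <- c("survey_report", class(out))
  out
}

# Rendering rules for the human-readable table: log-likelihood to 1 dp,
# weights to 2 dp saturating at "<0.001"/">0.999", dAICc to 2 dp below 10
# and 1 dp at or above, "Inf" for an infinite AICc penalty.

#' @rdname render_survey
#' @export
format_weight <- function(w) {
  ifelse(is.na(w), "",
         ifelse(w < 0.001, "<0.001",
                ifelse(w > 0.999, ">0.999", sprintf("%.2f", w))))
}

#' @rdname render_survey
#' @export
format_daicc <- function(d) {
  ifelse(is.na(d), "",
         ifelse(is.infinite(d), "Inf",
                ifelse(abs(d) < 10, sprintf("%.2f", d), sprintf("%.1f", d))))
}

#' Render a survey report as a plain-text table
#'
#' @param survey A `"survey_report"`.
#' @return Character vector of lines (markdown pipe table).
#' @export
render_survey <- function(survey) {
  hdr <- c(
    "| Bone | Measurement | n | dAICc (uni) | weight (uni) | logLik (uni) | dAICc (bi) | weight (bi) | logLik (bi) |",
    "|------|-------------|---|-------------|--------------|--------------|------------|-------------|-------------|")
  body <- vapply(seq_len(nrow(survey)), function(i) {
    r <- survey[i, ]
    if (r$status == "skipped") {
      sprintf("| %s | %s | %d | skipped |  |  |  |  |  |", r$element, r$code, r$n)
    } else {
      sprintf("| %s | %s | %d | %s | %s | %.1f | %s | %s | %.1f |",
              r$element, r$code, r$n,
              format_daicc(r$daicc_uni), format_weight(r$w_uni), r$loglik_uni,
              format_daicc(r$daicc_bi), format_weight(r$w_bi), r$loglik_bi)
    }
  }, character(1))
  c(hdr, body)
}

#' Write a survey report to disk
#'
#' Writes full-precision machine output (JSON; infinities encoded as the
#' string `"Inf"`) and the rendered plain-text table side by side.
#'
#' @param survey A `"survey_report"`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "survey.json")
  md_path <- file.path(dir, "survey.md")
  csv_path <- file.path(dir, "survey.csv")
  df <- as.data.frame(survey)
  jsonlite::write_json(
    list(seed = attr(survey, "seed"), rows = df),
    json_path, auto_unbox = TRUE, digits = NA, na = "string")
  writeLines(render_survey(survey), md_path)
  readr::write_csv(df, csv_path)
  invisible(c(json = json_path, md = md_path, csv = csv_path))
}
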