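#' Measurement catalog for the four skeletal elements
#'
#' The analysis is built around 25 linear measurements taken on four
#' well-sampled skeletal elements of *Placerias hesternus*: 6 on the
#' maxilla, 8 on the premaxilla, 6 on the quadrate (three per mandibular
#' condyle) and 5 on the fibula. Each catalog entry records the element,
#' a short measurement code, a free-text description and the anatomical
#' axis of the measurement (dorsoventral, mediolateral, anteroposterior,
#' or other for oblique/diameter measurements).
#'
#' @return A tibble with columns `element`, `code`, `description`, `axis`;
#'   exactly 25 rows.
#' @export
#' @examples
#' catalog <- measurement_catalog()
#' table(catalog$element)
measurement_catalog <- function() {
  entry <- function(element, code, description, axis) {
    tibble::tibble(element = element, code = code,
                   description = description, axis = axis)
  }
  dplyr::bind_rows(
    entry("maxilla", "jcp_DV", "jugal suture to caniniform process tip", "DV"),
    entry("maxilla", "jpp_ML", "jugal suture to pterygoid pit", "ML"),
    entry("maxilla", "jpm_AP", "premaxillary suture to jugal suture", "AP"),
    entry("maxilla", "td", "tooth diameter", "other"),
    entry("maxilla", "ad", "alveolar cavity depth", "other"),
    entry("maxilla", "ttc", "tooth socket to caniniform tip", "other"),
    entry("premaxilla", "at_to_np", "anterior tip to nasal process tip", "other"),
    entry("premaxilla", "at_to_mxs", "anterior tip to maxillary suture", "other"),
    entry("premaxilla", "pg_ML", "palatal groove width", "ML"),
    entry("premaxilla", "mxs_to_np", "maxillary suture to nasal process tip", "other"),
    entry("premaxilla", "AP", "anteroposterior length", "AP"),
    entry("premaxilla", "mxs_ML", "width between maxillary sutures", "ML"),
    entry("premaxilla", "pg_depth", "palatal groove depth", "other"),
    entry("premaxilla", "np_ML", "nasal process width", "ML"),
    entry("quadrate", "mmc_AP", "medial mandibular condyle length", "AP"),
    entry("quadrate", "mmc_ML", "medial mandibular condyle width", "ML"),
    entry("quadrate", "mmc_DV", "medial mandibular condyle height", "DV"),
    entry("quadrate", "lmc_AP", "lateral mandibular condyle length", "AP"),
    entry("quadrate", "lmc_ML", "lateral mandibular condyle width", "ML"),
    entry("quadrate", "lmc_DV", "lateral mandibular condyle height", "DV"),
    entry("fibula", "tc_to_fc", "tibial condyle to femoral condyle", "other"),
    entry("fibula", "dc_tip_to_tip", "distal condyle tip to tip", "other"),
    entry("fibula", "pc_DV", "proximal condyle height", "DV"),
    entry("fibula", "tc_to_dc", "tibial condyle to distal condyle", "other"),
    entry("fibula", "ms_DV", "minimum dorsoventral midshaft diameter", "DV")
  )
}

#' Measurement codes valid for one element
#'
#' @param element One of `"maxilla"`, `"premaxilla"`, `"quadrate"`, `"fibula"`.
#' @param catalog A catalog tibble, by default [measurement_catalog()].
#' @return Character vector of measurement codes.
#' @export
element_codes <- function(element, catalog = measurement_catalog()) {
  element <- match.arg(element, unique(catalog$element))
  catalog$code[catalog$element == element]
}

elements_all <- function() c("maxilla", "premaxilla", "quadrate", "fibula")
sides_all <- function() c("left", "right", "fused", "unknown")
nominal_characters <- function() {
  c("tooth_present", "socket_present", "proximal_eruption")
}
nominal_levels <- function() c("yes", "no", "indeterminate")
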