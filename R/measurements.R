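#' Construct and validate a measurement table
#'
#' A measurement table holds one row per specimen-element (left and right
#' elements are independent observations; specimens cannot be paired in a
#' disarticulated quarry assemblage). Columns are `specimen_id`, `element`,
#' `side`, one column per catalog measurement code (mm; `NA` where the
#' specimen is broken through that landmark, or where the code belongs to a
#' different element), and the three nominal tooth characters
#' (`tooth_present`, `socket_present`, `proximal_eruption`; values `yes`,
#' `no`, `indeterminate`).
#'
#' Validation enforces: all present measurement values strictly positive;
#' values only under codes valid for the row's element; unique
#' `specimen_id` + `element` + `side`.
#'
#' @param df A data frame with at least `specimen_id`, `element`, `side`.
#'   Missing measurement columns are added as all-`NA`; missing nominal
#'   columns are added as `"indeterminate"`.
#' @param catalog Measurement catalog, by default [measurement_catalog()].
#' @return A validated tibble with the full canonical column set.
#' @export
measurement_table <- function(df, catalog = measurement_catalog()) {
  stopifnot(is.data.frame(df))
  needed <- c("specimen_id", "element", "side")
  missing_meta <- setdiff(needed, names(df))
  if (length(missing_meta) > 0) {
    stop("measurement table lacks column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$specimen_id <- as.character(df$specimen_id)
  df$element <- as.character(df$element)
  df$side <- as.character(df$side)

  bad_el <- setdiff(unique(df$element), elements_all())
  if (length(bad_el) > 0) {
    stop("unknown element(s): ", paste(bad_el, collapse = ", "), call. = FALSE)
  }
  bad_side <- setdiff(unique(df$side), sides_all())
  if (length(bad_side) > 0) {
    stop("unknown side value(s): ", paste(bad_side, collapse = ", "),
         call. = FALSE)
  }

  known_cols <- c(needed, catalog$code, nominal_characters())
  extra <- setdiff(names(df), known_cols)
  if (length(extra) > 0) {
    stop("unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }

  for (code in setdiff(catalog$code, names(df))) df[[code]] <- NA_real_
  for (nm in setdiff(nominal_characters(), names(df))) {
    df[[nm]] <- "indeterminate"
  }
  for (code in catalog$code) {
    df[[code]] <- suppressWarnings(as.numeric(df[[code]]))
  }
  for (nm in nominal_characters()) {
    v <- as.character(df[[nm]])
    v[is.na(v) | v == ""] <- "indeterminate"
    bad <- setdiff(unique(v), nominal_levels())
    if (length(bad) > 0) {
      stop("invalid value(s) for ", nm, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    df[[nm]] <- v
  }

  key <- paste(df$specimen_id, df$element, df$side, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate specimen_id + element + side: ",
         paste(unique(df$specimen_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }

  for (i in seq_len(nrow(df))) {
    valid <- element_codes(df$element[i], catalog)
    vals <- unlist(df[i, catalog$code])
    present <- names(vals)[!is.na(vals)]
    stray <- setdiff(present, valid)
    if (length(stray) > 0) {
      stop("row ", i, " (", df$specimen_id[i], ", ", df$element[i],
           "): value under code(s) not valid for this element: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
    nonpos <- present[vals[present] <= 0]
    if (length(nonpos) > 0) {
      stop("row ", i, " (", df$specimen_id[i],
           "): non-positive measurement in ",
           paste(nonpos, collapse = ", "), call. = FALSE)
    }
  }

  df[, c(needed, catalog$code, nominal_characters())]
}

#' Read a measurement table from CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a mandatory header
#' row; empty cells are missing measurements. Values are millimetres and
#' are not rounded on read.
#'
#' @param path Path to a CSV file.
#' @param catalog Measurement catalog.
#' @return A validated measurement table tibble.
#' @export
read_measurements <- function(path, catalog = measurement_catalog()) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  measurement_table(df, catalog)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: missing values become empty cells.
#'
#' @param table A measurement table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Restrict to complete cases for a set of measurements
#'
#' Fragmentary fossils contribute unevenly: a specimen enters an analysis
#' only if it is complete for every measurement that analysis uses
#' (listwise deletion per analysis, so each analysis has its own n).
#'
#' @param table A measurement table.
#' @param element Element to keep.
#' @param codes Measurement codes that must all be present.
#' @return The subset of `table`, original row order preserved. An empty
#'   result is returned as-is (downstream operations decide whether that
#'   is an error).
#' @export
complete_cases <- function(table, element, codes) {
  element <- match.arg(element, elements_all())
  valid <- element_codes(element)
  bad <- setdiff(codes, valid)
  if (length(bad) > 0) {
    stop("code(s) not valid for ", element, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- table$element == element
  for (code in codes) keep <- keep & !is.na(table[[code]])
  table[keep, , drop = FALSE]
}

#' Log10-transform one measurement column
#'
#' All likelihood fitting is done on the log10 scale; complete cases must
#' already have been selected for `code`.
#'
#' @param table A measurement table.
#' @param element Element of interest.
#' @param code Measurement code.
#' @return Numeric vector of log10(mm) values, one per record.
#' @export
log10_values <- function(table, element, code) {
  tab <- table[table$element == element, , drop = FALSE]
  x <- tab[[code]]
  if (is.null(x)) stop("unknown measurement code: ", code, call. = FALSE)
  if (anyNA(x)) {
    stop("missing values present for ", code,
         "; select complete cases first", call. = FALSE)
  }
  log10(x)
}

#' Tally a nominal tooth character
#'
#' Counts yes/no over the specimens where the character could be assessed;
#' `indeterminate` records (too fragmentary to judge) are excluded from
#' the assessable n.
#'
#' @param table A measurement table.
#' @param character One of `"tooth_present"`, `"socket_present"`,
#'   `"proximal_eruption"`.
#' @return A list with `yes`, `no`, `indeterminate` counts and
#'   `n_assessable = yes + no`.
#' @export
tally_nominal <- function(table, character) {
  if (!character %in% nominal_characters()) {
    stop("unknown nominal character: ", character, call. = FALSE)
  }
  v <- table[[character]]
  list(
    yes = sum(v == "yes"),
    no = sum(v == "no"),
    indeterminate = sum(v == "indeterminate"),
    n_assessable = sum(v %in% c("yes", "no"))
  )
}
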