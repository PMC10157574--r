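#' Symptom categories annotated on lay descriptions
#'
#' The eleven binary symptom categories used to characterise health-state
#' lay descriptions, in the fixed column order expected by catalog files:
#' mobility, pain, mental symptoms, fatigue, disfigurement, sensory symptoms,
#' infection/diarrhoea, substance use, activities of daily living (ADL),
#' cognitive symptoms, and other physical symptoms.
#'
#' @return Character vector of the 11 category keys (column names are
#'   `flag_<key>`).
#' @export
symptom_categories <- function() {
  c("mobility", "pain", "mental", "fatigue", "disfigurement", "sensory",
    "infection", "substance", "adl", "cognitive", "other")
}

flag_cols <- function() paste0("flag_", symptom_categories())

#' Load a health-state catalog
#'
#' Reads the universe of health states from a headered, comma-delimited
#' UTF-8 file. Required columns: `state_id`, `label`, `lay_description`,
#' the eleven `flag_*` symptom columns (0/1), and `is_phe_anchor` (0/1).
#' An optional `dw_available` column (0/1) marks states for which no
#' disability weight is estimable; it defaults to `TRUE`. Column order is
#' irrelevant: headers are honoured.
#'
#' @param path Path to the catalog file.
#' @return A tibble of class `dw_catalog`, one row per health state,
#'   ordered by `state_id`, with logical flag columns.
#' @seealso [example_catalog()] for the packaged 206-state fixture.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_dw_catalog(raw)
}

#' Validate a data frame as a health-state catalog
#'
#' @param x Data frame with the columns described in [load_catalog()].
#' @return A validated `dw_catalog` tibble ordered by `state_id`.
#' @export
as_dw_catalog <- function(x) {
  x <- as_tibble(x)
  needed <- c("state_id", "label", "lay_description", flag_cols(), "is_phe_anchor")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!("dw_available" %in% names(x))) x$dw_available <- TRUE
  if (nrow(x) > 0 && (anyNA(x$state_id) || !is.numeric(x$state_id))) {
    abort("state_id must be numeric and non-missing")
  }
  x$state_id <- as.integer(x$state_id)
  if (nrow(x) == 0) {
    for (cl in c(flag_cols(), "is_phe_anchor", "dw_available")) {
      x[[cl]] <- logical(0)
    }
    x$label <- character(0)
    x$lay_description <- character(0)
  }
  dup <- unique(x$state_id[duplicated(x$state_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate state_id in catalog: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(x$label) | is.na(x$label))) abort("labels must be non-empty")
  for (cl in c(flag_cols(), "is_phe_anchor", "dw_available")) {
    v <- x[[cl]]
    if (is.logical(v)) next
    if (is.numeric(v) && all(v %in% c(0, 1))) {
      x[[cl]] <- as.logical(v)
    } else {
      abort(paste0("column ", cl, " must be boolean (0/1 or TRUE/FALSE)"))
    }
  }
  x <- dplyr::arrange(x, .data$state_id)
  class(x) <- c("dw_catalog", class(x))
  x
}

#' Write a health-state catalog
#'
#' Inverse of [load_catalog()]: flags are written as 0/1 so the file
#' round-trips to an identical in-memory catalog.
#'
#' @param catalog A `dw_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- as_tibble(catalog)
  for (cl in c(flag_cols(), "is_phe_anchor", "dw_available")) {
    out[[cl]] <- as.integer(out[[cl]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged example catalog of 206 health states
#'
#' The 206 health-state labels of the Wuhan DW survey with synthetic
#' stand-in lay descriptions, synthetic symptom-category flags (keyword
#' seeded, topped up to realistic category frequencies) and a synthetic
#' 28-state population-health-equivalence anchor subset spread across the
#' severity range. State 193 is marked `dw_available = FALSE`. The labels
#' are real; descriptions, flags and the anchor subset are documented
#' stand-ins for unpublished survey annexes.
#'
#' @return A `dw_catalog` tibble with 206 rows.
#' @export
example_catalog <- function() {
  load_catalog(system.file("extdata", "health_states_synthetic.csv",
                           package = "dwkit", mustWork = TRUE))
}

#' Published disability weights of the Wuhan survey
#'
#' The 205 estimated disability weights (with 95% uncertainty intervals)
#' for the 206-state catalog; state 193 has no estimable weight and is
#' absent from the table.
#'
#' @return Tibble with columns `state_id`, `dw`, `ui_low`, `ui_high`.
#' @export
wuhan_dws <- function() {
  readr::read_csv(system.file("extdata", "wuhan_dws.csv",
                              package = "dwkit", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Load a reference disability-weight table
#'
#' Reads an external reference table (e.g. another survey's published DWs)
#' for cross-survey comparison. Weights must lie in \[0, 1\]; a reference of
#' exactly 0 is flagged because it breaks the proportional-difference
#' computation downstream.
#'
#' @param path Two-column file `state_id,dw`.
#' @param catalog A `dw_catalog`; IDs in the catalog but absent from the
#'   reference are reported with a warning.
#' @return Tibble `state_id`, `reference_dw` covering a subset of catalog IDs.
#' @export
load_reference_dws <- function(path, catalog) {
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("state_id", "dw") %in% names(ref))) {
    abort("reference table must have columns state_id, dw")
  }
  if (any(ref$dw < 0 | ref$dw > 1, na.rm = TRUE)) {
    abort("reference dw outside [0, 1]")
  }
  zero <- ref$state_id[!is.na(ref$dw) & ref$dw == 0]
  if (length(zero) > 0) {
    warn(paste0("reference dw of exactly 0 for state(s) ",
                paste(zero, collapse = ", "),
                "; proportional differences are undefined there"))
  }
  miss <- setdiff(catalog$state_id, ref$state_id)
  if (length(miss) > 0) {
    warn(paste0(length(miss), " catalog state(s) missing from reference: ",
                paste(utils::head(miss, 10), collapse = ", "),
                if (length(miss) > 10) ", ..." else ""))
  }
  tibble(state_id = as.integer(ref$state_id), reference_dw = ref$dw)
}
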