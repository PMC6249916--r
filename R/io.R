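#' Read a clinical covariate and outcome table
#'
#' Reads a cohort CSV and validates its structure: `patient_id` plus the
#' time/event columns for the requested endpoints must be present, times
#' must be numeric and nonnegative, event flags 0/1. `"Present"/"Absent"`
#' and `"Yes"/"No"` strings are recoded to 1/0 (Present = 1), with the
#' recoding recorded in the returned attribute `encodings`. Extra columns
#' are preserved untouched; empty strings and `"NA"` become missing
#' values.
#'
#' @param path CSV file path.
#' @param required Required columns besides `patient_id` (default the TTR
#'   and OS time/event columns).
#' @return Data frame with attribute `encodings` (named list of recoded
#'   columns).
#' @export
read_clinical_csv <- function(path,
                              required = c("ttr_months", "ttr_event",
                                           "os_months", "os_event")) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("patient_id", required)
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop_input("missing required column(s): ", paste(miss, collapse = ", "))
  }
  encodings <- list()
  for (nm in setdiff(names(dat), "patient_id")) {
    v <- dat[[nm]]
    if (is.character(v)) {
      u <- unique(stats::na.omit(v))
      if (all(u %in% c("Present", "Absent"))) {
        dat[[nm]] <- as.integer(v == "Present")
        encodings[[nm]] <- c(Present = 1, Absent = 0)
      } else if (all(u %in% c("Yes", "No"))) {
        dat[[nm]] <- as.integer(v == "Yes")
        encodings[[nm]] <- c(Yes = 1, No = 0)
      }
    }
  }
  for (nm in intersect(c("ttr_months", "os_months"), names(dat))) {
    v <- suppressWarnings(as.numeric(dat[[nm]]))
    bad <- which(is.na(v) & !is.na(dat[[nm]]))
    if (length(bad)) {
      stop_input("non-numeric time in column '", nm, "' at row ",
                 bad[1])
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop_input("negative time in column '", nm, "'")
    }
    dat[[nm]] <- v
  }
  for (nm in intersect(c("ttr_event", "os_event"), names(dat))) {
    if (!all(dat[[nm]] %in% c(0, 1, NA))) {
      stop_input("event column '", nm, "' must be 0/1")
    }
  }
  attr(dat, "encodings") <- encodings
  dat
}
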