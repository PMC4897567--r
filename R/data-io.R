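#' Packaged cancer survival datasets
#'
#' Two published randomly right-censored survival datasets shipped as
#' plain-text fixtures:
#' \describe{
#'   \item{\code{"cervical"}}{Survival times in days of 16 cervical-cancer
#'     patients under radiotherapy alone (the control arm of a randomised
#'     radiosensitiser trial); 11 deaths, 5 censored.}
#'   \item{\code{"breast"}}{Survival times in months of 121 breast-cancer
#'     patients treated 1929--1938; 65 deaths, 56 censored.}
#' }
#' Times are stored exactly as published (days, months); the shape estimate
#' of the generalised exponential fit is invariant to the time unit, while
#' the scale estimate transforms as an inverse time.
#'
#' @param name \code{"cervical"} or \code{"breast"}.
#' @return A data frame with columns \code{time} (positive) and
#'   \code{status} (1 = death observed, 0 = censored).
#' @examples
#' d <- gexp_cancer_data("cervical")
#' table(d$status)
#' @export
gexp_cancer_data <- function(name = c("cervical", "breast")) {
  name <- match.arg(name)
  file <- system.file("extdata",
                      paste0(name, "_cancer.csv"), package = "gexpcens",
                      mustWork = TRUE)
  read_survival_table(file)
}

#' Read a censored survival table from a delimited text file
#'
#' Reads a header-ed delimited file (comma, tab or semicolon are detected
#' from the header line) into a validated censored sample.
#'
#' @param path file path.
#' @param time_col,status_col column names holding times and indicators.
#' @param status_is_event if \code{TRUE} (default) the status column marks
#'   events (1 = failure); if \code{FALSE} it marks censoring and is
#'   flipped on input.
#' @return A data frame with columns \code{time} and \code{status}
#'   (1 = event).
#' @export
read_survival_table <- function(path, time_col = "time",
                                status_col = "status",
                                status_is_event = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  for (col in c(time_col, status_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")")
  tm <- df[[time_col]]
  st <- df[[status_col]]
  if (!is.numeric(tm) || any(!is.finite(tm)))
    stop("non-numeric or non-finite time in row(s) ",
         paste(which(!is.finite(suppressWarnings(as.numeric(tm)))),
               collapse = ", "))
  if (any(tm < 0))
    stop("negative time in row(s) ", paste(which(tm < 0), collapse = ", "))
  bad <- !(st %in% c(0, 1))
  if (any(bad))
    stop("status outside {0,1} in row(s) ", paste(which(bad), collapse = ", "))
  if (!status_is_event) st <- 1 - st
  out <- data.frame(time = tm, status = as.integer(st))
  check_sample(out$time, out$status)
  out
}
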