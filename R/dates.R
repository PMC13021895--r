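#' Parse FAERS date strings
#'
#' FAERS distributes dates as plain digit strings: a full date is 8 digits
#' (`YYYYMMDD`), a month-precision date 6 digits (`YYYYMM`) and a
#' year-precision date 4 digits (`YYYY`). Anything else is classified as
#' `invalid`; empty or `NA` input is `missing`. An 8-digit string must also
#' be a real calendar date (so `"20230230"` is `invalid`), and a 6-digit
#' string must name a month 01-12. The parser never raises on malformed
#' input: every string gets a precision class.
#'
#' @param x character vector of raw date strings.
#' @return A data.frame with one row per input: `text` (trimmed input),
#'   `precision` (one of `"day"`, `"month"`, `"year"`, `"missing"`,
#'   `"invalid"`) and `date` (a `Date`, `NA` unless precision is `"day"`).
#' @examples
#' parse_faers_date(c("20230101", "202302", "2023", "20230230", ""))
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  text <- trimws(x)
  text[is.na(x)] <- ""
  n <- length(text)
  precision <- rep("invalid", n)
  date <- rep(as.Date(NA), n)

  precision[text == ""] <- "missing"
  digits <- grepl("^[0-9]+$", text)

  is8 <- digits & nchar(text) == 8L
  if (any(is8)) {
    # parse each distinct string once; real tables repeat dates heavily
    ux <- unique(text[is8])
    du <- as.Date(ux, format = "%Y%m%d")
    # strptime rolls some impossible dates; formatting back catches them all
    oku <- !is.na(du) & format(du, "%Y%m%d") == ux
    idx <- match(text[is8], ux)
    ok <- oku[idx]
    precision[is8][ok] <- "day"
    date[is8][ok] <- du[idx][ok]
  }

  is6 <- digits & nchar(text) == 6L
  if (any(is6)) {
    mon <- as.integer(substr(text[is6], 5L, 6L))
    precision[is6][mon >= 1L & mon <= 12L] <- "month"
  }

  precision[digits & nchar(text) == 4L] <- "year"

  data.frame(text = text, precision = precision, date = date,
             stringsAsFactors = FALSE)
}

#' Convert a reported age to years
#'
#' FAERS ages come with a unit code (`AGE_COD`). Decades are multiplied by
#' 10; months, weeks and days are divided by 12, 52 and 365.25. Hours are
#' treated as unknown (they occur only in neonatal reports and carry no
#' resolution at the year scale used here). A missing value or an
#' unrecognized unit yields `NA`.
#'
#' @param value numeric or character vector of age values.
#' @param unit character vector of FAERS unit codes (`YR`, `DEC`, `MON`,
#'   `WK`, `DY`; case-insensitive; also accepts spelled-out forms).
#' @return numeric vector of ages in years (`NA` where unknown).
#' @export
age_in_years <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  u <- toupper(trimws(as.character(unit)))
  factor <- rep(NA_real_, length(v))
  factor[u %in% c("YR", "YEAR", "YEARS")] <- 1
  factor[u %in% c("DEC", "DECADE", "DECADES")] <- 10
  factor[u %in% c("MON", "MONTH", "MONTHS")] <- 1 / 12
  factor[u %in% c("WK", "WEEK", "WEEKS")] <- 1 / 52
  factor[u %in% c("DY", "DAY", "DAYS")] <- 1 / 365.25
  out <- v * factor
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

#' Convert a reported weight to kilograms
#'
#' @param value numeric or character vector of weights.
#' @param unit character vector of FAERS weight unit codes (`KG`, `LBS`,
#'   `GMS`); unknown units yield `NA`.
#' @return numeric vector of weights in kg.
#' @export
weight_in_kg <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  u <- toupper(trimws(as.character(unit)))
  factor <- rep(NA_real_, length(v))
  factor[u %in% c("KG", "KGS", "")] <- 1
  factor[u %in% c("LBS", "LB")] <- 0.45359237
  factor[u %in% c("GMS", "G")] <- 1 / 1000
  # FAERS leaves WT_COD blank for many kg entries; blank counts as kg only
  # when a value is present
  out <- v * factor
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}
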