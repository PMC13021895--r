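#' @keywords internal
"_PACKAGE"

# Canonical column bindings per table kind. Each canonical name maps to the
# FAERS header aliases it may appear under (schemas drift across quarters;
# binding is by case-insensitive header name, never by position).
.faers_schema <- list(
  DEMO = list(
    mandatory = c(primaryid = "PRIMARYID", caseid = "CASEID"),
    optional = list(
      fda_dt = c("FDA_DT", "INIT_FDA_DT"),
      event_dt = "EVENT_DT",
      sex = c("SEX", "GNDR_COD"),
      age = "AGE", age_cod = "AGE_COD",
      occp_cod = "OCCP_COD",
      country = c("REPORTER_COUNTRY", "OCCR_COUNTRY", "COUNTRY"),
      wt = "WT", wt_cod = "WT_COD"
    )
  ),
  DRUG = list(
    mandatory = c(primaryid = "PRIMARYID"),
    optional = list(
      drug_seq = c("DRUG_SEQ", "DSG_DRUG_SEQ"),
      role_code = "ROLE_COD",
      drug_name = "DRUGNAME",
      prod_ai = "PROD_AI",
      route = "ROUTE",
      start_dt = "START_DT"
    )
  ),
  REAC = list(
    mandatory = c(primaryid = "PRIMARYID"),
    optional = list(pt = "PT")
  ),
  OUTC = list(
    mandatory = c(primaryid = "PRIMARYID"),
    optional = list(outcome_code = c("OUTC_COD", "OUTC_CODE"))
  ),
  THER = list(
    mandatory = c(primaryid = "PRIMARYID"),
    optional = list(
      drug_seq = c("DSG_DRUG_SEQ", "DRUG_SEQ"),
      start_dt = "START_DT", end_dt = "END_DT"
    )
  ),
  INDI = list(
    mandatory = c(primaryid = "PRIMARYID"),
    optional = list(
      drug_seq = c("INDI_DRUG_SEQ", "DRUG_SEQ"),
      indi_pt = "INDI_PT"
    )
  ),
  DELETED = list(
    mandatory = c(caseid = "CASEID"),
    optional = list()
  )
)

# FAERS header names used when writing, in output order.
.faers_out_cols <- list(
  DEMO = c(PRIMARYID = "primaryid", CASEID = "caseid", FDA_DT = "fda_dt",
           EVENT_DT = "event_dt", SEX = "sex", AGE = "age",
           AGE_COD = "age_cod", OCCP_COD = "occp_cod",
           REPORTER_COUNTRY = "country", WT = "wt", WT_COD = "wt_cod"),
  DRUG = c(PRIMARYID = "primaryid", DRUG_SEQ = "drug_seq",
           ROLE_COD = "role_code", DRUGNAME = "drug_name",
           PROD_AI = "prod_ai", ROUTE = "route", START_DT = "start_dt"),
  REAC = c(PRIMARYID = "primaryid", PT = "pt"),
  OUTC = c(PRIMARYID = "primaryid", OUTC_COD = "outcome_code"),
  THER = c(PRIMARYID = "primaryid", DSG_DRUG_SEQ = "drug_seq",
           START_DT = "start_dt", END_DT = "end_dt"),
  INDI = c(PRIMARYID = "primaryid", INDI_DRUG_SEQ = "drug_seq",
           INDI_PT = "indi_pt"),
  DELETED = c(CASEID = "caseid")
)

#' Read a FAERS-style quarterly ASCII table
#'
#' FAERS quarterly extracts are `$`-delimited text files with a header row,
#' distributed in latin-1 encoding. This reader binds columns by
#' case-insensitive header name (column order in the file is irrelevant),
#' ignores columns it does not know, skips and counts lines whose field
#' count does not match the header, and parses the fields each table kind
#' needs: dates are classified by [parse_faers_date()], sex and drug role
#' codes are mapped to closed vocabularies, ages to years and weights to kg.
#'
#' @param path path to the table file.
#' @param kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`,
#'   `"INDI"`, `"DELETED"`.
#' @param sep field delimiter, `"$"` in FAERS distributions.
#' @param encoding file encoding; undecodable bytes are replaced.
#' @return A data.frame of parsed records (one per surviving data line,
#'   in file order) with canonical lower-case columns; derived columns
#'   (`*_date`, `*_prec`, `age_years`, `weight_kg`) sit beside the raw text
#'   fields. The number of skipped malformed lines is attached as attribute
#'   `"n_skipped"`.
#' @seealso [write_faers_table()], [parse_faers_records()]
#' @export
read_faers_table <- function(path, kind, sep = "$", encoding = "latin1") {
  kind <- match.arg(toupper(kind), names(.faers_schema))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = encoding, warn = FALSE)
  lines <- iconv(lines, from = encoding, to = "UTF-8", sub = "?")
  if (length(lines) == 0L) stop("empty file (no header row): ", path)
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]

  fields <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty field is dropped by strsplit; tolerate one short
  ok <- nf == length(header) | nf == length(header) - 1L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message("read_faers_table: skipped ", n_skipped,
            " malformed line(s) in ", basename(path))
  }
  fields <- fields[ok]
  if (length(fields) == 0L) {
    raw <- as.data.frame(matrix(character(0), nrow = 0,
                                ncol = length(header)),
                         stringsAsFactors = FALSE)
  } else {
    raw <- as.data.frame(
      do.call(rbind, lapply(fields, function(f) {
        length(f) <- length(header)
        f
      })),
      stringsAsFactors = FALSE
    )
  }
  names(raw) <- header
  out <- parse_faers_records(raw, kind)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Parse a raw FAERS table into canonical records
#'
#' Takes a data.frame of character columns carrying FAERS header names (as
#' read from file or produced by [generate_faers()]) and returns the
#' canonical parsed records for `kind`. Exposed separately so in-memory
#' synthetic tables take the same code path as files.
#'
#' @param raw data.frame of character columns named with FAERS headers.
#' @inheritParams read_faers_table
#' @return data.frame of parsed records; see [read_faers_table()].
#' @export
parse_faers_records <- function(raw, kind) {
  kind <- match.arg(toupper(kind), names(.faers_schema))
  schema <- .faers_schema[[kind]]
  hdr <- toupper(trimws(names(raw)))

  pick <- function(aliases) {
    idx <- match(toupper(aliases), hdr)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    col <- as.character(raw[[idx[[1L]]]])
    col[is.na(col)] <- ""
    # trim only the entries that need it; most fields are already clean
    ws <- grepl("^[ \t\r]|[ \t\r]$", col, perl = TRUE)
    if (any(ws)) col[ws] <- trimws(col[ws])
    col
  }

  n <- nrow(raw)
  out <- list()
  for (canon in names(schema$mandatory)) {
    col <- pick(schema$mandatory[[canon]])
    if (is.null(col)) {
      stop("mandatory column '", schema$mandatory[[canon]],
           "' missing from ", kind, " table")
    }
    out[[canon]] <- col
  }
  for (canon in names(schema$optional)) {
    col <- pick(schema$optional[[canon]])
    out[[canon]] <- if (is.null(col)) rep("", n) else col
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  if (kind == "DEMO") {
    bad <- !nzchar(out$primaryid)
    if (any(bad)) out <- out[!bad, , drop = FALSE]
    fda <- parse_faers_date(out$fda_dt)
    evt <- parse_faers_date(out$event_dt)
    out$fda_dt <- fda$text
    out$fda_dt_prec <- fda$precision
    out$fda_dt_date <- fda$date
    out$event_dt <- evt$text
    out$event_dt_prec <- evt$precision
    out$event_dt_date <- evt$date
    sx <- toupper(out$sex)
    out$sex <- ifelse(sx %in% c("F", "FEMALE"), "F",
                      ifelse(sx %in% c("M", "MALE"), "M", "unknown"))
    out$age_years <- age_in_years(out$age, out$age_cod)
    out$weight_kg <- weight_in_kg(out$wt, out$wt_cod)
  } else if (kind == "DRUG") {
    rc <- toupper(out$role_code)
    out$role_code <- ifelse(rc %in% c("PS", "SS", "C", "I"), rc, "unknown")
    st <- parse_faers_date(out$start_dt)
    out$start_dt <- st$text
    out$start_dt_prec <- st$precision
    out$start_dt_date <- st$date
  } else if (kind == "REAC") {
    out$pt <- gsub("[[:space:]]+", " ", out$pt)
    out <- out[nzchar(out$pt) & nzchar(out$primaryid), , drop = FALSE]
  } else if (kind == "THER") {
    st <- parse_faers_date(out$start_dt)
    out$start_dt <- st$text
    out$start_dt_prec <- st$precision
    out$start_dt_date <- st$date
  }
  if (kind != "DELETED") {
    out <- out[nzchar(out$primaryid), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write records back to a FAERS-style ASCII table
#'
#' The inverse of [read_faers_table()]: canonical records are rendered to
#' the `$`-delimited format with standard FAERS header names. Derived
#' columns are not written; re-reading the file reproduces every parsed
#' field (reading is idempotent on its own output).
#'
#' @param records data.frame of canonical records (or raw FAERS-named
#'   character columns, which are passed through).
#' @inheritParams read_faers_table
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path, kind, sep = "$") {
  kind <- match.arg(toupper(kind), names(.faers_schema))
  spec <- .faers_out_cols[[kind]]
  cols <- lapply(seq_along(spec), function(i) {
    canon <- spec[[i]]
    faers_name <- names(spec)[[i]]
    if (canon %in% names(records)) as.character(records[[canon]])
    else if (faers_name %in% names(records)) as.character(records[[faers_name]])
    else rep("", nrow(records))
  })
  lines <- c(paste(names(spec), collapse = sep),
             if (nrow(records) > 0)
               do.call(paste, c(cols, list(sep = sep))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
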