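#' Normalize a term for dictionary lookups
#'
#' Trims, collapses internal whitespace and upper-cases. Used for MedDRA
#' PT keys, where coding is case-insensitive.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  toupper(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Normalize a drug name for lexicon matching
#'
#' Like [normalize_term()] but punctuation is replaced by spaces first, so
#' "Amoxicillin/Clavulanate" and "AMOXICILLIN CLAVULANATE" normalize to the
#' same key.
#'
#' @param x character vector of drug or active-ingredient names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  normalize_term(gsub("[[:punct:]]+", " ", as.character(x)))
}

#' Construct a drug lexicon
#'
#' A lexicon defines one drug cohort: a target label, the set of name
#' synonyms that identify the drug, and an exclusion set of names that must
#' never match (typically combination-product names, so a combination cohort
#' and a monotherapy cohort can be made disjoint by construction). A drug
#' record matches the lexicon when its normalized `DRUGNAME` or `PROD_AI`
#' equals a synonym and neither field equals an exclusion. Matching is
#' exact after normalization, never substring.
#'
#' @param target_label display label for the cohort.
#' @param synonyms character vector of names identifying the drug.
#' @param exclusions character vector of names that must not match.
#' @return an object of class `drug_lexicon`.
#' @export
drug_lexicon <- function(target_label, synonyms, exclusions = character(0)) {
  syn <- unique(normalize_drug_name(synonyms))
  syn <- syn[nzchar(syn)]
  exc <- unique(normalize_drug_name(exclusions))
  exc <- exc[nzchar(exc)]
  if (length(syn) == 0L) stop("lexicon needs at least one synonym")
  overlap <- intersect(syn, exc)
  if (length(overlap) > 0L) {
    stop("lexicon synonyms and exclusions overlap: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(target_label = target_label, synonyms = syn,
                 exclusions = exc),
            class = "drug_lexicon")
}

#' Read a drug lexicon file
#'
#' Plain-text format with `[synonyms]` and `[exclusions]` section headers,
#' one name per line; `#` starts a comment. An optional `[target]` section
#' holds the display label (default: the first synonym).
#'
#' @param path path to the lexicon file.
#' @return a `drug_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- "synonyms"
  target <- NULL
  syn <- character(0)
  exc <- character(0)
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    if (section == "target") target <- ln
    else if (section == "synonyms") syn <- c(syn, ln)
    else if (section == "exclusions") exc <- c(exc, ln)
    else stop("unknown lexicon section: [", section, "]")
  }
  if (is.null(target)) target <- if (length(syn)) syn[[1L]] else ""
  drug_lexicon(target, syn, exc)
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon>", x$target_label, "-", length(x$synonyms),
      "synonym(s),", length(x$exclusions), "exclusion(s)\n")
  invisible(x)
}

#' Match drug records against a lexicon
#'
#' @param drug_name,prod_ai character vectors (recycled against each other).
#' @param lexicon a [drug_lexicon()].
#' @return logical vector: record names match a synonym and no field matches
#'   an exclusion.
#' @export
lexicon_match <- function(drug_name, prod_ai, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  dn <- normalize_drug_name(drug_name)
  ai <- normalize_drug_name(prod_ai)
  hit <- dn %in% lexicon$synonyms | ai %in% lexicon$synonyms
  excluded <- dn %in% lexicon$exclusions | ai %in% lexicon$exclusions
  hit & !excluded
}

#' Construct a PT-to-SOC mapping
#'
#' MedDRA assigns each Preferred Term to one or more System Organ Classes.
#' MedDRA itself is licensed, so the mapping is supplied by the user as a
#' two-column table. Lookups are case-insensitive after whitespace
#' normalization; a PT may map to several SOCs; an unmapped PT yields an
#' empty result, never an error.
#'
#' @param pt,soc character vectors of equal length (duplicate rows merged).
#' @return an object of class `soc_mapping`.
#' @export
soc_mapping <- function(pt, soc) {
  pt <- normalize_term(pt)
  soc <- gsub("[[:space:]]+", " ", trimws(as.character(soc)))
  keep <- nzchar(pt)
  if (any(keep & !nzchar(soc))) {
    stop("PT row(s) with empty SOC: ",
         paste(utils::head(pt[keep & !nzchar(soc)], 3), collapse = ", "))
  }
  pt <- pt[keep]; soc <- soc[keep]
  pairs <- unique(data.frame(pt = pt, soc = soc, stringsAsFactors = FALSE))
  structure(list(entries = split(pairs$soc, pairs$pt)),
            class = "soc_mapping")
}

#' Read a tab-separated PT-to-SOC mapping file
#'
#' @param path path to a two-column (PT, SOC) tab-separated file; a header
#'   row is detected and skipped when its first field is `PT` (any case).
#' @return a [soc_mapping()].
#' @export
read_soc_mapping <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("SOC mapping must have two tab-separated columns")
  if (nrow(raw) > 0L && toupper(trimws(raw[1L, 1L])) == "PT") {
    raw <- raw[-1L, , drop = FALSE]
  }
  soc_mapping(raw[[1L]], raw[[2L]])
}

#' Look up the SOCs of Preferred Terms
#'
#' @param mapping a [soc_mapping()].
#' @param pt character vector of PT strings (any case/spacing).
#' @return a list, one character vector of SOC names per input PT
#'   (`character(0)` for unmapped PTs).
#' @export
soc_lookup <- function(mapping, pt) {
  stopifnot(inherits(mapping, "soc_mapping"))
  key <- normalize_term(pt)
  out <- mapping$entries[key]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  names(out) <- pt
  out
}

#' @export
print.soc_mapping <- function(x, ...) {
  cat("<soc_mapping>", length(x$entries), "PT(s),",
      length(unique(unlist(x$entries))), "SOC(s)\n")
  invisible(x)
}
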