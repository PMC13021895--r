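# Fixture builders and independent oracles shared across the test files.
# Oracles are written as plain scalar code, structurally unlike the
# vectorized implementations they check.

# --- raw table builders ----------------------------------------------------

raw_demo <- function(primaryid, caseid, fda_dt = "20230101",
                     event_dt = "", sex = "F", age = "", age_cod = "",
                     occp_cod = "", country = "US", wt = "", wt_cod = "") {
  n <- length(primaryid)
  r <- function(x) rep_len(as.character(x), n)
  data.frame(PRIMARYID = as.character(primaryid), CASEID = r(caseid),
             FDA_DT = r(fda_dt), EVENT_DT = r(event_dt), SEX = r(sex),
             AGE = r(age), AGE_COD = r(age_cod), OCCP_COD = r(occp_cod),
             REPORTER_COUNTRY = r(country), WT = r(wt), WT_COD = r(wt_cod),
             stringsAsFactors = FALSE)
}

raw_drug <- function(primaryid, drugname, role = "PS", start_dt = "",
                     prod_ai = drugname, route = "Oral", seq = "1") {
  data.frame(PRIMARYID = as.character(primaryid), DRUG_SEQ = seq,
             ROLE_COD = role, DRUGNAME = drugname, PROD_AI = prod_ai,
             ROUTE = route, START_DT = start_dt, stringsAsFactors = FALSE)
}

raw_reac <- function(primaryid, pt) {
  data.frame(PRIMARYID = as.character(primaryid), PT = pt,
             stringsAsFactors = FALSE)
}

# A tiny ready-made database: 6 reports, drug A cohort of 3.
toy_tables <- function() {
  demo <- raw_demo(primaryid = 101:106, caseid = 1:6,
                   fda_dt = rep("20230110", 6),
                   event_dt = c("20230105", "20230106", "", "20230107",
                                "20230108", "20230109"),
                   sex = c("F", "M", "F", "M", "F", "unknown"),
                   age = c("30", "70", "", "45", "61", "20"),
                   age_cod = c("YR", "YR", "", "YR", "YR", "YR"))
  drug <- raw_drug(primaryid = 101:106,
                   drugname = c("DRUG A", "DRUG A", "DRUG A",
                                "DRUG B", "DRUG B", "DRUG B"),
                   role = c("PS", "PS", "PS", "PS", "PS", "PS"),
                   start_dt = c("20230101", "20230102", "", "20230103",
                                "20230104", "20230105"))
  reac <- raw_reac(primaryid = c(101, 101, 102, 103, 104, 105, 106),
                   pt = c("PT1", "PT2", "PT1", "PT2", "PT1", "PT2", "PT2"))
  list(DEMO = demo, DRUG = drug, REAC = reac)
}

parsed_toy <- function() {
  t <- toy_tables()
  list(demo = parse_faers_records(t$DEMO, "DEMO"),
       drug = parse_faers_records(t$DRUG, "DRUG"),
       reac = parse_faers_records(t$REAC, "REAC"))
}

toy_reports <- function() {
  p <- parsed_toy()
  assemble_reports(p$demo, p$drug, p$reac)
}

# --- independent oracles ---------------------------------------------------

# Calendar validity without strptime: explicit leap-year and days-in-month
# arithmetic.
oracle_valid_ymd <- function(y, m, d) {
  if (m < 1 || m > 12 || d < 1) return(FALSE)
  leap <- (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)
  dim <- c(31, if (leap) 29 else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <= dim[m]
}

oracle_date_precision <- function(s) {
  s <- trimws(s)
  if (is.na(s) || s == "") return("missing")
  if (!grepl("^[0-9]+$", s)) return("invalid")
  if (nchar(s) == 4) return("year")
  if (nchar(s) == 6) {
    m <- as.integer(substr(s, 5, 6))
    return(if (m >= 1 && m <= 12) "month" else "invalid")
  }
  if (nchar(s) == 8) {
    ok <- oracle_valid_ymd(as.integer(substr(s, 1, 4)),
                           as.integer(substr(s, 5, 6)),
                           as.integer(substr(s, 7, 8)))
    return(if (ok) "day" else "invalid")
  }
  "invalid"
}

# Group-sort-take-last deduplication: for each caseid keep the record with
# the largest (fda_dt, numeric primaryid).
oracle_dedup <- function(demo) {
  kept <- character(0)
  for (cid in unique(demo$caseid)) {
    grp <- demo[demo$caseid == cid, , drop = FALSE]
    best <- 1L
    for (i in seq_len(nrow(grp))) {
      fi <- grp$fda_dt_date[i]; fb <- grp$fda_dt_date[best]
      pi <- as.numeric(grp$primaryid[i]); pb <- as.numeric(grp$primaryid[best])
      if (is.na(fb) || (!is.na(fi) && (fi > fb || (fi == fb && pi > pb)))) {
        best <- i
      } else if (is.na(fi) && is.na(fb) && pi > pb) {
        best <- i
      }
    }
    kept <- c(kept, grp$primaryid[best])
  }
  sort(kept)
}

# Loop-based 2x2 cell counts from report-level event sets.
oracle_cells <- function(report_ids, cohort_ids, event_sets, event) {
  a <- b <- cc <- d <- 0L
  for (id in report_ids) {
    has <- event %in% event_sets[[id]]
    if (id %in% cohort_ids) {
      if (has) a <- a + 1L else b <- b + 1L
    } else {
      if (has) cc <- cc + 1L else d <- d + 1L
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# Sort-and-interpolate quantile (type 7): h = (n-1)p + 1, linear between
# order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Scalar log-space evaluation of the five statistics (independent of the
# vectorized implementations).
oracle_stats <- function(a, b, c, d, z = 1.96) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  lror <- log(a) + log(d) - log(b) - log(c)
  se_r <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lprr <- (log(a) - log(a + b)) - (log(c) - log(c + d))
  se_p <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  lrrr <- log(a) + log(n) - log(a + b) - log(a + c)
  # BCPNN closed form, priors gamma_ij = alpha_i = beta_j = 1,
  # alpha = beta = 2
  g <- (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  eic <- (log(a + 1) + 2 * log(n + 2) -
            log(n + g) - log(a + b + 1) - log(a + c + 1)) / log(2)
  vic <- ((n - a + g - 1) / ((a + 1) * (1 + n + g)) +
            (n - a - b + 1) / ((a + b + 1) * (1 + n + 2)) +
            (n - a - c + 1) / ((a + c + 1) * (1 + n + 2))) / log(2)^2
  list(ror = exp(lror), ror_lo = exp(lror - z * se_r),
       ror_hi = exp(lror + z * se_r),
       prr = exp(lprr), prr_lo = exp(lprr - z * se_p),
       prr_hi = exp(lprr + z * se_p),
       chi2 = chi2,
       ic = lrrr / log(2), ic_expect = eic, ic_var = vic,
       ic025 = eic - 2 * sqrt(vic),
       ebgm = exp(lrrr), ebgm05 = exp(lrrr - z * se_r),
       ebgm95 = exp(lrrr + z * se_r))
}

# Group-sort-filter oracle over a whole cleaning run: dedup by case,
# drop deleted caseids, drop reports with a day-precision start after a
# day-precision event or a non-day FDA_DT. Returns surviving primaryids.
oracle_clean <- function(demo, deleted, start_by_pid, event_by_pid) {
  keep <- character(0)
  for (pid in oracle_dedup(demo)) {
    cid <- demo$caseid[demo$primaryid == pid]
    if (cid %in% deleted) next
    fda <- demo$fda_dt[demo$primaryid == pid]
    if (oracle_date_precision(fda) != "day") next
    st <- start_by_pid[[pid]]
    ev <- event_by_pid[[pid]]
    bad <- FALSE
    if (!is.null(st) && !is.null(ev) &&
        oracle_date_precision(ev) == "day") {
      for (s in st) {
        if (oracle_date_precision(s) == "day" &&
            as.Date(s, "%Y%m%d") > as.Date(ev, "%Y%m%d")) bad <- TRUE
      }
    }
    if (!bad) keep <- c(keep, pid)
  }
  sort(keep)
}

# Random DEMO fixture with planted caseid collisions and fda_dt ties.
random_demo_fixture <- function(n = 20) {
  cid <- sample(1:8, n, replace = TRUE)
  fda <- sample(c("20230101", "20230215", "20230301"), n, replace = TRUE)
  pid <- sample(1000:9999, n)
  raw <- raw_demo(primaryid = pid, caseid = cid, fda_dt = fda)
  parse_faers_records(raw, "DEMO")
}
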