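#' Default signal-detection thresholds
#'
#' The joint criterion declares a drug-event pair a signal only when all
#' four algorithms fire simultaneously, with at least `min_a` reports:
#' ROR >= 2 with 95% CI lower limit > 1; PRR >= 2 with 95% CI lower limit
#' > 1; IC025 > 0; EBGM05 > 2. Point thresholds are inclusive (>=),
#' interval-bound thresholds strict (>).
#'
#' @param min_a minimum report count gating all four algorithms.
#' @param ror_min,ror_ci_lo_min ROR point / CI lower-limit thresholds.
#' @param prr_min,prr_ci_lo_min PRR point / CI lower-limit thresholds.
#' @param ic025_min IC025 threshold.
#' @param ebgm05_min EBGM05 threshold.
#' @return a named list of thresholds.
#' @export
default_thresholds <- function(min_a = 3, ror_min = 2, ror_ci_lo_min = 1,
                               prr_min = 2, prr_ci_lo_min = 1,
                               ic025_min = 0, ebgm05_min = 2) {
  list(min_a = min_a, ror_min = ror_min, ror_ci_lo_min = ror_ci_lo_min,
       prr_min = prr_min, prr_ci_lo_min = prr_ci_lo_min,
       ic025_min = ic025_min, ebgm05_min = ebgm05_min)
}

#' Default BCPNN priors
#'
#' The closed-form BCPNN uses a Dirichlet prior on the joint cell
#' (`gamma_ij`) and Beta priors on the two margins. The defaults are the
#' standard single-drug/single-event choice: `gamma_ij = 1`,
#' `alpha_i = beta_j = 1`, `alpha = beta = 2`, under which an independence
#' table has E(IC) = 0 exactly.
#'
#' @param gamma_ij,alpha_i,beta_j,alpha,beta positive prior parameters.
#' @return a named list of priors.
#' @export
bcpnn_priors <- function(gamma_ij = 1, alpha_i = 1, beta_j = 1,
                         alpha = 2, beta = 2) {
  p <- list(gamma_ij = gamma_ij, alpha_i = alpha_i, beta_j = beta_j,
            alpha = alpha, beta = beta)
  if (any(unlist(p) <= 0)) stop("BCPNN priors must be positive")
  p
}

# Applicability of the frequentist ratio statistics: a >= min_a (the
# statistics are not applicable below three reports) and no zero cell (no
# continuity correction is applied).
.ratio_applicable <- function(a, b, c, d, min_a) {
  a >= min_a & b > 0 & c > 0 & d > 0
}

# counts arrive as integers; products like a*d overflow 32-bit range on
# large databases, so all statistics work in doubles
.as_cells <- function(a, b, c, d) {
  list(a = as.numeric(a), b = as.numeric(b),
       c = as.numeric(c), d = as.numeric(d))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a/c)/(b/d) = ad/(bc), with the log-symmetric Woolf interval
#' `exp(log(ROR) +/- 1.96*sqrt(1/a + 1/b + 1/c + 1/d))`. Not applicable
#' (all `NA`) when `a < min_a` or any of `b`, `c`, `d` is zero.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized).
#' @param min_a minimum event count for applicability (default 3).
#' @param conf_z normal quantile for the interval (1.96 for 95%).
#' @return data.frame with `ror`, `ror_lo`, `ror_hi`.
#' @export
compute_ror <- function(a, b, c, d, min_a = 3, conf_z = 1.96) {
  cl <- .as_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  ok <- .ratio_applicable(a, b, c, d, min_a)
  est <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = est,
             ror_lo = exp(log(est) - conf_z * se),
             ror_hi = exp(log(est) + conf_z * se))
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\], with interval
#' `exp(log(PRR) +/- 1.96*sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' Applicability as in [compute_ror()].
#'
#' @inheritParams compute_ror
#' @return data.frame with `prr`, `prr_lo`, `prr_hi`.
#' @export
compute_prr <- function(a, b, c, d, min_a = 3, conf_z = 1.96) {
  cl <- .as_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  ok <- .ratio_applicable(a, b, c, d, min_a)
  est <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  data.frame(prr = est,
             prr_lo = exp(log(est) - conf_z * se),
             prr_hi = exp(log(est) + conf_z * se))
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' `N*(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with Yates' correction,
#' `|ad - bc|` is reduced by `N/2` (floored at zero) before squaring. A
#' table with any zero margin is degenerate and returns 0. Reported
#' alongside the four algorithms but not part of the joint signal
#' criterion.
#'
#' @inheritParams compute_ror
#' @param yates apply the continuity correction.
#' @return numeric vector of chi-squared values.
#' @export
compute_chi2 <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  mprod <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  ifelse(mprod > 0, n * dev^2 / mprod, 0)
}

#' BCPNN information component and credibility bound
#'
#' The information component is `IC = log2(a*N / ((a+b)*(a+c)))`, the
#' observed-to-expected ratio on the log2 scale. Its posterior expectation
#' and variance under Dirichlet/Beta priors follow the standard closed
#' form: with `gamma = gamma_ij*(N+alpha)*(N+beta) /
#' ((a+b+alpha_i)*(a+c+beta_j))`,
#' `E(IC) = log2((a+gamma_ij)*(N+alpha)*(N+beta) /
#' ((N+gamma)*(a+b+alpha_i)*(a+c+beta_j)))` and
#' `V(IC) = (1/ln2^2) * ((N-a+gamma-gamma_ij)/((a+gamma_ij)*(1+N+gamma)) +
#' (N-(a+b)+alpha-alpha_i)/((a+b+alpha_i)*(1+N+alpha)) +
#' (N-(a+c)+beta-beta_j)/((a+c+beta_j)*(1+N+beta)))`. The lower
#' credibility bound is `IC025 = E(IC) - 2*sqrt(V(IC))` (factor 2 by
#' convention for this closed form).
#'
#' @inheritParams compute_ror
#' @param priors a [bcpnn_priors()] list.
#' @return data.frame with `ic`, `ic_expect`, `ic_var`, `ic025`.
#' @export
compute_bcpnn <- function(a, b, c, d, priors = bcpnn_priors()) {
  cl <- .as_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  m1 <- a + b
  m2 <- a + c
  ok <- n > 0 & m1 > 0 & m2 > 0
  ic <- ifelse(ok & a > 0, log2(a * n / (m1 * m2)),
               ifelse(ok, -Inf, NA_real_))
  g <- priors$gamma_ij * (n + priors$alpha) * (n + priors$beta) /
    ((m1 + priors$alpha_i) * (m2 + priors$beta_j))
  eic <- ifelse(ok,
                log2((a + priors$gamma_ij) * (n + priors$alpha) *
                       (n + priors$beta) /
                       ((n + g) * (m1 + priors$alpha_i) *
                          (m2 + priors$beta_j))),
                NA_real_)
  vic <- ifelse(ok,
                ((n - a + g - priors$gamma_ij) /
                   ((a + priors$gamma_ij) * (1 + n + g)) +
                   (n - m1 + priors$alpha - priors$alpha_i) /
                   ((m1 + priors$alpha_i) * (1 + n + priors$alpha)) +
                   (n - m2 + priors$beta - priors$beta_j) /
                   ((m2 + priors$beta_j) * (1 + n + priors$beta))) /
                  log(2)^2,
                NA_real_)
  data.frame(ic = ic, ic_expect = eic, ic_var = vic,
             ic025 = eic - 2 * sqrt(vic))
}

#' Closed-form EBGM (relative reporting ratio) with 95% interval
#'
#' As used here, EBGM is the relative reporting ratio
#' `a*N / ((a+b)*(a+c))` — identical to `2^IC` — with a log-symmetric
#' interval using the same standard error as the ROR. No empirical-Bayes
#' shrinkage is applied (true Gamma-Poisson shrinkage is a deliberate
#' non-goal; see the package vignette). Applicability as in
#' [compute_ror()].
#'
#' @inheritParams compute_ror
#' @return data.frame with `ebgm`, `ebgm05`, `ebgm95`.
#' @export
compute_ebgm <- function(a, b, c, d, min_a = 3, conf_z = 1.96) {
  cl <- .as_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  ok <- .ratio_applicable(a, b, c, d, min_a)
  n <- a + b + c + d
  est <- ifelse(ok, a * n / ((a + b) * (a + c)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ebgm = est,
             ebgm05 = exp(log(est) - conf_z * se),
             ebgm95 = exp(log(est) + conf_z * se))
}

#' Upper bound of a log-symmetric interval from point and lower bound
#'
#' For every interval of the form `exp(log(x) +/- z*se)`, the upper bound
#' equals `point^2 / lower`. Useful for auditing published tables that
#' print point, lower and upper values.
#'
#' @param point,lower point estimate and lower bound (vectorized).
#' @return the implied upper bound.
#' @export
ci_upper_from_lower <- function(point, lower) {
  point^2 / lower
}

#' Apply the joint signal criterion
#'
#' @param stats a data.frame carrying `a`, `ror`, `ror_lo`, `prr`,
#'   `prr_lo`, `ic025`, `ebgm05` (as produced by [signal_stats()]).
#' @param thresholds a [default_thresholds()] list.
#' @return `stats` with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_ebgm` and `signal` appended. A statistic marked
#'   not-applicable (`NA`) fails its criterion.
#' @export
evaluate_signal <- function(stats, thresholds = default_thresholds()) {
  th <- thresholds
  isTRUEv <- function(x) !is.na(x) & x
  stats$flag_ror <- isTRUEv(stats$ror >= th$ror_min &
                              stats$ror_lo > th$ror_ci_lo_min)
  stats$flag_prr <- isTRUEv(stats$prr >= th$prr_min &
                              stats$prr_lo > th$prr_ci_lo_min)
  stats$flag_bcpnn <- isTRUEv(stats$ic025 > th$ic025_min)
  stats$flag_ebgm <- isTRUEv(stats$ebgm05 > th$ebgm05_min)
  stats$signal <- stats$a >= th$min_a & stats$flag_ror & stats$flag_prr &
    stats$flag_bcpnn & stats$flag_ebgm
  stats
}

#' Compute all signal statistics for a set of 2x2 tables
#'
#' Runs the four disproportionality algorithms plus the chi-squared
#' statistic over every event table and applies the joint signal
#' criterion.
#'
#' @param table_set an `event_table_set` from [build_tables()], or any
#'   data.frame with columns `event`, `a`, `b`, `c`, `d`.
#' @param thresholds a [default_thresholds()] list.
#' @param priors a [bcpnn_priors()] list.
#' @param yates use Yates' correction for the chi-squared statistic.
#' @return data.frame with the cells, all statistics, per-criterion flags
#'   and the joint `signal` decision, one row per event.
#' @export
signal_stats <- function(table_set, thresholds = default_thresholds(),
                         priors = bcpnn_priors(), yates = FALSE) {
  a <- table_set$a; b <- table_set$b; c <- table_set$c; d <- table_set$d
  out <- data.frame(event = table_set$event, a = a, b = b, c = c, d = d,
                    stringsAsFactors = FALSE)
  out <- cbind(out,
               compute_ror(a, b, c, d, min_a = thresholds$min_a),
               compute_prr(a, b, c, d, min_a = thresholds$min_a),
               chi2 = compute_chi2(a, b, c, d, yates = yates),
               compute_bcpnn(a, b, c, d, priors = priors),
               compute_ebgm(a, b, c, d, min_a = thresholds$min_a))
  out <- evaluate_signal(out, thresholds)
  for (at in c("drug_label", "level", "n_cohort", "n_total")) {
    attr(out, at) <- attr(table_set, at)
  }
  out
}

#' Write a signal table to CSV
#'
#' One row per event with cells, statistics at full precision, a 2-decimal
#' display rendering of each ratio statistic with its interval, the
#' per-criterion flags and the joint decision.
#'
#' @param stats a [signal_stats()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(stats, path) {
  disp <- function(p, lo, hi) {
    ifelse(is.na(p), "NA",
           sprintf("%.2f (%.2f, %.2f)", p, lo, hi))
  }
  stats$ror_display <- disp(stats$ror, stats$ror_lo, stats$ror_hi)
  stats$prr_display <- disp(stats$prr, stats$prr_lo, stats$prr_hi)
  stats$ic_display <- ifelse(is.na(stats$ic_expect), "NA",
                             sprintf("%.2f (%.2f)", stats$ic_expect,
                                     stats$ic025))
  stats$ebgm_display <- disp(stats$ebgm, stats$ebgm05, stats$ebgm95)
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
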