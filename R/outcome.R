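## Outcome-association module: Kaplan-Meier estimation, log-rank testing and
## best-cutoff expression stratification.

#' Kaplan-Meier product-limit estimate
#'
#' Censoring at an event time is processed after the events at that time
#' (standard convention): censored subjects at time t remain at risk for the
#' events at t.
#'
#' @param times positive event/censoring times.
#' @param events event indicator (1 = event, 0 = censored).
#' @return an object of class `km_estimate`: data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` at each distinct time.
#' @examples
#' km <- km_curve(c(1, 2, 2, 3), c(1, 1, 0, 1))
#' km$surv[km$n_event > 0]  # 0.75, 0.50, 0.00
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop_invalid("empty survival input")
  if (length(times) != length(events))
    stop_invalid("times and events must have equal length")
  if (any(times <= 0)) stop_invalid("times must be > 0")
  if (!all(events %in% c(0, 1))) stop_invalid("events must be 0/1")
  ut <- sort(unique(times))
  n <- length(times)
  surv <- 1
  out <- data.frame(time = ut, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    c_ <- sum(times == ut[i] & events == 0)
    if (d > 0) surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c_
    out$surv[i] <- surv
  }
  structure(out, class = c("km_estimate", "data.frame"))
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' The classic observed-minus-expected statistic with hypergeometric
#' variance, referred to a chi-square distribution on 1 degree of freedom.
#' A group with zero events still contributes its at-risk counts.
#'
#' @param times,events survival data for all subjects.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `p`, `observed` and `expected` (per
#'   group, in level order).
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_invalid("exactly two groups are required")
  if (any(table(group) == 0L)) stop_invalid("both groups must be non-empty")
  in1 <- group == levels(group)[1L]
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    n_at <- sum(times >= t)
    n1_at <- sum(times >= t & in1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1_at / n_at
    if (n_at > 1)
      V <- V + d * (n1_at / n_at) * (1 - n1_at / n_at) *
        (n_at - d) / (n_at - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  O <- c(O1, sum(events == 1) - O1)
  E <- c(E1, sum(events == 1) - E1)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Best-cutoff expression stratification for survival
#'
#' Scans a grid of expression quantiles, splits samples into low (at or
#' below the cutoff) and high groups at each feasible grid point, evaluates
#' the log-rank p-value, and returns the cutoff minimizing p. Because the
#' minimum over a grid is anti-conservative, a grid-size Bonferroni-adjusted
#' p-value is always reported alongside the raw minimum. Ties in p are
#' broken toward the median quantile.
#'
#' @param table data.frame with columns `time`, `event`, `expression`.
#' @param grid quantile grid (default `seq(0.10, 0.90, by = 0.05)`).
#' @param min_group_frac minimum fraction of samples required in each group
#'   for a grid point to be feasible (default 0.10).
#' @return list with `cutoff_quantile`, `cutoff_value`, `groups` (factor
#'   low/high per sample), `p_raw`, `p_bonferroni`, `n_grid` (feasible grid
#'   points), and `scan` (per-grid-point table).
#' @export
best_cutoff <- function(table, grid = seq(0.10, 0.90, by = 0.05),
                        min_group_frac = 0.10) {
  need <- c("time", "event", "expression")
  if (!all(need %in% names(table)))
    stop_invalid("table needs columns ", paste(need, collapse = ", "))
  n <- nrow(table)
  scan <- data.frame(quantile = grid, cutoff = NA_real_, n_low = NA_integer_,
                     n_high = NA_integer_, p = NA_real_)
  for (i in seq_along(grid)) {
    cut <- stats::quantile(table$expression, grid[i], names = FALSE)
    low <- table$expression <= cut
    if (sum(low) < min_group_frac * n || sum(!low) < min_group_frac * n)
      next
    lr <- logrank_test(table$time, table$event,
                       factor(ifelse(low, "low", "high"),
                              levels = c("low", "high")))
    scan$cutoff[i] <- cut
    scan$n_low[i] <- sum(low)
    scan$n_high[i] <- sum(!low)
    scan$p[i] <- lr$p
  }
  feasible <- which(!is.na(scan$p))
  if (length(feasible) == 0L)
    stop_invalid("no feasible grid point (degenerate expression values?)")
  pmin_ <- min(scan$p[feasible])
  cand <- feasible[scan$p[feasible] == pmin_]
  best <- cand[which.min(abs(grid[cand] - 0.5))]  # ties toward the median
  low <- table$expression <= scan$cutoff[best]
  list(cutoff_quantile = grid[best],
       cutoff_value = scan$cutoff[best],
       groups = factor(ifelse(low, "low", "high"), levels = c("low", "high")),
       p_raw = scan$p[best],
       p_bonferroni = min(1, scan$p[best] * length(feasible)),
       n_grid = length(feasible),
       scan = scan)
}

#' Simulate survival data with expression-proportional hazard
#'
#' Expression z-scores are standard normal; event times are exponential with
#' hazard `lambda0 * exp(hazard_beta * z)`. Censoring is independent
#' exponential with rate `lambda0 * censor_rate / (1 - censor_rate)`, which
#' yields an expected censoring fraction of `censor_rate` under the null
#' (`hazard_beta = 0`).
#'
#' @param config a [sim_config()]; `hazard_beta` is the log-hazard slope per
#'   unit z-score.
#' @param n number of subjects (default 200).
#' @param censor_rate target censoring fraction in \[0, 1) (default 0.3).
#' @param median_months baseline median survival in months (default 24).
#' @param effect `"linear"` (default): log-hazard proportional to the
#'   expression z-score; `"threshold"`: the full `hazard_beta` applies only
#'   to samples with z above the population median (0), planting a step
#'   effect at the median for cutoff-selection checks.
#' @return list with `table` (data.frame: `sample`, `time`, `event`,
#'   `expression`) and `truth` (`hazard_beta`, `lambda0`).
#' @export
gen_survival <- function(config, n = 200L, censor_rate = 0.3,
                         median_months = 24,
                         effect = c("linear", "threshold")) {
  stopifnot(inherits(config, "sim_config"))
  effect <- match.arg(effect)
  assert_scalar_number(censor_rate, "censor_rate", lower = 0, upper = 1)
  if (censor_rate >= 1) stop_invalid("censor_rate must be < 1")
  lambda0 <- log(2) / median_months
  tab <- with_substream(config$seed, "survival", {
    z <- rnorm(n)
    lin <- if (effect == "linear") z else as.numeric(z > 0)
    haz <- lambda0 * exp(config$hazard_beta * lin)
    t_event <- stats::rexp(n, rate = haz)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n, rate = lambda0 * censor_rate / (1 - censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(sample = sprintf("P%03d", seq_len(n)),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               expression = z, stringsAsFactors = FALSE)
  })
  list(table = tab,
       truth = list(hazard_beta = config$hazard_beta, lambda0 = lambda0))
}
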