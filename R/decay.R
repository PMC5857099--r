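## Decay-kinetics module: ddCt quantification, endogenous-control
## normalization, exponential decay fitting and half-life comparison.

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct(target) - Ct(reference)` per sample; `ddCt = dCt(sample) -
#' dCt(calibrator)`; relative expression `= 2^(-ddCt)`. Technical replicates
#' are averaged on the Ct scale before exponentiation. Samples lacking the
#' reference gene are skipped with a warning; the calibrator sample always
#' maps to relative expression 1 for every gene measured in it.
#'
#' @param table data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference reference (endogenous control) gene id, e.g. `"18S"`.
#' @param calibrator calibrator sample id.
#' @return data.frame with `sample`, `gene`, `delta_ct`, `ddct`, `rel_expr`
#'   for every non-reference gene.
#' @examples
#' ct <- data.frame(sample = rep(c("cal", "s1"), each = 2),
#'                  gene = rep(c("18S", "g"), 2), replicate = 1,
#'                  ct = c(10, 17, 10, 15))
#' ddct(ct, reference = "18S", calibrator = "cal")$rel_expr  # 1, 4
#' @export
ddct <- function(table, reference, calibrator) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(table)))
    stop_invalid("table needs columns ", paste(need, collapse = ", "))
  if (!calibrator %in% table$sample)
    stop_invalid("calibrator sample '", calibrator, "' not found")
  ## average technical replicates on the Ct scale
  agg <- stats::aggregate(ct ~ sample + gene, data = table, FUN = mean)
  samples <- unique(agg$sample)
  ref_ct <- agg$ct[agg$gene == reference][match(samples,
            agg$sample[agg$gene == reference])]
  names(ref_ct) <- samples
  no_ref <- samples[is.na(ref_ct)]
  if (length(no_ref)) {
    warning("reference gene missing in sample(s) ",
            paste(no_ref, collapse = ", "), "; skipped")
    agg <- agg[!agg$sample %in% no_ref, , drop = FALSE]
  }
  agg <- agg[agg$gene != reference, , drop = FALSE]
  agg$delta_ct <- agg$ct - ref_ct[agg$sample]
  cal_dct <- agg$delta_ct[agg$sample == calibrator][
    match(agg$gene, agg$gene[agg$sample == calibrator])]
  agg$ddct <- agg$delta_ct - cal_dct
  agg$rel_expr <- 2^(-agg$ddct)
  agg[, c("sample", "gene", "delta_ct", "ddct", "rel_expr")]
}

#' Normalize an abundance series to an endogenous control
#'
#' Divides the target series elementwise by the control series (matched on
#' all shared key columns), then rescales each (gene, condition) series so
#' the mean at t = 0 is 1.
#'
#' @param raw data.frame with columns `gene`, `condition`, `replicate`,
#'   `time_h`, `abundance`.
#' @param control data.frame with the same key columns and the control
#'   `abundance`; a zero control value is an error naming the offending row.
#' @return `raw` with `abundance` replaced by the normalized series.
#' @export
normalize_to_control <- function(raw, control) {
  key <- function(d) paste(d$condition, d$replicate, d$time_h)
  idx <- match(key(raw), key(control))
  if (anyNA(idx)) stop_invalid("control series missing matching rows")
  ctrl_ab <- control$abundance[idx]
  if (any(ctrl_ab == 0)) {
    bad <- which(ctrl_ab == 0)[1L]
    stop_invalid("zero control abundance at condition=", raw$condition[bad],
                 " replicate=", raw$replicate[bad], " t=", raw$time_h[bad])
  }
  raw$abundance <- raw$abundance / ctrl_ab
  for (grp in split(seq_len(nrow(raw)),
                    paste(raw$gene, raw$condition))) {
    t0 <- grp[raw$time_h[grp] == 0]
    if (length(t0) == 0L) stop_invalid("series lacks a t = 0 anchor")
    raw$abundance[grp] <- raw$abundance[grp] / mean(raw$abundance[t0])
  }
  raw
}

#' Fit first-order exponential decay to a time course
#'
#' The primary estimator regresses `ln(abundance)` on time by ordinary least
#' squares across all replicate points (the best-fit line on a semilog plot);
#' the decay constant is minus the slope and the half-life is
#' `t_half = ln(2) / k`. A non-negative slope yields `k = 0`,
#' `t_half = Inf` and `decaying = FALSE` rather than a negative half-life.
#' `method = "nls"` refines the estimate by direct nonlinear least squares on
#' `a * exp(-k t)`, initialized from the log-linear fit.
#'
#' @param tc data.frame with columns `time_h` and `abundance` (and anything
#'   else, ignored); at least 3 distinct timepoints. Non-positive abundances
#'   are dropped with a warning on the log-linear path.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @param average_replicates average abundances per timepoint before fitting
#'   instead of pooling all points (default FALSE, preserving degrees of
#'   freedom).
#' @return an object of class `decay_fit`: list with `k` (1/h), `t_half` (h),
#'   `se_k`, `r_squared`, `n`, `decaying`, `method`.
#' @examples
#' tc <- data.frame(time_h = c(0, 2, 4, 6), abundance = 2^-(c(0, 2, 4, 6) / 2))
#' fit_decay(tc)$t_half  # 2
#' @export
fit_decay <- function(tc, method = c("loglinear", "nls"),
                      average_replicates = FALSE) {
  method <- match.arg(method)
  if (!all(c("time_h", "abundance") %in% names(tc)))
    stop_invalid("tc needs columns time_h and abundance")
  tc <- tc[is.finite(tc$time_h) & is.finite(tc$abundance), , drop = FALSE]
  if (any(tc$abundance <= 0)) {
    warning(sum(tc$abundance <= 0),
            " non-positive abundance point(s) dropped")
    tc <- tc[tc$abundance > 0, , drop = FALSE]
  }
  if (length(unique(tc$time_h)) < 3L)
    stop_invalid("at least 3 distinct timepoints are required")
  if (average_replicates)
    tc <- stats::aggregate(abundance ~ time_h, data = tc, FUN = mean)
  fit <- stats::lm(log(abundance) ~ time_h, data = tc)
  slope <- stats::coef(fit)[["time_h"]]
  se <- summary(fit)$coefficients["time_h", "Std. Error"]
  r2 <- summary(fit)$r.squared
  k <- max(0, -slope)
  if (method == "nls" && k > 0) {
    nfit <- try(stats::nls(abundance ~ a * exp(-k * time_h), data = tc,
                           start = list(a = exp(stats::coef(fit)[[1L]]),
                                        k = k)),
                silent = TRUE)
    if (!inherits(nfit, "try-error")) {
      k <- max(0, stats::coef(nfit)[["k"]])
      se <- summary(nfit)$coefficients["k", "Std. Error"]
      res <- stats::resid(nfit)
      r2 <- 1 - sum(res^2) / sum((tc$abundance - mean(tc$abundance))^2)
    }
  }
  structure(list(k = k, t_half = if (k > 0) log(2) / k else Inf,
                 se_k = se, r_squared = r2, n = nrow(tc),
                 decaying = k > 0, method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> k = ", signif(x$k, 4), "/h, t1/2 = ",
      if (is.finite(x$t_half)) paste0(signif(x$t_half, 4), " h")
      else "Inf (non-decaying)",
      ", R^2 = ", signif(x$r_squared, 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Compare transcript stability between two conditions
#'
#' Reports the half-life ratio of the two fits and tests the decay-rate
#' difference through the time-by-condition interaction term of a joint
#' log-linear regression on the pooled points. When either fit is flagged
#' non-decaying the ratio is not applicable (NA) and no test is run.
#'
#' @param fit_a,fit_b [fit_decay()] results for the two conditions.
#' @param tc_a,tc_b the corresponding time courses (columns `time_h`,
#'   `abundance`).
#' @return list with `ratio` (`t_half(a) / t_half(b)`), `p` (interaction
#'   p-value), `applicable` flag, and the per-condition half-lives.
#' @export
compare_stability <- function(fit_a, fit_b, tc_a, tc_b) {
  stopifnot(inherits(fit_a, "decay_fit"), inherits(fit_b, "decay_fit"))
  if (!fit_a$decaying || !fit_b$decaying) {
    return(list(ratio = NA_real_, p = NA_real_, applicable = FALSE,
                t_half_a = fit_a$t_half, t_half_b = fit_b$t_half))
  }
  both <- rbind(data.frame(time_h = tc_a$time_h, abundance = tc_a$abundance,
                           condition = "a"),
                data.frame(time_h = tc_b$time_h, abundance = tc_b$abundance,
                           condition = "b"))
  both <- both[both$abundance > 0, , drop = FALSE]
  fit <- stats::lm(log(abundance) ~ time_h * condition, data = both)
  coefs <- summary(fit)$coefficients
  p <- coefs["time_h:conditionb", "Pr(>|t|)"]
  list(ratio = fit_a$t_half / fit_b$t_half, p = p, applicable = TRUE,
       t_half_a = fit_a$t_half, t_half_b = fit_b$t_half)
}

#' Simulate a transcription-inhibition decay time course
#'
#' Abundance follows `exp(-k t) * (1 + eps)` with Gaussian multiplicative
#' noise `eps ~ N(0, noise_cv)` truncated to keep abundances positive.
#' Default timepoints follow the DRB design (0, 2, 4, 6, 8 h) with 3
#' replicates. Decay constants per gene and condition come from the config
#' half-lives (`k = ln 2 / t_half`) or can be given directly.
#'
#' @param config a [sim_config()].
#' @param genes character vector of gene names (default two targets).
#' @param k optional named list `gene -> c(control = , knockdown = )` of
#'   decay constants (1/h, >= 0); overrides the config half-lives.
#' @param times timepoints in hours (default `c(0, 2, 4, 6, 8)`).
#' @param n_replicates replicates per condition (default 3).
#' @param noise_cv multiplicative noise level (default 0.10).
#' @return list with `tc` (data.frame: `gene`, `condition`, `replicate`,
#'   `time_h`, `abundance`) and `truth` (`gene`, `condition`, `k`,
#'   `t_half`).
#' @export
gen_timecourse <- function(config, genes = c("WFDC1", "IL17D"), k = NULL,
                           times = c(0, 2, 4, 6, 8), n_replicates = 3L,
                           noise_cv = 0.10) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(k)) {
    k <- stats::setNames(rep(list(c(
      control = log(2) / config$half_life_hours$control,
      knockdown = log(2) / config$half_life_hours$knockdown)),
      length(genes)), genes)
  }
  for (kk in unlist(k)) if (!is.finite(kk) || kk < 0)
    stop_invalid("decay constants must be finite and >= 0")
  conditions <- names(k[[genes[1L]]])
  grid <- expand.grid(time_h = times, replicate = seq_len(n_replicates),
                      condition = conditions,
                      gene = genes, stringsAsFactors = FALSE)
  tc <- with_substream(config$seed, "timecourse", {
    kvec <- mapply(function(g, cond) k[[g]][[cond]], grid$gene,
                   grid$condition)
    expected <- exp(-kvec * grid$time_h)
    noise <- 1 + rnorm(nrow(grid), sd = noise_cv)
    noise[noise <= 0.05] <- 0.05  # guard: keep abundances positive
    grid$abundance <- expected * noise
    grid
  })
  truth <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, condition = names(k[[g]]), k = unname(k[[g]]),
               t_half = ifelse(k[[g]] > 0, log(2) / k[[g]], Inf),
               stringsAsFactors = FALSE)))
  list(tc = tc[, c("gene", "condition", "replicate", "time_h", "abundance")],
       truth = truth)
}
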