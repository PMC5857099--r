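#' Simulation configuration
#'
#' Bundles the knobs shared by the `gen_*` generators. Defaults mirror the
#' study design wherever it states a value: three screening datasets with 10
#' samples per group on a log2-intensity scale, a 354-sample RNA-seq cohort,
#' stability contrasts at 0 h and 9 h after transcription inhibition with two
#' replicates, DRB time courses at 0/2/4/6/8 h, and a knockdown half-life of
#' half the control value for destabilized transcripts.
#'
#' @param n_genes number of simulated genes/transcripts.
#' @param n_rbp_genes number of genes designated RBPs (a prefix of the gene
#'   list); must not exceed `n_genes`.
#' @param n_planted number of RBP genes planted down-regulated in all three
#'   screening datasets.
#' @param samples_per_group samples per group in each screening dataset
#'   (minimum 2).
#' @param planted_logfc planted group difference in log2 units; negative means
#'   down-regulated in the case group.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param nb_dispersion negative-binomial dispersion for count generators
#'   (variance `mu + dispersion * mu^2`); values near 0 approach Poisson.
#'   The default 0.01 corresponds to a biological coefficient of variation
#'   of 0.1, the conventional value for replicates of genetically identical
#'   cell lines (the experiments emulated here are cell-line knockdowns).
#' @param rip_enrichment_fold expected IP/input ratio for bound transcripts;
#'   must exceed 1.
#' @param half_life_hours named list with elements `control` and `knockdown`,
#'   the half-lives (hours) of destabilized transcripts per condition; stable
#'   transcripts use the `control` value in both conditions.
#' @param hazard_beta log-hazard slope per unit expression z-score for
#'   [gen_survival].
#' @param n_cohort_samples cohort size for [gen_cohort].
#' @param seed integer global seed; each generator derives an independent
#'   substream from it, so the same config yields byte-identical output on
#'   every call.
#'
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_rbp_genes = 40, seed = 7)
#' @export
sim_config <- function(n_genes = 1000,
                       n_rbp_genes = 100,
                       n_planted = min(10L, n_rbp_genes),
                       samples_per_group = 10,
                       planted_logfc = -1,
                       noise_sd = 0.5,
                       nb_dispersion = 0.01,
                       rip_enrichment_fold = 8,
                       half_life_hours = list(control = 9, knockdown = 4.5),
                       hazard_beta = 0,
                       n_cohort_samples = 354,
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(n_rbp_genes, "n_rbp_genes", lower = 1)
  if (n_rbp_genes > n_genes)
    stop_invalid("n_rbp_genes (", n_rbp_genes, ") must not exceed n_genes (",
                 n_genes, ")")
  assert_scalar_number(n_planted, "n_planted", lower = 0)
  if (n_planted > n_rbp_genes)
    stop_invalid("n_planted must not exceed n_rbp_genes")
  assert_scalar_number(samples_per_group, "samples_per_group", lower = 2)
  assert_scalar_number(planted_logfc, "planted_logfc")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(rip_enrichment_fold, "rip_enrichment_fold",
                       lower = 1, strict_lower = TRUE)
  if (!is.list(half_life_hours) ||
      !all(c("control", "knockdown") %in% names(half_life_hours)))
    stop_invalid("half_life_hours must be a list with 'control' and 'knockdown'")
  for (hl in unlist(half_life_hours))
    if (!is.finite(hl) || hl <= 0)
      stop_invalid("half-lives must be positive and finite")
  assert_scalar_number(hazard_beta, "hazard_beta")
  assert_scalar_number(n_cohort_samples, "n_cohort_samples", lower = 3)
  assert_scalar_number(seed, "seed")

  structure(list(
    n_genes = as.integer(n_genes),
    n_rbp_genes = as.integer(n_rbp_genes),
    n_planted = as.integer(n_planted),
    samples_per_group = as.integer(samples_per_group),
    planted_logfc = planted_logfc,
    noise_sd = noise_sd,
    nb_dispersion = nb_dispersion,
    rip_enrichment_fold = rip_enrichment_fold,
    half_life_hours = half_life_hours,
    hazard_beta = hazard_beta,
    n_cohort_samples = as.integer(n_cohort_samples),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes (", x$n_rbp_genes, " RBPs, ",
      x$n_planted, " planted), ", x$samples_per_group, "/group, logFC ",
      x$planted_logfc, ", noise sd ", x$noise_sd, ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
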