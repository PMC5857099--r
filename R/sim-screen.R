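## Generators for the screening module: three two-group log-intensity
## matrices with planted down-regulated RBP genes, and a gene-level
## copy-number table straddling the deletion-filter threshold.

#' Simulate three two-group screening datasets with planted RBP effects
#'
#' Emulates the three public expression comparisons used to prioritize RBP
#' genes (tumor vs normal, omental metastasis vs primary tumor, spheroid vs
#' monolayer). Each dataset is an independent genes-by-samples log2-intensity
#' matrix with two equal-size groups. A designated subset of the RBP genes
#' (`config$n_planted`, by default planted in all three datasets) carries
#' `config$planted_logfc` in the case group; all other genes have zero
#' expected group difference. Noise is Gaussian with `config$noise_sd` on the
#' log2 scale.
#'
#' @param config a [sim_config()].
#' @param plant_pattern optional logical matrix (`n_rbp_genes` x 3) saying in
#'   which datasets each RBP gene is planted; overrides the default
#'   first-`n_planted`-in-all-three pattern.
#' @return a list with `datasets` (list of three [expression_dataset()]s,
#'   named `cancer`, `metastasis`, `spheroid`), `rbp_ids`, and `truth`
#'   (data.frame: `gene`, `is_rbp`, `planted_1..3`, `true_logfc`).
#' @examples
#' sim <- gen_screen_datasets(sim_config(n_genes = 50, n_rbp_genes = 10,
#'                                       n_planted = 2, seed = 1))
#' head(sim$truth)
#' @export
gen_screen_datasets <- function(config, plant_pattern = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes; nr <- config$n_rbp_genes
  n <- config$samples_per_group
  genes <- gene_ids(ng)
  rbp_ids <- genes[seq_len(nr)]
  if (is.null(plant_pattern)) {
    plant_pattern <- matrix(FALSE, nr, 3L)
    if (config$n_planted > 0)
      plant_pattern[seq_len(config$n_planted), ] <- TRUE
  }
  if (!is.matrix(plant_pattern) || nrow(plant_pattern) != nr ||
      ncol(plant_pattern) != 3L || !is.logical(plant_pattern))
    stop_invalid("plant_pattern must be a logical n_rbp_genes x 3 matrix")
  planted <- matrix(FALSE, ng, 3L)
  planted[seq_len(nr), ] <- plant_pattern

  ds_names <- c("cancer", "metastasis", "spheroid")
  group_levels <- list(c("normal", "tumor"),
                       c("primary", "metastasis"),
                       c("monolayer", "spheroid"))
  datasets <- with_substream(config$seed, "screen", {
    baseline <- stats::runif(ng, 5, 12)
    lapply(1:3, function(d) {
      vals <- matrix(rnorm(ng * 2 * n, sd = config$noise_sd), ng, 2 * n)
      vals <- vals + baseline
      case_cols <- (n + 1):(2 * n)
      vals[planted[, d], case_cols] <-
        vals[planted[, d], case_cols] + config$planted_logfc
      dimnames(vals) <- list(genes, sprintf("%s_S%02d", ds_names[d],
                                            seq_len(2 * n)))
      expression_dataset(vals, factor(rep(group_levels[[d]], each = n),
                                      levels = group_levels[[d]]))
    })
  })
  names(datasets) <- ds_names
  truth <- data.frame(gene = genes,
                      is_rbp = genes %in% rbp_ids,
                      planted_1 = planted[, 1L],
                      planted_2 = planted[, 2L],
                      planted_3 = planted[, 3L],
                      true_logfc = ifelse(rowSums(planted) > 0,
                                          config$planted_logfc, 0),
                      stringsAsFactors = FALSE)
  list(datasets = datasets, rbp_ids = rbp_ids, truth = truth)
}

#' Simulate a gene-level copy-number alteration table
#'
#' Background genes draw deletion fractions from Beta(1, 20) (rarely deleted)
#' and amplification fractions from Beta(1, 30). Genes named in
#' `straddle_genes` instead receive deterministic deletion fractions that
#' straddle the 5\% filter threshold: odd positions get values above it
#' (0.051, 0.08, 0.12, 0.20, 0.30, recycled), even positions values below
#' (0.049, 0.03, 0.02, 0.01, 0.005, recycled), so the deletion-filter outcome
#' on those genes is known by construction.
#'
#' @param config a [sim_config()].
#' @param straddle_genes character vector of genes given deterministic
#'   fractions; defaults to the all-three planted RBP genes of the default
#'   plant pattern (the first `config$n_planted` genes).
#' @param fractions optional named numeric vector of deletion fractions that
#'   fully overrides the draw for those genes; values must lie in \[0, 1\].
#' @return a list with `cna` (data.frame: `gene`, `fraction_deleted`,
#'   `fraction_amplified`) and `truth` (data.frame: `gene`, `above_threshold`
#'   relative to 0.05).
#' @export
gen_cna <- function(config, straddle_genes = NULL, fractions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids(config$n_genes)
  if (is.null(straddle_genes) && config$n_planted > 0)
    straddle_genes <- genes[seq_len(config$n_planted)]
  cna <- with_substream(config$seed, "cna", {
    data.frame(gene = genes,
               fraction_deleted = stats::rbeta(length(genes), 1, 20),
               fraction_amplified = stats::rbeta(length(genes), 1, 30),
               stringsAsFactors = FALSE)
  })
  if (length(straddle_genes)) {
    above <- c(0.051, 0.08, 0.12, 0.20, 0.30)
    below <- c(0.049, 0.03, 0.02, 0.01, 0.005)
    k <- length(straddle_genes)
    vals <- numeric(k)
    odd <- seq(1L, k, by = 2L); even <- seq_len(k)[seq_len(k) %% 2L == 0L]
    vals[odd] <- rep_len(above, length(odd))
    vals[even] <- rep_len(below, length(even))
    cna$fraction_deleted[match(straddle_genes, cna$gene)] <- vals
  }
  if (!is.null(fractions)) {
    if (is.null(names(fractions)) || any(fractions < 0 | fractions > 1))
      stop_invalid("fractions must be a named vector with values in [0, 1]")
    cna$fraction_deleted[match(names(fractions), cna$gene)] <- fractions
  }
  truth <- data.frame(gene = cna$gene,
                      above_threshold = cna$fraction_deleted > 0.05,
                      stringsAsFactors = FALSE)
  list(cna = cna, truth = truth)
}
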