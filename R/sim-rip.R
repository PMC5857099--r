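## Generators for the target-calling module: RIP-seq counts with planted
## bound transcripts, matching peaks and gene models, and transcription-
## inhibition count matrices with planted destabilized transcripts.

#' Simulate a RIP-seq experiment with planted bound transcripts
#'
#' Input and IgG libraries draw negative-binomial counts around a per-
#' transcript baseline; the IP library multiplies the baseline by
#' `config$rip_enrichment_fold` for bound transcripts (the first `n_bound`
#' transcripts) and leaves it unchanged otherwise, so the expected IP/input
#' count ratio is the enrichment fold for bound transcripts and 1 elsewhere.
#' Each bound transcript receives one peak whose midpoint falls in its 3'UTR
#' a short distance downstream of the stop codon; gene models are two-exon
#' transcripts laid head-to-tail on one chromosome, alternating strands.
#'
#' @param config a [sim_config()]; `rip_enrichment_fold` must be > 1 (this is
#'   validated at config construction).
#' @param n_bound number of planted bound transcripts (default
#'   `max(1, round(0.1 * n_genes))`).
#' @param peak_offset_bp distance from the stop codon to the planted peak
#'   midpoint, in bp into the 3'UTR (default 25).
#' @return list with `rip` (a [rip_experiment()]), `peaks` (BED-like
#'   data.frame), `models` (gene-model data.frame, see
#'   [annotate_peak_region()]), and `truth` (`transcript_id`, `is_bound`,
#'   `baseline_mean`).
#' @export
gen_rip <- function(config, n_bound = max(1L, round(0.1 * config$n_genes)),
                    peak_offset_bp = 25L) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  if (n_bound > ng) stop_invalid("n_bound must not exceed n_genes")
  ids <- gene_ids(ng, "TX")
  bound <- seq_len(ng) <= n_bound
  fold <- config$rip_enrichment_fold

  out <- with_substream(config$seed, "rip", {
    mu <- 2^stats::runif(ng, 5, 9)  # baseline mean counts, 32..512
    ip <- rnb(ng, mu * ifelse(bound, fold, 1), config$nb_dispersion)
    input <- rnb(ng, mu, config$nb_dispersion)
    igg <- rnb(ng, mu, config$nb_dispersion)
    list(mu = mu, counts = data.frame(transcript_id = ids, ip = ip,
                                      input = input, igg = igg,
                                      stringsAsFactors = FALSE))
  })

  ## deterministic gene models: 2 exons of 600 bp separated by a 400 bp
  ## intron; CDS from 100 into exon1 to 200 before the transcript 3' end,
  ## leaving a >= 200 bp 3'UTR. Transcripts tile chr1 with 1 kb gaps.
  tx_len <- 600L + 400L + 600L
  starts <- (seq_len(ng) - 1L) * (tx_len + 1000L)
  strand <- ifelse(seq_len(ng) %% 2L == 1L, "+", "-")
  models <- do.call(rbind, lapply(seq_len(ng), function(i) {
    s <- starts[i]
    ex <- data.frame(start = c(s, s + 1000L), end = c(s + 600L, s + 1600L))
    if (strand[i] == "+") {
      cds <- data.frame(start = c(s + 100L, s + 1000L),
                        end = c(s + 600L, s + 1400L))
    } else {
      ## mirrored: 3'UTR at the genomic left end
      cds <- data.frame(start = c(s + 200L, s + 1000L),
                        end = c(s + 600L, s + 1500L))
    }
    data.frame(transcript_id = ids[i], chrom = "chr1", strand = strand[i],
               feature = rep(c("exon", "CDS"), each = 2L),
               start = c(ex$start, cds$start), end = c(ex$end, cds$end),
               stringsAsFactors = FALSE)
  }))

  peak_half <- 20L
  peaks <- do.call(rbind, lapply(which(bound), function(i) {
    s <- starts[i]
    mid <- if (strand[i] == "+") s + 1400L + peak_offset_bp
           else s + 200L - peak_offset_bp
    data.frame(chrom = "chr1", start = mid - peak_half, end = mid + peak_half,
               name = paste0("peak_", ids[i]), score = 0L,
               strand = strand[i], stringsAsFactors = FALSE)
  }))

  truth <- data.frame(transcript_id = ids, is_bound = bound,
                      baseline_mean = out$mu, stringsAsFactors = FALSE)
  list(rip = rip_experiment(out$counts), peaks = peaks, models = models,
       truth = truth)
}

#' Simulate a transcription-inhibition stability experiment
#'
#' Counts are generated for knockdown and control cells at 0 h and `t_hours`
#' after transcription inhibition. The expected abundance decays as
#' `abundance(0) * 2^(-t / t_half)`; destabilized transcripts (the first
#' `n_destab`) use `config$half_life_hours$knockdown` in the knockdown and
#' `$control` in the control, while all others use the control half-life in
#' both conditions. Counts are negative-binomial around the expectation.
#' Reported library sizes are anchored at the common expected time-zero
#' total, emulating spike-in (absolute) depth normalization: the stability
#' contrast of a transcript then reflects its own retention rather than the
#' composition shift induced by global RNA loss in the knockdown.
#'
#' @param config a [sim_config()].
#' @param n_destab number of planted destabilized transcripts (default
#'   `max(1, round(0.1 * n_genes))`).
#' @param t_hours the late timepoint in hours (default 9).
#' @param n_replicates replicates per condition and timepoint (default 2).
#' @return list with `counts` (matrix transcripts x samples), `samples`
#'   (sample metadata: `sample`, `condition`, `time_h`, `replicate`),
#'   `lib_sizes`, and `truth` (`transcript_id`, `is_destabilized`,
#'   `half_life_control`, `half_life_knockdown`).
#' @export
gen_stability <- function(config,
                          n_destab = max(1L, round(0.1 * config$n_genes)),
                          t_hours = 9, n_replicates = 2L) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  if (n_destab > ng) stop_invalid("n_destab must not exceed n_genes")
  assert_scalar_number(t_hours, "t_hours", lower = 0, strict_lower = TRUE)
  ids <- gene_ids(ng, "TX")
  destab <- seq_len(ng) <= n_destab
  hl_ctrl <- rep(config$half_life_hours$control, ng)
  hl_kd <- ifelse(destab, config$half_life_hours$knockdown,
                  config$half_life_hours$control)

  samples <- expand.grid(replicate = seq_len(n_replicates),
                         time_h = c(0, t_hours),
                         condition = c("control", "knockdown"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_t%g_r%d", substr(samples$condition, 1, 4),
                            samples$time_h, samples$replicate)
  samples <- samples[, c("sample", "condition", "time_h", "replicate")]

  res <- with_substream(config$seed, "stability", {
    mu0 <- 2^stats::runif(ng, 6, 11)
    counts <- sapply(seq_len(nrow(samples)), function(j) {
      hl <- if (samples$condition[j] == "knockdown") hl_kd else hl_ctrl
      expected <- mu0 * 2^(-samples$time_h[j] / hl)
      rnb(ng, expected, config$nb_dispersion)
    })
    list(mu0 = mu0, counts = counts)
  })
  counts <- res$counts
  dimnames(counts) <- list(ids, samples$sample)
  ## spike-in-style anchor: one common expected t0 total for every sample
  lib_sizes <- stats::setNames(rep(sum(res$mu0), nrow(samples)),
                               samples$sample)
  truth <- data.frame(transcript_id = ids, is_destabilized = destab,
                      half_life_control = hl_ctrl, half_life_knockdown = hl_kd,
                      baseline_mean = res$mu0, stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, lib_sizes = lib_sizes,
       truth = truth)
}

#' Simulate steady-state knockdown/control count matrices
#'
#' Companion to [gen_stability()] for the steady-state arm of target calling:
#' knockdown cells express planted down-regulated transcripts at
#' `2^planted_logfc` times the control level; counts are negative binomial.
#'
#' @param config a [sim_config()].
#' @param n_down number of planted down-regulated transcripts (default
#'   `max(1, round(0.1 * n_genes))`).
#' @param n_replicates replicates per condition (default 3).
#' @return list with `kd`, `ctrl` (count matrices sharing rownames),
#'   `lib_sizes_kd`, `lib_sizes_ctrl` and `truth`.
#' @export
gen_steady_state <- function(config,
                             n_down = max(1L, round(0.1 * config$n_genes)),
                             n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  ids <- gene_ids(ng, "TX")
  down <- seq_len(ng) <= n_down
  res <- with_substream(config$seed, "steady", {
    mu <- 2^stats::runif(ng, 6, 11)  # 64..2048: expressed-gene range
    mu_kd <- mu * ifelse(down, 2^config$planted_logfc, 1)
    kd <- sapply(seq_len(n_replicates), function(j)
      rnb(ng, mu_kd, config$nb_dispersion))
    ctrl <- sapply(seq_len(n_replicates), function(j)
      rnb(ng, mu, config$nb_dispersion))
    list(mu = mu, mu_kd = mu_kd, kd = kd, ctrl = ctrl)
  })
  kd <- res$kd; ctrl <- res$ctrl
  dimnames(kd) <- list(ids, sprintf("kd_r%d", seq_len(n_replicates)))
  dimnames(ctrl) <- list(ids, sprintf("ctrl_r%d", seq_len(n_replicates)))
  truth <- data.frame(transcript_id = ids, is_down = down,
                      stringsAsFactors = FALSE)
  ## expected totals as library sizes, mirroring gen_stability
  list(kd = kd, ctrl = ctrl,
       lib_sizes_kd = rep(sum(res$mu_kd), n_replicates),
       lib_sizes_ctrl = rep(sum(res$mu), n_replicates),
       truth = truth)
}

#' Deterministic three-set membership fixture with exact region counts
#'
#' Builds a transcript membership table whose three sets (bound, steady-state
#' down, destabilized) have exactly the requested sizes and triple
#' intersection. Pairwise overlaps default to the minimal feasible
#' configuration: each pairwise overlap equals the triple intersection
#' (surplus elements sit outside all overlaps). The construction is validated
#' by inclusion-exclusion; an infeasible request raises an error naming the
#' violated region.
#'
#' @param n_bound,n_down,n_destab set sizes.
#' @param n_triple size of the triple intersection.
#' @param pairwise_overlaps optional named numeric vector with elements
#'   `bound_down`, `bound_destab`, `down_destab` giving total pairwise
#'   overlaps (each must be >= `n_triple`).
#' @param seed optional integer; when given, transcript ids are shuffled
#'   reproducibly, otherwise they are sequential.
#' @return data.frame with `transcript_id` and logical columns `bound`,
#'   `steady_down`, `destabilized`.
#' @examples
#' m <- fixture_venn(1084, 708, 2560, 91)
#' sum(m$bound & m$steady_down & m$destabilized)  # 91
#' @export
fixture_venn <- function(n_bound, n_down, n_destab, n_triple,
                         pairwise_overlaps = NULL, seed = NULL) {
  for (v in c(n_bound, n_down, n_destab, n_triple))
    assert_scalar_number(v, "set size", lower = 0)
  if (is.null(pairwise_overlaps))
    pairwise_overlaps <- c(bound_down = n_triple, bound_destab = n_triple,
                           down_destab = n_triple)
  need <- c("bound_down", "bound_destab", "down_destab")
  if (!all(need %in% names(pairwise_overlaps)))
    stop_invalid("pairwise_overlaps needs elements ",
                 paste(need, collapse = ", "))
  ab <- pairwise_overlaps[["bound_down"]]
  ac <- pairwise_overlaps[["bound_destab"]]
  bc <- pairwise_overlaps[["down_destab"]]
  region <- c(
    triple = n_triple,
    bound_down_only = ab - n_triple,
    bound_destab_only = ac - n_triple,
    down_destab_only = bc - n_triple,
    bound_only = n_bound - ab - ac + n_triple,
    down_only = n_down - ab - bc + n_triple,
    destab_only = n_destab - ac - bc + n_triple
  )
  bad <- names(region)[region < 0]
  if (length(bad))
    stop(errorCondition(
      paste0("infeasible set configuration: region '", bad[1L],
             "' would need ", region[bad[1L]], " elements"),
      class = c("rbpscreen_infeasible", "error")))
  flags <- rbind(
    matrix(rep(c(TRUE, TRUE, TRUE), region["triple"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, FALSE), region["bound_down_only"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE, TRUE), region["bound_destab_only"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE, TRUE), region["down_destab_only"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE, FALSE), region["bound_only"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE, FALSE), region["down_only"]), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE), region["destab_only"]), ncol = 3, byrow = TRUE)
  )
  n <- nrow(flags)
  ids <- sprintf("VTX%05d", seq_len(max(n, 1L)))[seq_len(n)]
  if (!is.null(seed)) {
    ord <- withr::with_seed(as.integer(seed), sample.int(n))
    flags <- flags[ord, , drop = FALSE]
  }
  data.frame(transcript_id = ids, bound = flags[, 1L],
             steady_down = flags[, 2L], destabilized = flags[, 3L],
             stringsAsFactors = FALSE)
}
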