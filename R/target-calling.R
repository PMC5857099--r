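## Target-calling module: RIP-seq bound set, steady-state down-regulated set,
## destabilized set, their triple intersection, peak-region annotation, the
## secreted-gene filter and the 3'UTR-length qPCR assay.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length / 1000) * (library size / 1e6))`.
#'
#' @param counts non-negative count matrix (transcripts x samples) or vector.
#' @param lengths transcript lengths in base pairs (> 0), one per row.
#' @param lib_sizes mapped-read totals per sample (> 0), one per column.
#' @return numeric matrix (or vector) of RPKM values.
#' @examples
#' compute_rpkm(matrix(10), lengths = 1000, lib_sizes = 1e6)  # 10
#' @export
compute_rpkm <- function(counts, lengths, lib_sizes) {
  if (any(lengths <= 0)) stop_invalid("transcript lengths must be > 0")
  if (any(lib_sizes <= 0)) stop_invalid("library sizes must be > 0")
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = length(lib_sizes))
  if (nrow(counts) != length(lengths))
    stop_invalid("lengths must match the number of transcripts")
  if (ncol(counts) != length(lib_sizes))
    stop_invalid("lib_sizes must match the number of samples")
  sweep(counts / (lengths / 1000), 2L, lib_sizes / 1e6, "/")
}

#' Construct a RIP-seq experiment
#'
#' @param counts data.frame with columns `transcript_id`, `ip`, `input`, and
#'   optionally `igg` (non-negative counts).
#' @param lib_sizes named numeric vector with elements `ip`, `input` and (if
#'   present) `igg`, all > 0. Defaults to the column sums.
#' @return an object of class `rip_experiment`.
#' @export
rip_experiment <- function(counts, lib_sizes = NULL) {
  need <- c("transcript_id", "ip", "input")
  if (!all(need %in% names(counts)))
    stop_invalid("counts needs columns transcript_id, ip, input")
  libs <- intersect(c("ip", "input", "igg"), names(counts))
  if (any(unlist(counts[libs]) < 0)) stop_invalid("counts must be >= 0")
  if (is.null(lib_sizes))
    lib_sizes <- vapply(counts[libs], sum, numeric(1))
  if (any(lib_sizes <= 0)) stop_invalid("library sizes must be > 0")
  structure(list(counts = counts, lib_sizes = lib_sizes[libs]),
            class = "rip_experiment")
}

#' Call transcripts bound by the RBP from RIP-seq counts
#'
#' Enrichment is computed on counts per million with a pseudocount:
#' `log2((IP_cpm + pc) / (input_cpm + pc))` and analogously against the IgG
#' control. A transcript is called bound when both enrichments reach
#' `log2(min_fold)` and its input CPM reaches the expression floor. When the
#' experiment lacks an IgG library the call falls back to input-only with a
#' warning.
#'
#' @param rip a [rip_experiment()].
#' @param min_fold_vs_input,min_fold_vs_igg linear fold thresholds (default 2).
#' @param min_input_cpm expression floor on input CPM (default 1).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame with `transcript_id`, CPM columns, `enrichment_input`,
#'   `enrichment_igg` (NA without IgG), and logical `bound`.
#' @export
call_bound <- function(rip, min_fold_vs_input = 2, min_fold_vs_igg = 2,
                       min_input_cpm = 1, pseudocount = 0.5) {
  stopifnot(inherits(rip, "rip_experiment"))
  cts <- rip$counts
  ip_cpm <- cpm_of(cts$ip, rip$lib_sizes[["ip"]])
  input_cpm <- cpm_of(cts$input, rip$lib_sizes[["input"]])
  enr_input <- log2((ip_cpm + pseudocount) / (input_cpm + pseudocount))
  has_igg <- "igg" %in% names(cts) && "igg" %in% names(rip$lib_sizes)
  if (has_igg) {
    igg_cpm <- cpm_of(cts$igg, rip$lib_sizes[["igg"]])
    enr_igg <- log2((ip_cpm + pseudocount) / (igg_cpm + pseudocount))
  } else {
    warning("no IgG library; falling back to input-only bound calling")
    igg_cpm <- NA_real_
    enr_igg <- NA_real_
  }
  bound <- enr_input >= log2(min_fold_vs_input) & input_cpm >= min_input_cpm
  if (has_igg) bound <- bound & enr_igg >= log2(min_fold_vs_igg)
  data.frame(transcript_id = cts$transcript_id,
             ip_cpm = ip_cpm, input_cpm = input_cpm, igg_cpm = igg_cpm,
             enrichment_input = enr_input, enrichment_igg = enr_igg,
             bound = bound, stringsAsFactors = FALSE)
}

#' Annotate peaks with a genomic region label and stop-codon distance
#'
#' Each peak is assigned by the position of its midpoint,
#' `floor((start + end) / 2)` in 0-based coordinates. Within each overlapping
#' transcript the midpoint is classified as 5'UTR, CDS, 3'UTR (exonic,
#' relative to the CDS span in transcript orientation) or intron; peaks
#' touching no transcript are intergenic. Across overlapping transcripts the
#' label with the highest priority wins (default 3'UTR > 5'UTR > CDS >
#' intron, reflecting the 3'UTR-centric focus of stability-regulating RBPs;
#' switchable via `priority`). `distance_to_stop` is the signed distance in
#' genomic base pairs from the midpoint to the last CDS base in transcript
#' orientation: negative upstream of the stop, positive downstream.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param models gene models: data.frame with columns `transcript_id`,
#'   `chrom`, `strand` (`+`/`-`), `feature` (`exon`/`CDS`), `start`, `end`
#'   (0-based half-open). CDS must lie within the exon union.
#' @param priority character vector ordering region labels from most to least
#'   preferred on overlap.
#' @return `peaks` with added columns `region`, `transcript_id` (the
#'   label-providing transcript, NA if intergenic) and `distance_to_stop`
#'   (NA unless the transcript has a CDS).
#' @export
annotate_peak_region <- function(peaks, models,
                                 priority = c("3'UTR", "5'UTR", "CDS",
                                              "intron")) {
  if (any(peaks$start >= peaks$end))
    stop_invalid("malformed peak interval: start must be < end")
  if (any(models$start >= models$end))
    stop_invalid("malformed model interval: start must be < end")
  txs <- split(models, models$transcript_id)
  mids <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  region <- rep("intergenic", n)
  tx_of <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  rank_of <- function(lab) match(lab, priority, nomatch = length(priority) + 1L)
  for (i in seq_len(n)) {
    best <- Inf
    for (tx in txs) {
      if (tx$chrom[1L] != peaks$chrom[i]) next
      exons <- tx[tx$feature == "exon", , drop = FALSE]
      cds <- tx[tx$feature == "CDS", , drop = FALSE]
      span <- c(min(tx$start), max(tx$end))
      m <- mids[i]
      if (m < span[1L] || m >= span[2L]) next
      in_exon <- any(m >= exons$start & m < exons$end)
      strand <- tx$strand[1L]
      if (!in_exon) {
        lab <- "intron"; d <- NA_real_
      } else if (nrow(cds) == 0L) {
        lab <- "3'UTR"  # non-coding: treat exonic hits as UTR-like
        d <- NA_real_
      } else {
        cds_start <- min(cds$start); cds_end <- max(cds$end)
        in_cds <- m >= cds_start & m < cds_end
        if (in_cds) {
          lab <- "CDS"
        } else if ((strand == "+" && m >= cds_end) ||
                   (strand == "-" && m < cds_start)) {
          lab <- "3'UTR"
        } else {
          lab <- "5'UTR"
        }
        ## last CDS base in transcript orientation
        d <- if (strand == "+") m - (cds_end - 1L) else cds_start - m
      }
      if (rank_of(lab) < best) {
        best <- rank_of(lab)
        region[i] <- lab
        tx_of[i] <- tx$transcript_id[1L]
        dist[i] <- d
      }
    }
  }
  peaks$region <- region
  peaks$transcript_id <- tx_of
  peaks$distance_to_stop <- dist
  peaks
}

#' Tabulate the peak region distribution
#'
#' @param annotated output of [annotate_peak_region()].
#' @return data.frame with `region`, `n`, `fraction`.
#' @export
peak_region_distribution <- function(annotated) {
  labs <- c("3'UTR", "5'UTR", "CDS", "intron", "intergenic")
  tab <- table(factor(annotated$region, levels = labs))
  data.frame(region = labs, n = as.integer(tab),
             fraction = as.numeric(tab) / max(1L, nrow(annotated)),
             stringsAsFactors = FALSE)
}

#' Transcripts down-regulated at steady state upon knockdown
#'
#' Per transcript, the linear fold change is the ratio of mean control CPM to
#' mean knockdown CPM (pseudocount 0.5 on both), and the p-value comes from a
#' two-sided two-sample t-test on log2 CPM with Benjamini-Hochberg adjustment
#' across transcripts. A transcript is selected when fold change down is
#' strictly greater than `min_fold` and q is below `max_q`.
#'
#' @param kd_counts,ctrl_counts count matrices (transcripts x replicates) with
#'   identical rownames; at least 2 replicates each unless `fc_only`.
#' @param kd_lib_sizes,ctrl_lib_sizes library sizes per replicate (default:
#'   column sums).
#' @param min_fold strict linear fold threshold (default 1.1).
#' @param max_q BH-adjusted p threshold (default 0.05).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param fc_only if TRUE, skip the test (single-replicate designs) and select
#'   on fold change alone.
#' @return list with `table` (per-transcript fold, p, q, selected) and
#'   `selected` (character vector of transcript ids).
#' @export
steady_state_down <- function(kd_counts, ctrl_counts,
                              kd_lib_sizes = colSums(kd_counts),
                              ctrl_lib_sizes = colSums(ctrl_counts),
                              min_fold = 1.1, max_q = 0.05,
                              pseudocount = 0.5, fc_only = FALSE) {
  if (!identical(rownames(kd_counts), rownames(ctrl_counts)))
    stop_invalid("kd and ctrl matrices must share rownames")
  if (!fc_only && (ncol(kd_counts) < 2L || ncol(ctrl_counts) < 2L))
    stop_invalid("need >= 2 replicates per condition; for single-replicate ",
                 "designs use fc_only = TRUE (fold-change-only mode)")
  kd_cpm <- cpm_of(kd_counts, kd_lib_sizes) + pseudocount
  ct_cpm <- cpm_of(ctrl_counts, ctrl_lib_sizes) + pseudocount
  fold_down <- rowMeans(ct_cpm) / rowMeans(kd_cpm)
  if (fc_only) {
    p <- q <- rep(NA_real_, nrow(kd_counts))
    selected <- fold_down > min_fold
  } else {
    lk <- log2(kd_cpm); lc <- log2(ct_cpm)
    nk <- ncol(lk); nc <- ncol(lc)
    mk <- rowMeans(lk); mc <- rowMeans(lc)
    vk <- rowSums((lk - mk)^2) / (nk - 1)
    vc <- rowSums((lc - mc)^2) / (nc - 1)
    sp2 <- ((nk - 1) * vk + (nc - 1) * vc) / (nk + nc - 2)
    se <- sqrt(sp2 * (1 / nk + 1 / nc))
    t <- (mk - mc) / se
    p <- 2 * stats::pt(abs(t), nk + nc - 2, lower.tail = FALSE)
    p[se == 0] <- ifelse(mk[se == 0] == mc[se == 0], 1, 0)
    q <- stats::p.adjust(p, method = "BH")
    selected <- fold_down > min_fold & q < max_q
  }
  tab <- data.frame(transcript_id = rownames(kd_counts),
                    fold_down = fold_down, p = p, q = q,
                    selected = selected, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, selected = tab$transcript_id[tab$selected])
}

#' Compute per-transcript stability measures from an inhibition experiment
#'
#' The stability measure is the difference between the knockdown-vs-control
#' log2 fold changes at the late and early timepoints:
#' `stability_delta = logFC(t_late) - logFC(t0)`, each logFC being the mean
#' log2 CPM (pseudocount) in knockdown minus control. A negative delta means
#' the transcript decays faster when the RBP is depleted.
#'
#' @param counts count matrix (transcripts x samples).
#' @param samples data.frame describing the columns of `counts`, with columns
#'   `sample`, `condition` (`knockdown`/`control`) and `time_h` (two distinct
#'   values, the smaller treated as t0).
#' @param lib_sizes library sizes (default column sums).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame with `transcript_id`, `logfc_t0`, `logfc_t1`,
#'   `stability_delta`.
#' @export
stability_measures <- function(counts, samples, lib_sizes = colSums(counts),
                               pseudocount = 0.5) {
  times <- sort(unique(samples$time_h))
  if (length(times) != 2L)
    stop_invalid("samples must cover exactly two timepoints")
  lcpm <- log2(cpm_of(counts, lib_sizes) + pseudocount)
  lfc_at <- function(t) {
    kd <- samples$time_h == t & samples$condition == "knockdown"
    ct <- samples$time_h == t & samples$condition == "control"
    if (!any(kd) || !any(ct))
      stop_invalid("both conditions required at time ", t)
    rowMeans(lcpm[, kd, drop = FALSE]) - rowMeans(lcpm[, ct, drop = FALSE])
  }
  l0 <- lfc_at(times[1L]); l1 <- lfc_at(times[2L])
  data.frame(transcript_id = rownames(counts), logfc_t0 = l0, logfc_t1 = l1,
             stability_delta = l1 - l0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Transcripts destabilized upon knockdown
#'
#' Selects transcripts whose stability delta is strictly below
#' `-log2(min_fold)`, i.e. whose retention after transcription inhibition
#' drops more than `min_fold`-fold in knockdown relative to control.
#'
#' @param measures data.frame from [stability_measures()] (columns
#'   `transcript_id`, `stability_delta`; rows with NA delta are skipped with a
#'   warning).
#' @param min_fold strict linear fold threshold (default 1.1).
#' @return character vector of destabilized transcript ids.
#' @export
destabilized_set <- function(measures, min_fold = 1.1) {
  delta <- measures$stability_delta
  if (anyNA(delta)) {
    warning(sum(is.na(delta)), " transcript(s) missing a timepoint; skipped")
    measures <- measures[!is.na(delta), , drop = FALSE]
    delta <- measures$stability_delta
  }
  measures$transcript_id[delta < -log2(min_fold)]
}

#' Intersect bound, down-regulated and destabilized transcript sets
#'
#' The triple intersection is the candidate set of transcripts directly bound
#' and stabilized by the RBP. The summary reports the intersection also as a
#' percentage of the bound set (`pct_of_bound`), the headline statistic of
#' this analysis; it is kept at full precision internally and conventionally
#' reported rounded to 2 decimals.
#'
#' @param bound,down,destab character vectors of transcript ids.
#' @return an object of class `target_calls`: list with `table` (per
#'   transcript: three flags plus `in_intersection`) and `summary`
#'   (`n_bound`, `n_down`, `n_destab`, `n_intersection`, `pct_of_bound`; the
#'   percentage is NA when the bound set is empty).
#' @examples
#' tc <- intersect_targets(c("a", "b"), c("b", "c"), c("b", "d"))
#' tc$summary$n_intersection  # 1
#' @export
intersect_targets <- function(bound, down, destab) {
  universe <- sort(unique(c(bound, down, destab)))
  tab <- data.frame(transcript_id = universe,
                    bound = universe %in% bound,
                    steady_down = universe %in% down,
                    destabilized = universe %in% destab,
                    stringsAsFactors = FALSE)
  tab$in_intersection <- tab$bound & tab$steady_down & tab$destabilized
  n_bound <- sum(tab$bound)
  n_int <- sum(tab$in_intersection)
  pct <- if (n_bound > 0) 100 * n_int / n_bound else NA_real_
  structure(list(table = tab,
                 summary = list(n_bound = n_bound,
                                n_down = sum(tab$steady_down),
                                n_destab = sum(tab$destabilized),
                                n_intersection = n_int,
                                pct_of_bound = pct)),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  s <- x$summary
  pct <- if (is.na(s$pct_of_bound)) "n/a" else
    sprintf("%.2f%%", s$pct_of_bound)
  cat("<target_calls> bound ", s$n_bound, ", steady-state down ", s$n_down,
      ", destabilized ", s$n_destab, "; triple intersection ",
      s$n_intersection, " (", pct, " of bound)\n", sep = "")
  invisible(x)
}

#' Restrict a target set to genes encoding secreted proteins
#'
#' @param targets character vector of target transcript/gene ids.
#' @param secreted_ids user-supplied character vector of secreted-protein
#'   gene ids (no annotation database is bundled).
#' @return the order-preserving intersection `targets` \eqn{\cap}
#'   `secreted_ids`.
#' @export
secreted_filter <- function(targets, secreted_ids) {
  targets[targets %in% secreted_ids]
}

#' 3'UTR length assay from qPCR amplicons along the UTR
#'
#' For each condition, the level of every distal 3'UTR amplicon is expressed
#' relative to the coding-sequence (CDS) amplicon; per amplicon, a two-sided
#' t-test on the log ratios compares the two conditions, with BH adjustment
#' across amplicons. The verdict is "no length change" when no amplicon is
#' significant at `alpha` after adjustment.
#'
#' @param levels data.frame with columns `amplicon`, `condition` (two
#'   levels), `replicate`, `level` (relative expression > 0).
#' @param cds_amplicon id of the CDS reference amplicon.
#' @param alpha significance level on BH-adjusted p (default 0.05).
#' @return list with `table` (amplicon, mean log2 distal/CDS ratio per
#'   condition, p, q, significant) and `verdict`.
#' @export
utr_length_assay <- function(levels, cds_amplicon, alpha = 0.05) {
  need <- c("amplicon", "condition", "replicate", "level")
  if (!all(need %in% names(levels)))
    stop_invalid("levels needs columns ", paste(need, collapse = ", "))
  conds <- unique(levels$condition)
  if (length(conds) != 2L)
    stop_invalid("exactly two conditions are required")
  if (!cds_amplicon %in% levels$amplicon)
    stop_invalid("CDS amplicon '", cds_amplicon, "' absent from the table")
  cds <- levels[levels$amplicon == cds_amplicon, ]
  dist_amps <- setdiff(unique(levels$amplicon), cds_amplicon)
  if (length(dist_amps) == 0L)
    stop_invalid("at least one distal amplicon is required")
  rows <- lapply(dist_amps, function(a) {
    da <- levels[levels$amplicon == a, ]
    key <- function(d) paste(d$condition, d$replicate)
    ratio <- log2(da$level / cds$level[match(key(da), key(cds))])
    g1 <- ratio[da$condition == conds[1L]]
    g2 <- ratio[da$condition == conds[2L]]
    if (length(g1) < 2L || length(g2) < 2L)
      stop_invalid("amplicon ", a, ": >= 2 replicates per condition required")
    p <- if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
      if (mean(g1) == mean(g2)) 1 else 0
    } else {
      stats::t.test(g1, g2, var.equal = TRUE)$p.value
    }
    data.frame(amplicon = a, mean_ratio_1 = mean(g1), mean_ratio_2 = mean(g2),
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  names(tab)[2:3] <- paste0("mean_log2_ratio_", conds)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < alpha
  list(table = tab,
       verdict = if (any(tab$significant)) "length change detected"
                 else "no length change")
}
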