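## Screening module: prioritize RBP genes across three two-group expression
## datasets, then filter candidates by copy-number deletion fraction.

#' Construct a two-group expression dataset
#'
#' @param values numeric matrix of log2 intensities, genes in rows, samples in
#'   columns; rownames are gene ids, colnames are sample ids.
#' @param group factor (or vector coercible to one) with exactly two levels,
#'   one entry per sample. The first level is the reference group; log fold
#'   changes are case minus reference.
#' @return an object of class `expr_dataset`.
#' @export
expression_dataset <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) == 0L)
    stop_invalid("values must be a non-empty numeric matrix")
  if (is.null(rownames(values))) stop_invalid("values must have gene rownames")
  if (anyDuplicated(rownames(values)))
    stop_invalid("duplicate gene ids in values")
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop_invalid("group must have exactly two levels")
  if (length(group) != ncol(values))
    stop_invalid("group length must match the number of samples")
  if (any(table(group) < 2L))
    stop_invalid("each group needs at least 2 samples")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  structure(list(values = values, group = group), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", paste(levels(x$group), table(x$group), collapse = " vs "),
      ")\n", sep = "")
  invisible(x)
}

#' Median-center each gene across all samples
#'
#' Subtracts the per-gene median over \emph{all} samples, reproducing the
#' "log2 median centered intensity" convention of two-group microarray
#' comparisons. Group structure is untouched.
#'
#' @param dataset an [expression_dataset()].
#' @return the dataset with every gene row having median 0.
#' @examples
#' ds <- expression_dataset(
#'   matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL)),
#'   c("n", "n", "t"))
#' apply(median_center(ds)$values, 1, stats::median)  # all zero
#' @export
median_center <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  v <- dataset$values
  if (any(!is.finite(v))) stop_invalid("values must be finite")
  med <- apply(v, 1L, stats::median)
  dataset$values <- v - med
  dataset
}

#' Per-gene two-sample t-test between the dataset's groups
#'
#' Computes, for every gene, the log fold change (case group mean minus
#' reference group mean) and a two-sided two-sample t-test. The default is
#' Student's pooled-variance test; Welch's correction is available via
#' `var_equal = FALSE`. Degenerate genes with zero variance in both groups and
#' equal means get `t = 0, p = 1` by convention; zero variance with unequal
#' means gives `p = 0`.
#'
#' @param dataset an [expression_dataset()]; values are used as-is (apply
#'   [median_center()] first to match the screening convention).
#' @param var_equal pooled-variance (Student) t when `TRUE` (default), Welch
#'   otherwise.
#' @return a data.frame with columns `gene`, `mean_ref`, `mean_case`, `logfc`,
#'   `t`, `p`.
#' @export
two_group_ttest <- function(dataset, var_equal = TRUE) {
  stopifnot(inherits(dataset, "expr_dataset"))
  v <- dataset$values
  g <- dataset$group
  ref <- levels(g)[1L]
  a <- v[, g != ref, drop = FALSE]  # case
  b <- v[, g == ref, drop = FALSE]  # reference
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  diff <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- diff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zerovar <- se == 0
  if (any(zerovar)) {
    t[zerovar] <- ifelse(diff[zerovar] == 0, 0, sign(diff[zerovar]) * Inf)
    p[zerovar] <- ifelse(diff[zerovar] == 0, 1, 0)
    df[zerovar] <- na + nb - 2
  }
  data.frame(gene = rownames(v), mean_ref = mb, mean_case = ma,
             logfc = diff, t = t, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank significantly down-regulated RBP genes and assign percentiles
#'
#' Restricts to RBP genes with `p < alpha` and negative log fold change, ranks
#' them ascending by log fold change (most down-regulated first; ties broken
#' by smaller p, then gene id), and assigns each a down-regulation percentile.
#'
#' The percentile denominator is, by default, the number of RBP genes present
#' in the dataset (`denominator = "rbp_total"`): "top 10% of the most
#' down-regulated RBP genes" then means the most down-regulated tenth of the
#' RBP census, independent of how many genes clear the significance gate.
#' `denominator = "ranked"` divides by the number of gate-passing genes
#' instead.
#'
#' @param stats a data.frame from [two_group_ttest()].
#' @param rbp_ids character vector of RBP gene ids; ids absent from `stats`
#'   are ignored with a warning.
#' @param alpha significance gate on the raw p-value (default 0.05).
#' @param denominator `"rbp_total"` (default) or `"ranked"`; see Details.
#' @return `stats` restricted to the ranked genes, ordered most-down first,
#'   with extra columns `down_rank` and `down_rank_percentile`.
#' @export
rank_top_down <- function(stats, rbp_ids, alpha = 0.05,
                          denominator = c("rbp_total", "ranked")) {
  denominator <- match.arg(denominator)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  missing_ids <- setdiff(rbp_ids, stats$gene)
  if (length(missing_ids))
    warning(length(missing_ids), " RBP id(s) not present in the dataset; ",
            "ignored (e.g. ", missing_ids[1L], ")")
  in_rbp <- stats$gene %in% rbp_ids
  pool <- stats[in_rbp & stats$p < alpha & stats$logfc < 0, , drop = FALSE]
  n_denom <- switch(denominator,
                    rbp_total = sum(in_rbp),
                    ranked = nrow(pool))
  if (nrow(pool) == 0L) {
    pool$down_rank <- integer(0)
    pool$down_rank_percentile <- numeric(0)
    return(pool)
  }
  ord <- order(pool$logfc, pool$p, pool$gene)
  pool <- pool[ord, , drop = FALSE]
  pool$down_rank <- seq_len(nrow(pool))
  pool$down_rank_percentile <- pool$down_rank / n_denom
  rownames(pool) <- NULL
  pool
}

#' Select high-priority genes from three percentile rankings
#'
#' A gene enters the priority set if it satisfies any of three category rules:
#' (1) it scores (percentile at or below `thr_score`) in all three datasets;
#' (2) its percentile is at or below `thr_any1` in at least one dataset; or
#' (3) at or below `thr_any2` in at least two datasets. The result is the
#' union, with each member annotated with every rule it satisfies.
#'
#' @param rankings a list of exactly three data.frames from [rank_top_down()]
#'   (columns `gene`, `down_rank_percentile`).
#' @param thr_score percentile threshold defining "scoring" (default 0.10).
#' @param thr_any1 threshold for the any-one-dataset rule (default 0.05).
#' @param thr_any2 threshold for the any-two-datasets rule (default 0.10).
#' @return a data.frame with columns `gene`, `all_three`, `top5_any_one`,
#'   `top10_any_two`, `rules` (comma-separated), and `percentile_1..3`
#'   (NA where the gene was not ranked).
#' @export
select_high_priority <- function(rankings, thr_score = 0.10,
                                 thr_any1 = 0.05, thr_any2 = 0.10) {
  if (!is.list(rankings) || length(rankings) != 3L)
    stop_invalid("rankings must be a list of exactly three ranking tables")
  for (thr in c(thr_score, thr_any1, thr_any2))
    assert_scalar_number(thr, "threshold", lower = 0, upper = 1)
  genes <- sort(unique(unlist(lapply(rankings, function(r) r$gene))))
  perc <- sapply(rankings, function(r) {
    r$down_rank_percentile[match(genes, r$gene)]
  })
  perc <- matrix(perc, nrow = length(genes), ncol = 3L)
  scoring <- !is.na(perc) & perc <= thr_score
  rule1 <- rowSums(scoring) == 3L
  rule2 <- rowSums(!is.na(perc) & perc <= thr_any1) >= 1L
  rule3 <- rowSums(!is.na(perc) & perc <= thr_any2) >= 2L
  keep <- rule1 | rule2 | rule3
  rules <- vapply(which(keep), function(i) {
    paste(c("all_three", "top5_any_one", "top10_any_two")[
      c(rule1[i], rule2[i], rule3[i])], collapse = ",")
  }, character(1))
  out <- data.frame(gene = genes[keep],
                    all_three = rule1[keep],
                    top5_any_one = rule2[keep],
                    top10_any_two = rule3[keep],
                    rules = rules,
                    percentile_1 = perc[keep, 1L],
                    percentile_2 = perc[keep, 2L],
                    percentile_3 = perc[keep, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Filter a priority set by copy-number deletion fraction
#'
#' Keeps genes deleted in strictly more than `min_fraction` of tumors.
#'
#' @param priority a data.frame with a `gene` column (e.g. from
#'   [select_high_priority()]) or a character vector of gene ids.
#' @param cna a data.frame with columns `gene`, `fraction_deleted` and
#'   optionally `fraction_amplified`, fractions in \[0, 1\].
#' @param min_fraction strict lower bound on `fraction_deleted` (default 0.05).
#' @return a data.frame (`gene`, `fraction_deleted`) sorted descending by
#'   deletion fraction. Genes absent from `cna` are dropped with a warning.
#' @export
filter_by_deletion <- function(priority, cna, min_fraction = 0.05) {
  genes <- if (is.data.frame(priority)) priority$gene else as.character(priority)
  assert_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  if (!all(c("gene", "fraction_deleted") %in% names(cna)))
    stop_invalid("cna must have columns 'gene' and 'fraction_deleted'")
  if (any(cna$fraction_deleted < 0 | cna$fraction_deleted > 1))
    stop_invalid("fraction_deleted must lie in [0, 1]")
  idx <- match(genes, cna$gene)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " priority gene(s) absent from the CNA table; dropped")
    genes <- genes[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  fd <- cna$fraction_deleted[idx]
  keep <- fd > min_fraction
  out <- data.frame(gene = genes[keep], fraction_deleted = fd[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$fraction_deleted, out$gene), , drop = FALSE]
}

#' Run the full RBP screening pipeline
#'
#' Median-centers each dataset, computes per-gene Student t-tests, ranks
#' significantly down-regulated RBP genes, forms the three-category priority
#' set, and applies the copy-number deletion filter.
#'
#' @param datasets list of three [expression_dataset()]s.
#' @param rbp_ids character vector of RBP gene ids.
#' @param cna CNA table (see [filter_by_deletion()]), or NULL to skip the
#'   deletion filter.
#' @param alpha,thr_score,thr_any1,thr_any2,min_fraction thresholds passed to
#'   the component steps.
#' @param denominator percentile convention, see [rank_top_down()].
#' @return a list with `stats` (per-dataset t-test tables), `rankings`,
#'   `priority` (the priority set) and `candidates` (deletion-filtered, NULL
#'   when `cna` is NULL).
#' @export
screen_rbp_candidates <- function(datasets, rbp_ids, cna = NULL,
                                  alpha = 0.05, thr_score = 0.10,
                                  thr_any1 = 0.05, thr_any2 = 0.10,
                                  min_fraction = 0.05,
                                  denominator = "rbp_total") {
  if (length(datasets) != 3L)
    stop_invalid("exactly three datasets are required")
  stats <- lapply(datasets, function(d) two_group_ttest(median_center(d)))
  rankings <- lapply(stats, rank_top_down, rbp_ids = rbp_ids, alpha = alpha,
                     denominator = denominator)
  priority <- select_high_priority(rankings, thr_score, thr_any1, thr_any2)
  candidates <- if (!is.null(cna))
    filter_by_deletion(priority, cna, min_fraction) else NULL
  list(stats = stats, rankings = rankings, priority = priority,
       candidates = candidates)
}
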