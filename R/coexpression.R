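## Co-expression / immune-association module: log2-CPM transform, composite
## high/low groups, immune-factor differential expression, Z-score matrices
## and Pearson correlation.

#' Log2 counts per million (voom-style offset)
#'
#' `log2((count + 0.5) / (library size + 1) * 1e6)`.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @param lib_sizes library sizes per sample (> 0; default column sums).
#' @return numeric matrix of log2-CPM values.
#' @export
logcpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop_invalid("library sizes must be > 0")
  log2(sweep(counts + 0.5, 2L, lib_sizes + 1, "/") * 1e6)
}

#' Composite high/low expression sample groups
#'
#' For a single gene, the high (low) group is the top (bottom)
#' `floor(q * n)` samples by that gene's expression. For a gene pair, the
#' high group is the intersection of both genes' top-q sample sets and the
#' low group the intersection of both bottom-q sets — samples extreme for
#' both genes simultaneously. Ties are broken by sample order (a message is
#' emitted when ties are present).
#'
#' @param expr log-expression matrix (genes x samples) with dimnames.
#' @param genes one or two gene ids present in `expr`.
#' @param q extreme-quantile fraction, in (0, 0.5).
#' @return an object of class `composite_groups`: list with `genes`, `q`,
#'   `high`, `low` (character vectors of sample ids). An empty high or low
#'   group is an error.
#' @export
composite_groups <- function(expr, genes, q = 0.30) {
  assert_scalar_number(q, "q", lower = 0, upper = 0.5, strict_lower = TRUE)
  if (q >= 0.5) stop_invalid("q must be < 0.5")
  if (!length(genes) %in% 1:2) stop_invalid("supply one or two genes")
  if (!all(genes %in% rownames(expr)))
    stop_invalid("gene(s) absent from the matrix: ",
                 paste(setdiff(genes, rownames(expr)), collapse = ", "))
  n <- ncol(expr)
  k <- floor(q * n)
  if (k < 1L) stop_invalid("q * n < 1: no samples selected")
  top_set <- function(g) {
    v <- expr[g, ]
    if (anyDuplicated(v)) message("ties in ", g, " broken by sample order")
    colnames(expr)[order(-v, seq_len(n))[seq_len(k)]]
  }
  bottom_set <- function(g) {
    v <- expr[g, ]
    colnames(expr)[order(v, seq_len(n))[seq_len(k)]]
  }
  high <- Reduce(intersect, lapply(genes, top_set))
  low <- Reduce(intersect, lapply(genes, bottom_set))
  if (length(high) == 0L || length(low) == 0L)
    stop(errorCondition(
      paste0("empty ", if (length(high) == 0L) "high" else "low",
             " composite group for ", paste(genes, collapse = "+"),
             " at q = ", q),
      class = c("rbpscreen_empty_group", "error")))
  structure(list(genes = genes, q = q, high = high, low = low),
            class = "composite_groups")
}

#' @export
print.composite_groups <- function(x, ...) {
  cat("<composite_groups> ", paste(x$genes, collapse = " + "), " at q = ",
      x$q, ": ", length(x$high), " high / ", length(x$low), " low samples\n",
      sep = "")
  invisible(x)
}

#' Immune-factor differential expression between composite groups
#'
#' For each immune-factor gene, the log fold change is the mean log2-CPM in
#' the high group minus the low group; a negative logFC means the factor is
#' higher where the index gene is low (anti-correlation). P-values come from
#' Welch's two-sided t-test with Benjamini-Hochberg adjustment across the
#' immune list; a gene passes when `|logFC| >= lfc_gate` and `p <= p_gate`
#' (the BH q is reported alongside). Immune genes absent from the matrix are
#' skipped with a warning.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param groups a [composite_groups()] object.
#' @param immune_list character vector of immune-factor gene ids.
#' @param lfc_gate absolute log2 fold-change gate (default 0.75). Set
#'   `lfc_scale = "linear"` to interpret the gate as a linear fold change.
#' @param p_gate raw p-value gate (default 0.01).
#' @param lfc_scale `"log2"` (default) or `"linear"`.
#' @return list with `table` (gene, logfc, p, q, passes) and `z` (Z-score
#'   matrix over the high+low samples, via [zscore_rows()]).
#' @export
immune_de <- function(expr, groups, immune_list, lfc_gate = 0.75,
                      p_gate = 0.01, lfc_scale = c("log2", "linear")) {
  stopifnot(inherits(groups, "composite_groups"))
  lfc_scale <- match.arg(lfc_scale)
  if (length(immune_list) == 0L) stop_invalid("immune_list is empty")
  present <- immune_list %in% rownames(expr)
  if (!all(present)) {
    warning(sum(!present), " immune gene(s) absent from the matrix; skipped")
    immune_list <- immune_list[present]
  }
  hi <- expr[immune_list, groups$high, drop = FALSE]
  lo <- expr[immune_list, groups$low, drop = FALSE]
  logfc <- rowMeans(hi) - rowMeans(lo)
  p <- vapply(seq_along(immune_list), function(i) {
    if (stats::sd(hi[i, ]) == 0 && stats::sd(lo[i, ]) == 0)
      return(if (mean(hi[i, ]) == mean(lo[i, ])) 1 else 0)
    stats::t.test(hi[i, ], lo[i, ])$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  gate <- if (lfc_scale == "log2") lfc_gate else log2(lfc_gate)
  passes <- abs(logfc) >= gate & p <= p_gate
  tab <- data.frame(gene = immune_list, logfc = logfc, p = p, q = q,
                    passes = passes, row.names = NULL,
                    stringsAsFactors = FALSE)
  z <- zscore_rows(expr[immune_list, c(groups$high, groups$low),
                        drop = FALSE])
  list(table = tab, z = z)
}

#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; the p-value uses the transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Row-wise Z scores (population standard deviation)
#'
#' Per gene: `(value - row mean) / row sd`, with the population sd
#' (divisor n). Constant rows are returned as zeros with a warning.
#'
#' @param expr numeric matrix (genes x samples).
#' @return Z-score matrix of the same shape.
#' @export
zscore_rows <- function(expr) {
  m <- rowMeans(expr)
  sd_pop <- sqrt(rowMeans((expr - m)^2))
  if (any(sd_pop == 0)) {
    warning(sum(sd_pop == 0), " constant row(s) returned as zeros")
    sd_pop[sd_pop == 0] <- Inf
  }
  (expr - m) / sd_pop
}

#' Simulate an RNA-seq cohort with planted gene-gene correlations
#'
#' A latent Gaussian log2 expression level is drawn per gene and sample with
#' a requested correlation structure; negative-binomial counts are sampled
#' around `2^latent`. Correlations are specified against a single index gene
#' (the first of `genes`) via `r_with_index`; cross-correlations among the
#' other genes follow the implied single-factor structure `r_i * r_j`, which
#' is always positive semi-definite. A full correlation matrix can be given
#' instead and is validated for positive semi-definiteness.
#'
#' @param config a [sim_config()]; `n_cohort_samples` sets the cohort size
#'   (default 354).
#' @param genes character vector of gene names; the first is the index gene.
#' @param r_with_index numeric vector (length `length(genes) - 1`) of target
#'   latent correlations between the index gene and each remaining gene,
#'   each in \[-1, 1\].
#' @param sigma latent log2 standard deviation per gene (default 1).
#' @param cor_matrix optional full latent correlation matrix overriding
#'   `r_with_index`.
#' @param n_background additional uncorrelated background genes (default 50).
#' @return list with `counts` (genes x samples), `lib_sizes`, `latent`
#'   (latent log2 matrix) and `truth` (requested correlation per gene).
#' @export
gen_cohort <- function(config, genes = c("SORBS2", "WFDC1", "IL17D"),
                       r_with_index = c(0.5, 0.5), sigma = 1,
                       cor_matrix = NULL, n_background = 50L) {
  stopifnot(inherits(config, "sim_config"))
  p <- length(genes)
  if (is.null(cor_matrix)) {
    if (length(r_with_index) != p - 1L)
      stop_invalid("r_with_index must have length(genes) - 1 entries")
    if (any(abs(r_with_index) > 1))
      stop_invalid("correlations must lie in [-1, 1]")
    r <- c(1, r_with_index)
    cor_matrix <- outer(r, r)
    diag(cor_matrix) <- 1
  }
  if (!isSymmetric(unname(cor_matrix)) || nrow(cor_matrix) != p)
    stop_invalid("cor_matrix must be a symmetric ", p, "x", p, " matrix")
  ev <- eigen(cor_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_invalid("requested correlation matrix is not positive semi-definite")
  n <- config$n_cohort_samples
  all_genes <- c(genes, if (n_background > 0)
    sprintf("BG%03d", seq_len(n_background)))
  res <- with_substream(config$seed, "cohort", {
    ## factor the (possibly singular) correlation matrix via eigen
    e <- eigen(cor_matrix, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
    z <- matrix(rnorm(n * p), n, p) %*% t(L)  # n x p latent, requested cor
    zbg <- matrix(rnorm(n * max(0L, n_background)), n)
    latent_z <- cbind(z, zbg)
    mu0 <- stats::runif(length(all_genes), 5, 10)  # baseline log2 mean
    latent <- t(latent_z) * sigma + mu0            # genes x samples
    counts <- matrix(rnb(length(latent), 2^latent, config$nb_dispersion),
                     nrow = nrow(latent))
    list(latent = latent, counts = counts)
  })
  dimnames(res$counts) <- list(all_genes, sprintf("P%03d", seq_len(n)))
  dimnames(res$latent) <- dimnames(res$counts)
  truth <- data.frame(gene = all_genes,
                      r_with_index = c(1, if (p > 1) cor_matrix[1, -1],
                                       rep(0, max(0L, n_background))),
                      stringsAsFactors = FALSE)
  list(counts = res$counts, lib_sizes = colSums(res$counts),
       latent = res$latent, truth = truth)
}
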