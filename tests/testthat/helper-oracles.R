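## Independent brute-force oracles and small fixture builders used across the
## suite. Oracles deliberately re-derive results by enumeration or textbook
## formulas, never by calling the code paths they check.

## enumeration oracle for the three-category priority rules
brute_priority <- function(perc, thr_score = 0.10, thr_any1 = 0.05,
                           thr_any2 = 0.10) {
  ## perc: genes x 3 matrix of percentiles (NA = not ranked)
  apply(perc, 1L, function(p) {
    ok <- !is.na(p)
    rule1 <- all(ok) && all(p <= thr_score)
    rule2 <- any(ok & p <= thr_any1)
    rule3 <- sum(ok & p <= thr_any2) >= 2
    rule1 || rule2 || rule3
  })
}

## set-algebra oracle for the triple intersection summary
brute_intersect <- function(bound, down, destab) {
  tri <- intersect(intersect(bound, down), destab)
  list(n_bound = length(unique(bound)), n_down = length(unique(down)),
       n_destab = length(unique(destab)), n_intersection = length(tri),
       pct_of_bound = if (length(unique(bound)) > 0)
         100 * length(tri) / length(unique(bound)) else NA_real_)
}

## textbook pooled-variance two-sample t-test
brute_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(abs(t), na + nb - 2, lower.tail = FALSE))
}

## quantile-intersection oracle for composite groups
brute_composite <- function(expr, genes, q) {
  n <- ncol(expr); k <- floor(q * n)
  tops <- lapply(genes, function(g)
    colnames(expr)[order(-expr[g, ], seq_len(n))[seq_len(k)]])
  bots <- lapply(genes, function(g)
    colnames(expr)[order(expr[g, ], seq_len(n))[seq_len(k)]])
  list(high = Reduce(intersect, tops), low = Reduce(intersect, bots))
}

## small two-group dataset builder
toy_dataset <- function(values, n_ref, n_case,
                        levels_ = c("ref", "case")) {
  expression_dataset(values, factor(rep(levels_, c(n_ref, n_case)),
                                    levels = levels_))
}

## pre-registered seed used for every frozen pilot value in this suite
PILOT_SEED <- 20260909
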