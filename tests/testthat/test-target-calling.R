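## Target-calling module: RPKM, bound calling, peak annotation, steady-state
## and destabilized sets, intersection, secreted filter, UTR-length assay.

test_that("compute_rpkm matches the elementwise formula", {
  expect_equal(compute_rpkm(matrix(0), 500, 1e6)[1, 1], 0)
  expect_equal(compute_rpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  withr::with_seed(5, {
    cts <- matrix(rpois(40, 50), 8, 5)
    len <- sample(200:5000, 8)
    lib <- runif(5, 1e6, 5e6)
  })
  oracle <- matrix(NA_real_, 8, 5)
  for (i in 1:8) for (j in 1:5)
    oracle[i, j] <- cts[i, j] / ((len[i] / 1000) * (lib[j] / 1e6))
  expect_equal(compute_rpkm(cts, len, lib), oracle)
  expect_error(compute_rpkm(matrix(1), 100, 0),
               class = "rbpscreen_invalid_input")
})

test_that("call_bound requires enrichment over input AND IgG plus a floor", {
  base <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                     ip = c(100, 800, 800, 5),
                     input = c(100, 100, 100, 0),
                     igg = c(100, 100, 800, 1))
  rip <- rip_experiment(base, lib_sizes = c(ip = 1e6, input = 1e6, igg = 1e6))
  b <- call_bound(rip)
  expect_identical(b$bound, c(FALSE,  # no enrichment at all
                              TRUE,   # 8x over both controls
                              FALSE,  # enriched over input only
                              FALSE)) # below the input CPM floor
  expect_equal(b$enrichment_input[1], 0)
  ## missing IgG: warning + input-only fallback
  noigg <- rip_experiment(base[c("transcript_id", "ip", "input")],
                          lib_sizes = c(ip = 1e6, input = 1e6))
  expect_warning(b2 <- call_bound(noigg), "IgG")
  expect_true(b2$bound[3])
  ## planted recovery, pilot-fixed at PILOT_SEED: all 50 planted called
  rip_sim <- gen_rip(sim_config(n_genes = 500, n_rbp_genes = 5,
                                seed = PILOT_SEED))
  calls <- call_bound(rip_sim$rip)
  expect_gte(mean(calls$bound[rip_sim$truth$is_bound]), 0.95)
  expect_lte(mean(calls$bound[!rip_sim$truth$is_bound]), 0.01)
})

test_that("annotate_peak_region handles strands, priority and intergenic", {
  model_minus <- data.frame(
    transcript_id = "tx1", chrom = "chr1", strand = "-",
    feature = c("exon", "CDS"), start = c(0, 300), end = c(1000, 900))
  ## peak midpoint 50 bp genomically left of the CDS start: 3'UTR on minus
  ## strand, 50 bp downstream of the stop in transcript orientation
  pk <- data.frame(chrom = "chr1", start = 240, end = 261)
  ann <- annotate_peak_region(pk, model_minus)
  expect_identical(ann$region, "3'UTR")
  expect_identical(ann$distance_to_stop, 50)

  ## plus-strand classification of all compartments
  model_plus <- data.frame(
    transcript_id = "tx2", chrom = "chr2", strand = "+",
    feature = c("exon", "exon", "CDS"),
    start = c(0, 2000, 500), end = c(1000, 3000, 2500))
  pks <- data.frame(chrom = "chr2",
                    start = c(100, 700, 1400, 2700, 5000),
                    end = c(121, 721, 1421, 2721, 5021))
  ann2 <- annotate_peak_region(pks, model_plus)
  expect_identical(ann2$region,
                   c("5'UTR", "CDS", "intron", "3'UTR", "intergenic"))
  expect_true(is.na(ann2$transcript_id[5]))
  ## peak on a chromosome with no model at all
  expect_identical(annotate_peak_region(
    data.frame(chrom = "chrX", start = 0, end = 21), model_plus)$region,
    "intergenic")

  ## strand consistency: mirroring the gene model preserves the label and
  ## the transcript-oriented stop distance
  L <- 10000
  mirror <- function(df) {
    out <- df
    out$start <- L - df$end
    out$end <- L - df$start
    if (!is.null(df$strand))
      out$strand <- ifelse(df$strand == "+", "-", "+")
    out
  }
  ann_m <- annotate_peak_region(mirror(pks), mirror(model_plus))
  expect_identical(ann_m$region, ann2$region)
  expect_identical(ann_m$distance_to_stop, ann2$distance_to_stop)

  expect_error(annotate_peak_region(data.frame(chrom = "c", start = 5, end = 5),
                                    model_plus),
               class = "rbpscreen_invalid_input")
})

test_that("steady_state_down: strict 1.1 boundary and planted recovery", {
  ## identical matrices: nothing selected
  m <- matrix(rpois(20, 100) + 1, 5, 4,
              dimnames = list(paste0("t", 1:5), NULL))
  same <- steady_state_down(m[, 1:2], m[, 1:2], c(1e6, 1e6), c(1e6, 1e6))
  expect_identical(length(same$selected), 0L)

  ## exact 1.1-fold boundary is excluded (strict >): 11/10 == 1.1 in doubles
  kd <- matrix(10, 2, 2, dimnames = list(c("a", "b"), NULL))
  ctrl <- matrix(c(11, 11, 12, 12), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  r <- steady_state_down(kd, ctrl, c(1e6, 1e6), c(1e6, 1e6),
                         pseudocount = 0, fc_only = TRUE)
  expect_equal(r$table$fold_down, c(1.1, 1.2))
  expect_identical(r$selected, "b")

  ## single replicate without fc_only is an instructive error
  expect_error(steady_state_down(m[, 1, drop = FALSE], m[, 2, drop = FALSE]),
               "fc_only")

  ## planted 2-fold-down transcripts recovered at the pilot-fixed rate
  ss <- gen_steady_state(sim_config(n_genes = 500, n_rbp_genes = 5,
                                    seed = PILOT_SEED))
  got <- steady_state_down(ss$kd, ss$ctrl, ss$lib_sizes_kd,
                           ss$lib_sizes_ctrl)
  rec <- mean(ss$truth$transcript_id[ss$truth$is_down] %in% got$selected)
  fp <- mean(ss$truth$transcript_id[!ss$truth$is_down] %in% got$selected)
  expect_gte(rec, 0.40)  # pilot: 0.46 (n = 3, BH-limited at 2-fold)
  expect_lte(fp, 0.02)   # pilot: 0
})

test_that("destabilized_set applies a strict boundary on the delta", {
  meas <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                     stability_delta = c(0, -1, -log2(1.1), -0.2))
  expect_identical(destabilized_set(meas), c("t2", "t4"))
  ## kd retention 25% vs ctrl retention 50% at 9 h: delta -1, included
  m2 <- data.frame(transcript_id = "x", logfc_t0 = 0,
                   logfc_t1 = log2(0.25) - log2(0.5),
                   stability_delta = log2(0.25) - log2(0.5))
  expect_identical(destabilized_set(m2), "x")
  ## missing timepoint: skipped with warning
  m3 <- data.frame(transcript_id = c("a", "b"),
                   stability_delta = c(NA, -2))
  expect_warning(got <- destabilized_set(m3), "skipped")
  expect_identical(got, "b")
  ## threshold monotonicity: raising min_fold never adds members
  withr::with_seed(6, {
    mm <- data.frame(transcript_id = paste0("t", 1:100),
                     stability_delta = rnorm(100, 0, 0.5))
  })
  s1 <- destabilized_set(mm, 1.1)
  s2 <- destabilized_set(mm, 1.5)
  expect_true(all(s2 %in% s1))
})

test_that("intersect_targets equals brute-force set algebra", {
  expect_identical(intersect_targets(c("a"), c("b"), c("c"))$summary$n_intersection, 0L)
  empty_bound <- intersect_targets(character(0), c("a"), c("a"))
  expect_true(is.na(empty_bound$summary$pct_of_bound))
  withr::with_seed(7, {
    for (i in 1:25) {
      u <- sprintf("t%03d", 1:60)
      b <- sample(u, rbinom(1, 60, 0.4))
      d <- sample(u, rbinom(1, 60, 0.4))
      s <- sample(u, rbinom(1, 60, 0.4))
      got <- intersect_targets(b, d, s)$summary
      oracle <- brute_intersect(b, d, s)
      expect_identical(got[c("n_bound", "n_down", "n_destab",
                             "n_intersection")],
                       lapply(oracle[1:4], as.integer))
      expect_equal(got$pct_of_bound, oracle$pct_of_bound)
      if (!is.na(got$pct_of_bound)) {
        expect_gte(got$pct_of_bound, 0)
        expect_lte(got$pct_of_bound, 100)
      }
    }
  })
})

test_that("secreted_filter is an order-preserving intersection", {
  seven <- c("BMPER", "C1QTNF1", "TFPI", "WNT9A", "WFDC1", "LGALS3BP",
             "IL17D")
  targets <- withr::with_seed(8, sample(c(seven, sprintf("g%03d", 1:84))))
  got <- secreted_filter(targets, seven)
  expect_identical(sort(got), sort(seven))
  expect_identical(got, targets[targets %in% seven])  # order preserved
  expect_identical(secreted_filter(targets, character(0)), character(0))
  expect_identical(secreted_filter(seven, c(seven, "extra")), seven)
})

test_that("utr_length_assay flags planted distal shortening only", {
  amps <- c("CDS", "d1", "d2")
  base <- expand.grid(amplicon = amps, condition = c("ctrl", "kd"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  base$level <- 1
  same <- utr_length_assay(base, "CDS")
  expect_true(all(same$table$p == 1))
  expect_identical(same$verdict, "no length change")

  ## halve the distal d2 ratio in knockdown; replicate-level variation is
  ## identical across conditions so only the planted shift can be flagged
  planted <- base
  planted$level <- 1 + 0.001 * planted$replicate
  kd_d2 <- planted$amplicon == "d2" & planted$condition == "kd"
  planted$level[kd_d2] <- 0.5 * planted$level[kd_d2]
  got <- utr_length_assay(planted, "CDS")
  expect_true(got$table$significant[got$table$amplicon == "d2"])
  expect_false(got$table$significant[got$table$amplicon == "d1"])
  expect_identical(got$verdict, "length change detected")

  expect_error(utr_length_assay(base[base$condition == "kd", ], "CDS"),
               class = "rbpscreen_invalid_input")
  expect_error(utr_length_assay(base, "missing"),
               class = "rbpscreen_invalid_input")
})
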