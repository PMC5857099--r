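## Generator contracts: determinism, zero-noise closed forms, planted truth.

test_that("every generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 60, n_rbp_genes = 12, n_planted = 3, seed = 42)
  for (gen in list(gen_screen_datasets, gen_cna, gen_rip, gen_stability,
                   gen_steady_state, gen_timecourse, gen_cohort,
                   gen_survival)) {
    expect_identical(gen(cfg), gen(cfg))
  }
  ## substreams: a different seed changes the draws
  cfg2 <- sim_config(n_genes = 60, n_rbp_genes = 12, n_planted = 3, seed = 43)
  expect_false(identical(gen_screen_datasets(cfg)$datasets[[1]]$values,
                         gen_screen_datasets(cfg2)$datasets[[1]]$values))
})

test_that("screen datasets carry the planted group difference", {
  ## zero-noise limit: the planted contrast is exact
  cfg <- sim_config(n_genes = 40, n_rbp_genes = 10, n_planted = 4,
                    planted_logfc = -1, noise_sd = 1e-12, seed = 5)
  sim <- gen_screen_datasets(cfg)
  for (ds in sim$datasets) {
    diff <- rowMeans(ds$values[, ds$group == levels(ds$group)[2]]) -
      rowMeans(ds$values[, ds$group == levels(ds$group)[1]])
    expect_equal(unname(diff[1:4]), rep(-1, 4), tolerance = 1e-9)
    expect_equal(unname(diff[5:40]), rep(0, 36), tolerance = 1e-9)
  }
  expect_error(sim_config(n_genes = 5, n_rbp_genes = 6),
               class = "rbpscreen_invalid_input")
})

test_that("CNA fractions straddle the deletion threshold as planted", {
  cfg <- sim_config(n_genes = 30, n_rbp_genes = 10, n_planted = 4, seed = 9)
  cna <- gen_cna(cfg)
  expect_true(all(cna$cna$fraction_deleted >= 0 &
                    cna$cna$fraction_deleted <= 1))
  ## planted genes alternate above/below 0.05
  planted <- cna$cna[1:4, ]
  expect_identical(planted$fraction_deleted > 0.05, c(TRUE, FALSE, TRUE, FALSE))
  ## explicit fractions: filter keeps exactly the gene above 0.05
  cna2 <- gen_cna(cfg, fractions = c(G0001 = 0.051, G0002 = 0.049))
  kept <- filter_by_deletion(c("G0001", "G0002"), cna2$cna)
  expect_identical(kept$gene, "G0001")
  ## all-zero fractions: empty filter result
  zero <- gen_cna(cfg, straddle_genes = character(0),
                  fractions = setNames(rep(0, 30), cna$cna$gene))
  expect_identical(nrow(filter_by_deletion(cna$cna$gene, zero$cna)), 0L)
  expect_error(gen_cna(cfg, fractions = c(G0001 = 1.2)),
               class = "rbpscreen_invalid_input")
})

test_that("RIP counts realize the planted enrichment fold in expectation", {
  cfg <- sim_config(n_genes = 400, n_rbp_genes = 10, nb_dispersion = 0,
                    rip_enrichment_fold = 8, seed = 11)
  rip <- gen_rip(cfg, n_bound = 40)
  cts <- rip$rip$counts
  bnd <- rip$truth$is_bound
  expect_equal(sum(cts$ip[bnd]) / sum(cts$input[bnd]), 8, tolerance = 0.05)
  expect_equal(sum(cts$ip[!bnd]) / sum(cts$input[!bnd]), 1, tolerance = 0.05)
  expect_equal(sum(cts$igg[bnd]) / sum(cts$input[bnd]), 1, tolerance = 0.05)
  ## gene models are well-formed: CDS inside the exon union, sorted exons
  for (tx in split(rip$models, rip$models$transcript_id)) {
    ex <- tx[tx$feature == "exon", ]
    cds <- tx[tx$feature == "CDS", ]
    expect_true(all(cds$start >= min(ex$start) & cds$end <= max(ex$end)))
    expect_true(all(diff(sort(ex$start)) > 0))
  }
  expect_error(sim_config(rip_enrichment_fold = 1),
               class = "rbpscreen_invalid_input")
})

test_that("planted RIP peaks all annotate to the 3'UTR", {
  cfg <- sim_config(n_genes = 50, n_rbp_genes = 5, seed = 12)
  rip <- gen_rip(cfg, n_bound = 20)
  ann <- annotate_peak_region(rip$peaks, rip$models)
  expect_true(all(ann$region == "3'UTR"))
  expect_true(all(ann$distance_to_stop > 0))
})

test_that("stability generator reproduces half-life arithmetic exactly", {
  cfg <- sim_config(n_genes = 50, n_rbp_genes = 5, nb_dispersion = 0,
                    half_life_hours = list(control = 9, knockdown = 4.5),
                    seed = 13)
  st <- gen_stability(cfg, n_destab = 10, t_hours = 9)
  ## control retains half at 9 h (t_half = 9): totals ratio ~ 0.5
  tot <- colSums(st$counts)
  ctrl0 <- tot[st$samples$condition == "control" & st$samples$time_h == 0]
  ctrl9 <- tot[st$samples$condition == "control" & st$samples$time_h == 9]
  expect_equal(unname(mean(ctrl9) / mean(ctrl0)), 0.5, tolerance = 0.03)
  ## near-zero dispersion: measured stability delta approaches -1 for the
  ## planted transcripts (kd 4.5 h vs ctrl 9 h at 9 h <=> log2(1/4) - log2(1/2))
  cfg0 <- sim_config(n_genes = 300, n_rbp_genes = 5, nb_dispersion = 0,
                     seed = 14)
  st0 <- gen_stability(cfg0, n_destab = 60)
  sm <- stability_measures(st0$counts, st0$samples, st0$lib_sizes)
  expect_equal(mean(sm$stability_delta[st0$truth$is_destabilized]), -1,
               tolerance = 0.05)
  expect_equal(mean(sm$stability_delta[!st0$truth$is_destabilized]), 0,
               tolerance = 0.05)
  expect_error(
    sim_config(half_life_hours = list(control = -1, knockdown = 2)),
    class = "rbpscreen_invalid_input")
})

test_that("timecourse generator honors closed forms and recovers k", {
  cfg <- sim_config(seed = 15)
  flat <- gen_timecourse(cfg, genes = "g", k = list(g = c(control = 0)),
                         noise_cv = 0)
  expect_true(all(flat$tc$abundance == 1))
  half8 <- gen_timecourse(cfg, genes = "g",
                          k = list(g = c(control = log(2) / 8)),
                          noise_cv = 0)
  expect_equal(unique(half8$tc$abundance[half8$tc$time_h == 8]), 0.5)
  ## pilot-fixed at PILOT_SEED: k recovered within +/-10% at 10% noise, n=3
  g <- gen_timecourse(sim_config(seed = PILOT_SEED), genes = "g",
                      k = list(g = c(control = 0.2)))
  expect_equal(fit_decay(g$tc)$k, 0.2, tolerance = 0.10)
  expect_error(gen_timecourse(cfg, genes = "g", k = list(g = c(control = -1))),
               class = "rbpscreen_invalid_input")
})

test_that("cohort generator plants latent correlations", {
  cfg <- sim_config(seed = 16)
  ch <- gen_cohort(cfg, genes = c("A", "B", "C"), r_with_index = c(0, -0.9))
  expr <- logcpm(ch$counts, ch$lib_sizes)
  expect_lt(abs(cor(expr["A", ], expr["B", ])), 0.1)  # sampling bound, n=354
  expect_lt(cor(expr["A", ], expr["C", ]), -0.7)
  ## identical latent vectors: r = 1 exactly on the latent log scale
  ch2 <- gen_cohort(cfg, genes = c("A", "B"), r_with_index = 1,
                    n_background = 0L)
  expect_equal(cor(ch2$latent["A", ], ch2$latent["B", ]), 1)
  expect_error(
    gen_cohort(cfg, genes = c("A", "B", "C"),
               cor_matrix = matrix(c(1, 1, -1, 1, 1, 1, -1, 1, 1), 3)),
    class = "rbpscreen_invalid_input")
})

test_that("survival generator: KM steps and censoring contract", {
  cfg <- sim_config(seed = 17, hazard_beta = 0)
  sv <- gen_survival(cfg, n = 40, censor_rate = 0)$table
  expect_true(all(sv$event == 1))
  km <- km_curve(sv$time, sv$event)
  ## no censoring, all times distinct: drops by exactly 1/n at each event
  expect_equal(km$surv, 1 - seq_len(40) / 40)
  expect_error(gen_survival(cfg, censor_rate = 1),
               class = "rbpscreen_invalid_input")
})

test_that("fixture_venn hits requested region counts and errors when infeasible", {
  m <- fixture_venn(10, 10, 10, 10)
  expect_true(all(m$bound & m$steady_down & m$destabilized))
  expect_identical(nrow(m), 10L)
  expect_error(fixture_venn(5, 5, 5, 6), class = "rbpscreen_infeasible")
  expect_error(fixture_venn(5, 5, 5, 3,
                            pairwise_overlaps = c(bound_down = 5,
                                                  bound_destab = 5,
                                                  down_destab = 3)),
               "bound_only")
  ## inclusion-exclusion round trip on a batch of random feasible requests
  withr::with_seed(101, {
    for (i in 1:20) {
      tri <- sample(0:20, 1)
      sizes <- tri + sample(0:30, 3, replace = TRUE)
      m <- fixture_venn(sizes[1], sizes[2], sizes[3], tri, seed = i)
      calls <- intersect_targets(m$transcript_id[m$bound],
                                 m$transcript_id[m$steady_down],
                                 m$transcript_id[m$destabilized])
      expect_identical(calls$summary$n_bound, sizes[1])
      expect_identical(calls$summary$n_down, sizes[2])
      expect_identical(calls$summary$n_destab, sizes[3])
      expect_identical(calls$summary$n_intersection, tri)
    }
  })
})

test_that("null-hazard survival simulations calibrate the log-rank test", {
  ## type-I error within the 95% binomial CI of alpha = 0.05 over 200 reps
  reject <- vapply(1:200, function(i) {
    sv <- gen_survival(sim_config(seed = 7000 + i, hazard_beta = 0),
                       n = 60)$table
    med <- median(sv$expression)
    grp <- factor(ifelse(sv$expression <= med, "low", "high"),
                  levels = c("low", "high"))
    logrank_test(sv$time, sv$event, grp)$p < 0.05
  }, logical(1))
  expect_gte(sum(reject), qbinom(0.025, 200, 0.05))
  expect_lte(sum(reject), qbinom(0.975, 200, 0.05))
})
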