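short_scan_cfg <- function(...) {
  scan_config(
    n_sim = 4000,
    mcmc = list(chain_length = 2500, burn_in = 800, thin = 5, chains = 1),
    ...
  )
}

test_that("dominant F_ST is near zero without structure", {
  cfg <- sim_config(
    n_clusters = 5, pops_per_cluster = 1, n_admixed = 0,
    n_individuals_per_pop = 200, f_ct = 0, f_sc = 0, n_loci = 300,
    n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0, seed = 8
  )
  bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
  fst <- dominant_fst(bm)
  expect_lt(abs(attr(fst, "mean_fst")), 0.01)
  expect_gt(mean(abs(fst$fst) < 0.02), 0.85)
})

test_that("dominant F_ST recovers planted differentiation", {
  cfg <- sim_config(
    n_clusters = 5, pops_per_cluster = 1, n_admixed = 0,
    n_individuals_per_pop = 200, f_ct = 0.1, f_sc = 0, n_loci = 500,
    missing_rate = 0, n_replicate_pairs = 0, n_selected_loci = 0, seed = 7
  )
  bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
  fst <- dominant_fst(bm)
  expect_lt(abs(attr(fst, "mean_fst") - 0.1), 0.015)
  expect_true(all(fst$fst >= -1 & fst$fst <= 1))
})

test_that("opposite fixation gives near-maximal per-locus F_ST", {
  n <- 100
  x <- cbind(
    focal = rep(c(1L, 0L), each = n),
    filler1 = rep(c(0L, 1L), n),
    filler2 = rep(c(1L, 1L, 0L, 0L), n / 2)
  )
  rownames(x) <- paste0("i", seq_len(2 * n))
  m <- band_matrix(x, rep(c("A", "B"), each = n))
  fst <- dominant_fst(m)
  expect_gt(fst$fst[fst$locus == "focal"], 0.9)
})

test_that("monomorphic loci are excluded and counted", {
  x <- cbind(
    mono1 = rep(1L, 20), mono0 = rep(0L, 20),
    poly = rep(c(0L, 1L), 10)
  )
  rownames(x) <- paste0("i", 1:20)
  m <- band_matrix(x, rep(c("A", "B"), each = 10))
  fst <- dominant_fst(m)
  expect_equal(attr(fst, "n_excluded"), 2L)
  expect_setequal(attr(fst, "excluded_loci"), c("mono1", "mono0"))
  expect_identical(fst$locus, "poly")
})

test_that("iterative removal lowers the recalibrated target mean", {
  sim <- simulate_dataset(sim_config(seed = 11, selection_slope = 2.5))
  bm <- drop_replicates(sim$band_matrix)
  fd <- fdist_scan(bm, short_scan_cfg(), seed = 1)
  th <- attr(fd, "target_history")
  expect_gte(length(th), 2)
  expect_true(all(diff(th) < 0))
  expect_gt(sum(fd$candidate), 0)
  # reproducibility from the seed
  fd2 <- fdist_scan(bm, short_scan_cfg(), seed = 1)
  expect_identical(fd$p, fd2$p)
  expect_identical(fd$candidate, fd2$candidate)
})

test_that("the Bayesian scan with inclusion forbidden reports zero PIP", {
  dat <- two_cluster_bm(n_loci = 40, f_ct = 0.08, n_ind = 10, seed = 5)
  cfg <- scan_config(mcmc = list(
    chain_length = 400, burn_in = 100, thin = 2, chains = 1, prior_odds = 0
  ))
  bs <- suppressWarnings(bayescan_scan(dat$bm, cfg, seed = 2))
  expect_true(all(bs$pip == 0))
  expect_true(all(bs$qvalue == 1))
})

test_that("Bayesian q-values are monotone in the inclusion ranking", {
  dat <- two_cluster_bm(n_loci = 60, f_ct = 0.08, n_ind = 10, seed = 6)
  cfg <- scan_config(mcmc = list(
    chain_length = 800, burn_in = 200, thin = 2, chains = 1
  ))
  bs <- suppressWarnings(bayescan_scan(dat$bm, cfg, seed = 3))
  ord <- order(bs$pip, decreasing = TRUE)
  expect_true(all(diff(bs$qvalue[ord]) >= -1e-12))
  expect_true(all(bs$qvalue >= 0 & bs$qvalue <= 1))
})

test_that("a strongly differentiated locus earns high inclusion probability", {
  # background island F ~ 0.07, one locus fixed for opposite alleles between
  # the two halves of the gradient
  cfg <- sim_config(
    n_clusters = 9, pops_per_cluster = 1, n_admixed = 0,
    n_individuals_per_pop = 15, f_ct = 0.07, f_sc = 0, n_loci = 120,
    n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0, seed = 12
  )
  fs <- simulate_hierarchical_frequencies(cfg)
  fs$freq[, "L1"] <- rep(c(0.05, 0.95), c(4, 5))
  bm <- simulate_band_matrix(fs, cfg)
  bs <- bayescan_scan(bm, short_scan_cfg(), seed = 4)
  expect_gt(bs$pip[bs$locus == "L1"], 0.9)
  expect_lte(bs$qvalue[bs$locus == "L1"], 0.05)
})

test_that("the association scan counts models and rejects a strong signal", {
  # deterministic band frequencies 0.1 / 0.5 / 0.9 along predictor -1/0/1
  freq_band <- c(A = 0.1, B = 0.5, C = 0.9)
  p_allele <- 1 - sqrt(1 - freq_band)
  f <- rbind(
    A = c(p_allele["A"], 0.4), B = c(p_allele["B"], 0.4), C = c(p_allele["C"], 0.4)
  )
  colnames(f) <- c("signal", "noise")
  cfg <- sim_config(
    n_clusters = 1, pops_per_cluster = 3, n_admixed = 0,
    n_individuals_per_pop = 200, n_loci = 2, n_selected_loci = 0,
    missing_rate = 0, n_replicate_pairs = 0, seed = 13
  )
  bm <- simulate_band_matrix(f, cfg)
  bm$population <- rep(c("A", "B", "C"), each = 200)
  pred <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(c("A", "B", "C"), "axis1"))
  sam <- sam_scan(bm, pred, alpha = 0.01)
  expect_equal(attr(sam, "n_models"), 2L)
  sig <- sam[sam$locus == "signal", ]
  expect_lt(sig$wald_p, 1e-5)
  expect_lt(sig$g_p, 1e-5)
  expect_true(sig$significant)
  expect_gte(min(sam$g_stat), 0)
  # flags invariant to locus order
  bm2 <- band_matrix(bm$x[, c(2, 1)], bm$population)
  sam2 <- sam_scan(bm2, pred, alpha = 0.01)
  expect_equal(
    sam2$significant[match(sam$locus, sam2$locus)],
    sam$significant
  )
  expect_error(
    sam_scan(bm, matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "flat"))),
    "constant"
  )
})

test_that("Bonferroni control keeps the family-wise error in check", {
  any_hit <- vapply(1:10, function(r) {
    cfg <- sim_config(
      n_clusters = 9, pops_per_cluster = 1, n_admixed = 0,
      n_individuals_per_pop = 15, f_ct = 0, f_sc = 0, n_loci = 60,
      n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0,
      seed = 700 + r
    )
    bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
    pred <- withr::with_seed(800 + r, {
      matrix(rnorm(9), 9, 1, dimnames = list(sort(unique(bm$population)), "x"))
    })
    any(sam_scan(bm, pred, alpha = 0.01)$significant)
  }, TRUE)
  expect_lte(sum(any_hit), 2)
})

test_that("consensus flags combine candidate sets", {
  c1 <- consensus_outliers(list(fdist = c("L1", "L2")))
  expect_setequal(c1$locus, c("L1", "L2"))
  expect_true(all(c1$n_methods == 1))
  c2 <- consensus_outliers(list(a = c("L1"), b = c("L2")))
  expect_true(all(c2$n_methods == 1))
  c3 <- consensus_outliers(list(a = c("L1", "L3"), b = c("L3")))
  expect_equal(c3$n_methods[c3$locus == "L3"], 2)
})

test_that("trait correlations prune duplicates and find exact relations", {
  sim <- simulate_dataset(sim_config(seed = 14))
  ft <- band_frequencies(drop_replicates(sim$band_matrix))
  f <- freq_matrix(ft, "f")
  lc <- sim$truth$designated_locus
  twin <- withr::with_seed(40, rnorm(nrow(f)))
  ph <- list(
    net_house = tibble::tibble(
      population = rownames(f),
      mirror = f[, lc], # identical to the locus frequencies
      twin_a = twin,
      twin_b = 2 * twin # exact duplicate up to scale
    )
  )
  expect_warning(
    tc <- locus_trait_correlation(ft, ph, loci = lc),
    NA
  )
  pruned <- attr(tc, "pruned_traits")$net_house
  expect_length(pruned, 1)
  expect_true(pruned %in% c("twin_a", "twin_b"))
  mr <- tc[tc$trait == "mirror", ]
  expect_equal(mr$r, 1)
  expect_lt(mr$p_adj, 1e-6)
  expect_true(mr$significant)
})

test_that("the planted locus-trait link is recovered across replicates", {
  # with only nine populations, redundancy pruning occasionally removes the
  # linked trait itself (spurious inter-trait correlations at n = 9), so the
  # recovery rate is checked against a floor below the asymptotic rate
  hits <- vapply(1:25, function(r) {
    sim <- simulate_dataset(sim_config(seed = 900 + r))
    ft <- band_frequencies(drop_replicates(sim$band_matrix))
    tc <- locus_trait_correlation(ft, sim$phenotypes, sim$truth$designated_locus)
    any(
      tc$significant &
        tc$trait == "stem_trichomes" & tc$experiment == "net_house"
    )
  }, TRUE)
  expect_gte(mean(hits), 0.6)
})
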