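test_that("config validation rejects impossible settings", {
  expect_error(sim_config(f_ct = 1), "f_ct")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(n_selected_loci = 300, n_loci = 100), "exceeds")
  expect_error(
    plant_selected_loci(
      simulate_hierarchical_frequencies(small_cfg()),
      rep(0, 9),
      sim_config(n_loci = 60, n_selected_loci = 61)
    ),
    "exceeds"
  )
})

test_that("the same config and seed reproduce the dataset exactly", {
  s1 <- simulate_dataset(small_cfg())
  s2 <- simulate_dataset(small_cfg())
  expect_identical(s1$band_matrix, s2$band_matrix)
  expect_identical(s1$site_table, s2$site_table)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$selected_loci, s2$truth$selected_loci)
  f1 <- simulate_hierarchical_frequencies(small_cfg())
  f2 <- simulate_hierarchical_frequencies(small_cfg())
  expect_identical(f1$freq, f2$freq)
})

test_that("zero differentiation collapses the Beta cascade", {
  cfg <- small_cfg(f_ct = 0, f_sc = 0, n_admixed = 0)
  fs <- simulate_hierarchical_frequencies(cfg)
  for (i in seq_len(nrow(fs$freq))) {
    expect_equal(unname(fs$freq[i, ]), fs$ancestral)
  }
})

test_that("the admixed population is the 50/50 donor mixture", {
  fs <- simulate_hierarchical_frequencies(small_cfg())
  adm <- fs$populations$population[fs$populations$admixed]
  expect_length(adm, 1)
  expect_equal(
    fs$freq[adm, ],
    (fs$freq[fs$donors[1], ] + fs$freq[fs$donors[2], ]) / 2
  )
})

test_that("planted differentiation is recovered by the moment estimator", {
  # 30 demes drawn around the ancestral frequency at F = 0.08; the oracle is
  # an independent ratio-of-sums moment estimator applied to the true
  # frequencies (infinite within-deme sample)
  cfg <- sim_config(
    n_clusters = 30, pops_per_cluster = 1, n_admixed = 0,
    f_ct = 0.08, f_sc = 0, n_loci = 3000, n_selected_loci = 0, seed = 42
  )
  fs <- simulate_hierarchical_frequencies(cfg)
  big_n <- matrix(1e7, nrow(fs$freq), ncol(fs$freq))
  ora <- oracle_theta(fs$freq, big_n)
  expect_equal(ora, 0.08, tolerance = 0.01)
  est <- aflpscape:::wc_theta(fs$freq, big_n)
  # package per-locus estimates agree with the oracle in the mean (the
  # per-locus average carries a small Jensen bias relative to the
  # ratio-of-sums form, hence the absolute band)
  expect_lt(abs(mean(est$theta) - ora), 0.01)
})

test_that("selection planting shifts frequencies as configured", {
  cfg <- small_cfg(n_selected_loci = 5, selection_slope = 0)
  fs <- simulate_hierarchical_frequencies(cfg)
  env <- as.numeric(scale(seq_len(nrow(fs$freq))))
  planted <- plant_selected_loci(fs, env, cfg)
  sel <- planted$truth$selected_loci
  for (lc in sel) {
    expect_equal(
      unname(planted$freq_sim$freq[, lc]),
      rep(fs$ancestral[match(lc, colnames(fs$freq))], nrow(fs$freq))
    )
  }

  # slope 2 over a +-1.5 gradient lifts planted-locus F_ST above the
  # neutral mean (computed on true frequencies)
  cfg2 <- sim_config(
    n_loci = 400, n_selected_loci = 20, selection_slope = 2, seed = 17
  )
  fs2 <- simulate_hierarchical_frequencies(cfg2)
  env2 <- as.numeric(scale(seq_len(nrow(fs2$freq))))
  pl2 <- plant_selected_loci(fs2, env2, cfg2)
  big_n <- matrix(1e7, nrow(fs2$freq), ncol(fs2$freq))
  est <- aflpscape:::wc_theta(pl2$freq_sim$freq, big_n)
  sel_idx <- match(pl2$truth$selected_loci, colnames(fs2$freq))
  expect_gt(mean(est$theta[sel_idx]), mean(est$theta[-sel_idx], na.rm = TRUE))
})

test_that("truth round-trips through the JSON writer unchanged", {
  sim <- simulate_dataset(small_cfg())
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_identical(back$selected_loci, sim$truth$selected_loci)
  expect_identical(back$designated_locus, sim$truth$designated_locus)
  expect_equal(back$env_values, sim$truth$env_values)
  expect_equal(back$f_ct, sim$truth$f_ct)
})

test_that("band sampling follows Hardy-Weinberg dominance", {
  cfg <- sim_config(
    n_clusters = 1, pops_per_cluster = 1, n_admixed = 0,
    n_individuals_per_pop = 400, n_loci = 5, n_selected_loci = 0,
    missing_rate = 0, n_replicate_pairs = 0, seed = 3
  )
  # p = 1 everywhere -> all bands present
  f1 <- matrix(1, 1, 5, dimnames = list("A", paste0("L", 1:5)))
  expect_true(all(simulate_band_matrix(f1, cfg)$x == 1L))
  # p = 0.5 -> band probability 0.75
  f5 <- matrix(0.5, 1, 5, dimnames = list("A", paste0("L", 1:5)))
  bm <- simulate_band_matrix(f5, cfg)
  expect_equal(mean(bm$x), 0.75, tolerance = 0.02)
})

test_that("environment gradient strength controls the climate correlation", {
  r_with_lat <- function(strength, seeds) {
    vapply(seeds, function(s) {
      st <- simulate_environment(sim_config(env_gradient_strength = strength), seed = s)
      cor(st$rainfall, st$latitude)
    }, 0)
  }
  r1 <- r_with_lat(1, 1:100)
  expect_gt(mean(abs(r1)), 0.8)
  r0 <- r_with_lat(0, 1:100)
  expect_lt(abs(mean(r0)), 0.2)
  expect_identical(
    simulate_environment(small_cfg(), seed = 4),
    simulate_environment(small_cfg(), seed = 4)
  )
})

test_that("phenotype means respond to environment and the planted locus", {
  # all coefficients zero, no noise -> constant traits
  coefs0 <- list(net_house = c(stalk_height = 0), common_garden = c(stalk_height = 0))
  cfg0 <- small_cfg(
    phenotype_env_coefs = coefs0, phenotype_locus_coef = 0, noise_sd = 0
  )
  sim0 <- simulate_dataset(cfg0)
  expect_equal(var(sim0$phenotypes$net_house$stalk_height), 0)

  # strong locus effect, small noise -> |r| > 0.9 with the designated locus
  cfg1 <- sim_config(seed = 23, phenotype_locus_coef = 3, noise_sd = 0.05)
  sim1 <- simulate_dataset(cfg1)
  lc <- sim1$truth$designated_locus
  bf <- 1 - (1 - sim1$freq_sim$freq[, lc])^2
  r <- cor(bf, sim1$phenotypes$net_house$stem_trichomes)
  expect_gt(abs(r), 0.9)
  expect_identical(
    simulate_phenotypes(
      sim1$site_table, sim1$freq_sim, sim1$truth, cfg1
    ),
    sim1$phenotypes
  )
})
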