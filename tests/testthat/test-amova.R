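# from-definition AMOVA oracle: explicit loops over the squared-distance
# matrix, sums of squares from the textbook identities, components by
# solving the expected-mean-square equations
oracle_amova2 <- function(D2, pop) {
  N <- nrow(D2)
  pops <- unique(pop)
  P <- length(pops)
  sst <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sst <- sst + D2[i, j]
  sst <- sst / N
  ssw <- 0
  for (g in pops) {
    idx <- which(pop == g)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + D2[i, j]
    ssw <- ssw + acc / (2 * length(idx))
  }
  ssa <- sst - ssw
  msa <- ssa / (P - 1)
  msw <- ssw / (N - P)
  n_p <- as.numeric(table(pop)[pops])
  nprime <- (N - sum(n_p^2) / N) / (P - 1)
  sw <- msw
  sa <- (msa - msw) / nprime
  list(ss = c(ssa, ssw), sigma2 = c(sa, sw), phi = sa / (sa + sw))
}

test_that("two-level components equal the from-definition oracle", {
  # 4 individuals, 2 populations, hand-specified profiles
  x <- rbind(
    i1 = c(1L, 1L, 0L, 0L, 1L),
    i2 = c(1L, 0L, 0L, 1L, 1L),
    i3 = c(0L, 1L, 1L, 0L, 0L),
    i4 = c(0L, 0L, 1L, 1L, 0L)
  )
  colnames(x) <- paste0("L", 1:5)
  m <- band_matrix(x, c("A", "A", "B", "B"))
  res <- amova(m, n_perm = 0)
  D2 <- aflpscape:::individual_dist2(m)
  ora <- oracle_amova2(D2, m$population)
  expect_equal(res$table$SS, ora$ss, tolerance = 1e-12)
  expect_equal(res$table$sigma2, ora$sigma2, tolerance = 1e-12)
  expect_equal(unname(res$phi["phi_st"]), ora$phi, tolerance = 1e-12)
  expect_equal(sum(res$table$df), nrow(x) - 1)
})

test_that("identical individuals give zero components and Phi_ST = 0", {
  x <- matrix(1L, 8, 6, dimnames = list(paste0("i", 1:8), paste0("L", 1:6)))
  m <- band_matrix(x, rep(c("A", "B"), each = 4))
  res <- amova(m, n_perm = 0)
  expect_equal(res$table$sigma2, c(0, 0))
  expect_equal(unname(res$phi["phi_st"]), 0)
})

test_that("percentages sum to 100 and statistics ignore individual order", {
  sim <- simulate_dataset(small_cfg())
  bm <- drop_replicates(sim$band_matrix)
  groups <- setNames(
    sim$freq_sim$populations$cluster,
    sim$freq_sim$populations$population
  )
  groups[groups == "ADM"] <- "C2" # assign the admixed population explicitly
  res <- amova(bm, groups = groups, n_perm = 0)
  expect_equal(sum(res$table$percent), 100, tolerance = 1e-9)
  expect_equal(sum(res$table$df), nrow(bm$x) - 1)

  perm <- withr::with_seed(1, sample(nrow(bm$x)))
  bmp <- band_matrix(bm$x[perm, ], bm$population[perm])
  resp <- amova(bmp, groups = groups, n_perm = 0)
  expect_equal(resp$phi, res$phi, tolerance = 1e-12)
  expect_equal(resp$table$sigma2, res$table$sigma2, tolerance = 1e-12)
})

test_that("hierarchical permutation p-values respond to real structure", {
  dat <- two_cluster_bm(n_loci = 120, f_ct = 0.12, seed = 33)
  groups <- setNames(
    rep(c("G1", "G2"), each = 3), sprintf("P%02d", 1:6)
  )
  res <- amova(dat$bm, groups = groups, n_perm = 199, seed = 7)
  expect_lt(res$p_values["phi_st"], 0.05)
  expect_true(all(res$p_values > 0 & res$p_values <= 1))
  expect_equal(res$design, "three-level")
  expect_named(res$phi, c("phi_ct", "phi_sc", "phi_st"))
})

test_that("pairwise Phi_ST agrees with the two-population AMOVA", {
  sim <- simulate_dataset(small_cfg(seed = 55))
  bm <- drop_replicates(sim$band_matrix)
  ph <- pairwise_phist(bm)
  pops <- sort(unique(bm$population))
  keep <- bm$population %in% pops[c(2, 5)]
  sub <- band_matrix(bm$x[keep, ], bm$population[keep])
  res <- amova(sub, n_perm = 0)
  expect_equal(ph[pops[2], pops[5]], unname(res$phi["phi_st"]), tolerance = 1e-12)
  expect_equal(ph, t(ph))
})

test_that("an exactly duplicated population shows (near) zero Phi_ST", {
  withr::with_seed(21, {
    x <- matrix(rbinom(25 * 40, 1, 0.5), 25, 40)
  })
  colnames(x) <- paste0("L", 1:40)
  xx <- rbind(x, x)
  rownames(xx) <- paste0("i", 1:50)
  m <- band_matrix(xx, rep(c("A", "B"), each = 25))
  ph <- pairwise_phist(m)
  expect_lt(abs(ph["A", "B"]), 0.05)
})

test_that("pairwise Phi_ST increases with planted differentiation", {
  med_phi <- vapply(c(0.02, 0.05, 0.1), function(fsc) {
    reps <- vapply(1:3, function(r) {
      cfg <- sim_config(
        n_clusters = 1, pops_per_cluster = 5, n_admixed = 0,
        n_individuals_per_pop = 12, n_loci = 120, f_ct = 0, f_sc = fsc,
        n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0,
        seed = 100 * r + round(1000 * fsc)
      )
      bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
      stats::median(aflpscape:::unfold_lower(pairwise_phist(bm)))
    }, 0)
    stats::median(reps)
  }, 0)
  expect_true(all(diff(med_phi) > 0))
})

test_that("null AMOVA p-values are roughly uniform", {
  # no structure at all: individuals exchangeable among populations
  pvals <- vapply(1:40, function(r) {
    cfg <- sim_config(
      n_clusters = 1, pops_per_cluster = 4, n_admixed = 0,
      n_individuals_per_pop = 8, n_loci = 50, f_ct = 0, f_sc = 0,
      n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0,
      seed = 500 + r
    )
    bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
    amova(bm, n_perm = 99, seed = r)$p_values[["phi_st"]]
  }, 0)
  expect_lt(mean(pvals <= 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
})
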