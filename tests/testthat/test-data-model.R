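test_that("band matrix construction enforces its invariants", {
  x <- matrix(c(1, 0, NA, 1), 2, 2)
  expect_s3_class(band_matrix(x, c("A", "A")), "band_matrix")
  expect_error(band_matrix(matrix(2, 2, 2), c("A", "A")), "0, 1 or NA")
  xdup <- matrix(0:1, 2, 2, dimnames = list(c("i", "i"), NULL))
  expect_error(band_matrix(xdup, c("A", "A")), "duplicate")
  xallna <- matrix(c(1, 1, NA, NA), 2, 2)
  expect_error(band_matrix(xallna, c("A", "A")), "non-missing")
})

test_that("band matrix round-trips through both file dialects", {
  m <- tiny_bm()
  for (dialect in c("plain01", "genalex")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_band_matrix(m, path, dialect = dialect)
    m2 <- read_band_matrix(path, dialect = dialect)
    expect_identical(m2$x, m$x)
    expect_identical(m2$population, m$population)
    expect_identical(m2$replicate_of, m$replicate_of)
  }
})

test_that("missing codes reduce n_eff and parse errors carry line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,population,L1,L2",
    "i1,A,1,0",
    "i2,A,-9,1",
    "i3,B,0,1",
    "i4,B,1,1"
  ), path)
  m <- read_band_matrix(path)
  expect_true(is.na(m$x["i2", "L1"]))
  ft <- band_frequencies(m)
  expect_equal(ft$n_eff[ft$population == "A" & ft$locus == "L1"], 1L)

  writeLines(c("individual,population,L1", "i1,A,1", "i2,A"), path)
  expect_error(read_band_matrix(path), "ragged row at line 3")
  writeLines(c("individual,population,L1", "i1,A,7"), path)
  expect_error(read_band_matrix(path), "unknown code '7'")
  writeLines(c("individual,population,L1", "i1,A,1", "i1,B,0"), path)
  expect_error(read_band_matrix(path), "duplicate individual id 'i1'")
})

test_that("a survey-sized file parses in under a second", {
  cfg <- sim_config(seed = 12)
  bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_matrix(bm, path)
  elapsed <- system.time(m <- read_band_matrix(path))[["elapsed"]]
  expect_gte(nrow(m$x), 131)
  expect_identical(ncol(m$x), 229L)
  expect_lt(elapsed, 1)
})

test_that("band frequencies follow their definition and ignore row order", {
  m <- tiny_bm()
  ft <- band_frequencies(m)
  # population A, locus L4: 2 present of 2 scored
  expect_equal(ft$f[ft$population == "A" & ft$locus == "L4"], 1)
  expect_equal(ft$n_eff[ft$population == "A" & ft$locus == "L4"], 2L)
  # 3 present of 4 non-missing (1 of 5 missing) -> 0.75
  x <- matrix(c(1L, 1L, 1L, 0L, NA), ncol = 1)
  m5 <- band_matrix(x, rep("A", 5))
  ft5 <- band_frequencies(m5)
  expect_equal(ft5$f, 0.75)
  expect_equal(ft5$n_eff, 4L)
  # permutation invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  mp <- band_matrix(m$x[perm, ], m$population[perm])
  expect_equal(band_frequencies(mp), ft)
})

test_that("observed band frequencies converge to 1 - q^2", {
  freq <- matrix(c(0.5, 0.2, 0.9), nrow = 1,
    dimnames = list("A", c("L1", "L2", "L3"))
  )
  cfg <- sim_config(
    n_clusters = 1, pops_per_cluster = 1, n_admixed = 0,
    n_individuals_per_pop = 2000, n_loci = 3, n_selected_loci = 0,
    missing_rate = 0, n_replicate_pairs = 0, seed = 5
  )
  f_obs <- rowMeans(vapply(
    1:5, function(s) colMeans(simulate_band_matrix(freq, cfg, seed = s)$x),
    numeric(3)
  ))
  expect_equal(f_obs, 1 - (1 - freq[1, ])^2, tolerance = 0.02)
})

test_that("null-allele estimators match their definitions", {
  expect_equal(estimate_null_allele_freq(25, 100), 0.5)
  expect_equal(estimate_null_allele_freq(0, 15), 0)
  expect_error(estimate_null_allele_freq(1, 0), "undefined")

  # Bayesian posterior mean vs an independent fine-grid Riemann oracle
  riemann <- function(a, n, grid = 2e5) {
    q <- (seq_len(grid) - 0.5) / grid
    w <- q^(2 * a) * (1 - q^2)^(n - a)
    sum(q * w) / sum(w)
  }
  for (case in list(c(5, 15), c(0, 15), c(15, 15), c(40, 120))) {
    expect_equal(
      estimate_null_allele_freq(case[1], case[2], method = "bayes_uniform"),
      riemann(case[1], case[2]),
      tolerance = 1e-6
    )
  }
  # strictly interior for 0 < absent < n
  q1 <- estimate_null_allele_freq(1, 10, method = "bayes_uniform")
  expect_true(q1 > 0 && q1 < 1)
  # converges to the sqrt estimate as n grows
  n <- 1e5
  expect_equal(
    estimate_null_allele_freq(n / 4, n, method = "bayes_uniform"),
    0.5,
    tolerance = 1e-3
  )
})

test_that("genotyping error rate counts mismatches over shared comparisons", {
  x <- rbind(
    i1 = rep(1L, 229), i2 = rep(0L, 229),
    r1 = rep(1L, 229), r2 = c(1L, rep(0L, 228))
  )
  colnames(x) <- paste0("L", 1:229)
  m <- band_matrix(x, rep("A", 4), replicate_of = c(NA, NA, "i1", "i2"))
  expect_equal(genotyping_error_rate(m), 1 / (2 * 229) * 1)
  m0 <- band_matrix(x[c(1, 3), ], rep("A", 2), replicate_of = c(NA, "i1"))
  expect_equal(genotyping_error_rate(m0), 0)
  expect_error(genotyping_error_rate(tiny_bm()), "no replicate pairs")

  # simulated flips recovered within binomial error: 15 pairs x 229 loci
  cfg <- sim_config(seed = 31, missing_rate = 0)
  bm <- simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg)
  rate <- genotyping_error_rate(bm)
  n_comp <- 15 * 229
  se <- sqrt(0.0078 * (1 - 0.0078) / n_comp)
  expect_lt(abs(rate - 0.0078), 3.5 * se)
})

test_that("SSA inverts the HMC calibration line", {
  expect_equal(ssa_from_hmc(0.488), 0)
  expect_equal(ssa_from_hmc(1.813), 53)
  expect_equal(ssa_from_hmc(2.113), 65)
  expect_warning(out <- ssa_from_hmc(0.4), "clipped")
  expect_equal(out, 0)
})
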