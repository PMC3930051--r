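make_ds <- function(seed = 5, k_axes = 4) {
  sim <- simulate_dataset(sim_config(seed = seed))
  bm <- drop_replicates(sim$band_matrix)
  pops <- sim$freq_sim$populations
  build_distance_set(
    pairwise_phist(bm), sim$site_table, environment_pca(sim$site_table),
    k_axes = k_axes,
    cluster_labels = setNames(
      ifelse(pops$cluster == "ADM", "C2", pops$cluster), pops$population
    ),
    admixed = pops$population[pops$admixed]
  )
}

test_that("correlation-matrix PCA matches an SVD oracle up to sign", {
  sim <- simulate_dataset(sim_config(seed = 2))
  pca <- environment_pca(sim$site_table)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-10)
  # orthogonal axes
  g <- crossprod(pca$loadings)
  expect_equal(g, diag(ncol(pca$loadings)), tolerance = 1e-8, ignore_attr = TRUE)
  # independent oracle: prcomp (SVD) on the standardized variables
  vars <- rownames(pca$loadings)
  pr <- stats::prcomp(sim$site_table[vars], center = TRUE, scale. = TRUE)
  k <- sum(pr$sdev > 1e-8)
  for (a in seq_len(k)) {
    s <- sign(sum(pca$scores[, a] * pr$x[, a]))
    expect_equal(unname(pca$scores[, a]), s * unname(pr$x[, a]), tolerance = 1e-10)
  }
  # sign convention: the largest-magnitude loading on each axis is positive
  for (a in seq_len(ncol(pca$loadings))) {
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, a])), a], 0)
  }
})

test_that("PCA degenerate inputs are handled as specified", {
  df <- tibble::tibble(
    population = c("A", "B", "C"),
    v1 = c(1, 2, 3), v2 = c(2, 4, 6), v3 = c(5, 5, 5)
  )
  expect_error(environment_pca(df, c("v1", "v3")), "constant variable: v3")
  p2 <- environment_pca(df, c("v1", "v2"))
  expect_equal(p2$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(environment_pca(df[1:2, ], c("v1", "v2")), "at least 3 sites")
})

test_that("distance set linearizes, floors and categorizes as specified", {
  phi <- matrix(c(0, 0, 0.5, 0, 0, 0.2, 0.5, 0.2, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  site <- tibble::tibble(
    population = c("A", "B", "C"),
    latitude = c(32, 32, 31.5), longitude = c(35.5, 35.5, 35.6),
    v1 = c(1, 2, 3), v2 = c(3, 1, 2)
  )
  pca <- environment_pca(site, c("v1", "v2"))
  ds <- build_distance_set(phi, site, pca,
    k_axes = 2,
    cluster_labels = c(A = "C1", B = "C1", C = "C2")
  )
  expect_equal(ds$genetic["A", "B"], 0) # Phi = 0 -> 0
  expect_equal(ds$genetic["A", "C"], 1) # Phi = 0.5 -> 1
  # identical coordinates floored at 0.1 km -> ln(0.1)
  expect_equal(ds$geographic["A", "B"], log(0.1))
  expect_equal(
    sort(unique(aflpscape:::unfold_lower_chr(ds$category))),
    c("between", "within")
  )
  # linearization is monotone after clamping
  phis <- c(-0.2, 0, 0.1, 0.5, 0.9)
  lin <- pmin(pmax(phis, 0), 0.999) / (1 - pmin(pmax(phis, 0), 0.999))
  expect_true(all(diff(lin) >= 0))
})

test_that("a nine-population two-cluster design yields the expected pair counts", {
  ds <- make_ds(seed = 5)
  cats <- table(aflpscape:::unfold_lower_chr(ds$category))
  expect_equal(sum(cats), 36) # 9 populations -> 36 pairs
  # 1 admixed population -> 8 admixed-involved pairs
  expect_equal(unname(cats["admixed"]), 8)
  # clusters of 4 and 4: within = 2 * C(4,2) = 12, between = 16
  expect_equal(unname(cats["within"]), 12)
  expect_equal(unname(cats["between"]), 16)
})

test_that("the distance LMM reproduces exact category structure", {
  ds <- make_ds(seed = 6)
  cats <- factor(aflpscape:::unfold_lower_chr(ds$category))
  mu <- c(admixed = 0.3, between = 1.2, within = 0.1)
  y <- mu[as.character(cats)]
  ds$genetic <- aflpscape:::fold_lower(unname(y), ds$populations)
  fit <- fit_distance_lmm(ds, fixed = character(0))
  expect_gt(fit$r_squared, 0.999)
  expect_lt(fit$sigma2, 1e-4)
})

test_that("profiled ML matches a dense GLS oracle and lme4", {
  ds <- make_ds(seed = 7)
  fit <- fit_distance_lmm(ds, fixed = c("geo", "env"))
  # dense-covariance oracle at the fitted parameters
  des <- aflpscape:::lmm_design(ds, c("geo", "env"))
  V <- fit$sigma_u2 * tcrossprod(des$Z) + fit$sigma2 * diag(length(des$y))
  r <- des$y - des$X %*% fit$beta
  ll_oracle <- -0.5 * (length(des$y) * log(2 * pi) +
    determinant(V, logarithm = TRUE)$modulus +
    drop(crossprod(r, solve(V, r))))
  expect_equal(fit$loglik, as.numeric(ll_oracle), tolerance = 1e-6)

  skip_if_not_installed("lme4")
  td <- tidy(ds)
  lf <- lme4::lmer(genetic ~ geographic + environmental + (1 | category),
    data = td, REML = FALSE
  )
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(
    unname(as.numeric(fit$beta)), unname(lme4::fixef(lf)),
    tolerance = 1e-4
  )
})

test_that("adding a fixed effect never decreases the ML log-likelihood", {
  for (s in c(8, 9, 10)) {
    ds <- make_ds(seed = s)
    l0 <- fit_distance_lmm(ds, character(0))$loglik
    l1 <- fit_distance_lmm(ds, "geo")$loglik
    l2 <- fit_distance_lmm(ds, c("geo", "env"))$loglik
    expect_gte(l1, l0 - 1e-8)
    expect_gte(l2, l1 - 1e-8)
  }
})

test_that("the bootstrap LRT is degenerate when full equals reduced", {
  ds <- make_ds(seed = 11)
  bt <- parametric_bootstrap_lrt(ds, "geo", "geo", B = 49, seed = 1)
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p_value, 1)
  expect_error(
    parametric_bootstrap_lrt(ds, "geo", "env", B = 9),
    "subset"
  )
})

test_that("bootstrap p-values are invariant to population relabeling", {
  ds <- make_ds(seed = 12)
  p1 <- parametric_bootstrap_lrt(ds, "env", character(0), B = 99, seed = 3)$p_value
  relab <- setNames(sprintf("Q%02d", seq_along(ds$populations)), ds$populations)
  ds2 <- ds
  for (nm in c("genetic", "geographic", "environmental", "category")) {
    dimnames(ds2[[nm]]) <- list(relab[rownames(ds[[nm]])], relab[colnames(ds[[nm]])])
  }
  ds2$populations <- unname(relab[ds$populations])
  p2 <- parametric_bootstrap_lrt(ds2, "env", character(0), B = 99, seed = 3)$p_value
  expect_identical(p1, p2)
})

test_that("the fixed-effect estimate recovers a planted slope", {
  # y = 0.3 * env + category effects + noise; over replicates the estimate
  # should land within 2 empirical SDs of the truth about 95% of the time
  ds <- make_ds(seed = 13)
  cats <- factor(aflpscape:::unfold_lower_chr(ds$category))
  Z <- stats::model.matrix(~ 0 + cats)
  ev <- aflpscape:::unfold_lower(ds$environmental)
  est <- withr::with_seed(99, {
    vapply(1:100, function(r) {
      y <- 0.3 * ev + drop(Z %*% rnorm(ncol(Z), 0, 0.2)) + rnorm(length(ev), 0, 0.2)
      ds$genetic <- aflpscape:::fold_lower(y, ds$populations)
      fit_distance_lmm(ds, "env")$beta[["env"]]
    }, 0)
  })
  expect_equal(mean(est), 0.3, tolerance = 0.05)
  expect_gte(mean(abs(est - 0.3) < 2 * sd(est)), 0.93)
})
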