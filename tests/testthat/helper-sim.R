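# compact simulation configs and hand-built fixtures shared across tests

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      n_loci = 60, n_individuals_per_pop = 10, missing_rate = 0.01,
      n_replicate_pairs = 4, n_selected_loci = 2, seed = 101
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# a tiny fully-specified band matrix: 2 populations x 3 individuals, 4 loci
tiny_bm <- function() {
  x <- rbind(
    a1 = c(1L, 0L, 1L, 1L),
    a2 = c(1L, 1L, 0L, NA),
    a3 = c(0L, 1L, 1L, 1L),
    b1 = c(0L, 0L, 1L, 0L),
    b2 = c(1L, 0L, 0L, 0L),
    b3 = c(0L, 0L, 1L, 1L)
  )
  colnames(x) <- paste0("L", 1:4)
  band_matrix(x, population = rep(c("A", "B"), each = 3))
}

# band matrix with two clearly separated clusters, for tree/cluster tests
two_cluster_bm <- function(n_loci = 200, f_ct = 0.1, n_ind = 12, seed = 77,
                           pops_per_cluster = 3, admixed = 0) {
  cfg <- sim_config(
    n_clusters = 2, pops_per_cluster = pops_per_cluster, n_admixed = admixed,
    n_individuals_per_pop = n_ind, n_loci = n_loci, f_ct = f_ct, f_sc = 0.02,
    n_selected_loci = 0, missing_rate = 0, n_replicate_pairs = 0, seed = seed
  )
  list(
    bm = simulate_band_matrix(simulate_hierarchical_frequencies(cfg), cfg),
    cfg = cfg
  )
}

# independent ratio-of-sums Weir-Cockerham-type moment estimator, written
# from the definitions as an oracle (loops, no shared code with the package)
oracle_theta <- function(p, n) {
  num <- 0
  den <- 0
  for (l in seq_len(ncol(p))) {
    pj <- p[, l]
    nj <- n[, l]
    keep <- !is.na(pj) & nj > 0
    pj <- pj[keep]
    nj <- nj[keep]
    r <- length(pj)
    if (r < 2) next
    M <- sum(nj)
    pbar <- sum(nj * pj) / M
    msp <- sum(nj * (pj - pbar)^2) / (r - 1)
    msg <- sum(nj * pj * (1 - pj)) / (M - r)
    nc <- (M - sum(nj^2) / M) / (r - 1)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  num / den
}

# random symmetric distance-like matrix with zero diagonal
rand_dist <- function(n, labels = sprintf("P%02d", seq_len(n)), seed = NULL) {
  withr::with_seed(seed %||% sample.int(1e6, 1), {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
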