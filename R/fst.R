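#' Configuration for the candidate-locus scans
#'
#' @param n_sim Number of simulated neutral loci for the envelope scan.
#' @param envelope_quantile Upper quantile of the neutral F_ST given
#'   heterozygosity used to flag candidates, in `(0.5, 1)`.
#' @param theta Scaled diversity of the neutral model; in the Beta-model
#'   island approximation it sets the polymorphism conditioning (the minimum
#'   ancestral minor-allele frequency) of simulated loci.
#' @param iterate_removal Re-estimate the neutral target mean after removing
#'   detected candidates and rescan, up to `max_rounds` rounds.
#' @param max_rounds Maximum envelope-scan rounds.
#' @param mcmc List of Bayesian-scan settings: `chain_length`, `burn_in`,
#'   `thin`, `prior_odds` (prior odds of a locus effect being included,
#'   default 1:10), `chains`.
#' @param sam_alpha Family-wise significance level of the association scan.
#' @return A validated list of class `scan_config`.
#' @export
scan_config <- function(n_sim = 50000, envelope_quantile = 0.99,
                        theta = 0.018, iterate_removal = TRUE, max_rounds = 5,
                        mcmc = list(), sam_alpha = 0.01) {
  if (!(envelope_quantile > 0.5 && envelope_quantile < 1)) {
    abort("envelope_quantile must lie in (0.5, 1)")
  }
  if (theta <= 0) abort("theta must be positive")
  mcmc <- utils::modifyList(
    list(
      chain_length = 10000, burn_in = 2000, thin = 10,
      prior_odds = 0.1, chains = 2
    ),
    mcmc
  )
  structure(
    list(
      n_sim = n_sim, envelope_quantile = envelope_quantile, theta = theta,
      iterate_removal = iterate_removal, max_rounds = max_rounds,
      mcmc = mcmc, sam_alpha = sam_alpha
    ),
    class = "scan_config"
  )
}

#' Drop replicated individuals before analysis
#'
#' Replicate pairs exist for genotyping-error estimation only; analyses of
#' diversity and differentiation should see each individual once.
#'
#' @param m A [band_matrix()].
#' @return The band matrix without rows whose `replicate_of` is set.
#' @export
drop_replicates <- function(m) {
  keep <- is.na(m$replicate_of)
  if (all(keep)) {
    return(m)
  }
  band_matrix(m$x[keep, , drop = FALSE], m$population[keep])
}

# pooled sqrt-estimate polymorphism screen (the "99% level" criterion applied
# to the total sample): p_hat_total strictly inside (0.01, 0.99)
polymorphic_loci <- function(m, level = 0.99) {
  scored <- colSums(!is.na(m$x))
  absent <- colSums(m$x == 0, na.rm = TRUE)
  p_tot <- 1 - sqrt(absent / scored)
  p_tot > 1 - level & p_tot < level
}

# Weir-Cockerham-form moment estimator of F_ST from per-population estimated
# allele frequencies p (pops x loci) and weights m (effective sample sizes);
# for dominant data the per-individual information is about one allele's
# worth, so n_eff (individuals) serves as the allele-count weight
wc_theta <- function(p, m) {
  m[is.na(p)] <- 0
  p0 <- ifelse(is.na(p), 0, p)
  M <- colSums(m)
  r <- colSums(m > 0)
  pbar <- colSums(m * p0) / M
  msp <- colSums(m * sweep(p0, 2, pbar)^2) / (r - 1)
  msg <- colSums(m * p0 * (1 - p0)) / (M - r)
  nc <- (M - colSums(m^2) / M) / (r - 1)
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  list(theta = theta, pbar = pbar, he = 2 * pbar * (1 - pbar))
}

#' Per-locus dominant-marker F_ST
#'
#' Estimates per-population allele frequencies with the Bayesian
#' (uniform-prior) null-allele estimator, then computes a
#' Weir-Cockerham-form variance-partition theta per locus, total-sample
#' heterozygosity `He = 2*p_bar*q_bar` from the pooled mean frequency, and
#' the untrimmed arithmetic mean F_ST across loci. Monomorphic loci (pooled
#' dominant-allele frequency outside the 99% polymorphism criterion) are
#' excluded and counted.
#'
#' @param m A [band_matrix()].
#' @return Tibble of class `locus_fst` with columns `locus`, `fst`, `he`;
#'   attributes `mean_fst` (untrimmed mean), `n_excluded`,
#'   `excluded_loci`.
#' @export
dominant_fst <- function(m) {
  if (length(unique(m$population)) < 2) abort("need at least 2 populations")
  poly <- polymorphic_loci(m)
  excluded <- colnames(m$x)[!poly]
  mp <- band_matrix(
    m$x[, poly, drop = FALSE], m$population,
    replicate_of = m$replicate_of
  )
  bf <- band_freq_mats(mp)
  absent <- round((1 - bf$f) * bf$n)
  q <- matrix(NA_real_, nrow(bf$f), ncol(bf$f), dimnames = dimnames(bf$f))
  ok <- bf$n > 0
  q[ok] <- qhat_bayes_cached(absent[ok], bf$n[ok])
  est <- wc_theta(1 - q, bf$n)
  out <- tibble::tibble(
    locus = bf$loci,
    fst = est$theta,
    he = est$he
  )
  drop_na <- is.na(out$fst)
  if (any(drop_na)) {
    excluded <- c(excluded, out$locus[drop_na])
    out <- out[!drop_na, ]
  }
  attr(out, "mean_fst") <- mean(out$fst)
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_loci") <- excluded
  class(out) <- c("locus_fst", class(out))
  out
}
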