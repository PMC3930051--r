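# fast internal path: per-population band frequencies as matrices
# (populations x loci); f over non-missing entries only
band_freq_mats <- function(m) {
  pops <- sort(unique(m$population))
  g <- factor(m$population, levels = pops)
  pres <- rowsum(ifelse(is.na(m$x), 0L, m$x), g)
  nn <- rowsum((!is.na(m$x)) * 1L, g)
  f <- pres / nn # NaN where a population never scored the locus
  list(f = f, n = nn, populations = pops, loci = colnames(m$x))
}

#' Per-population band frequencies and null-allele estimates
#'
#' Computes, for every population x locus cell, the band frequency `f`
#' (fraction of non-missing individuals showing the band), the number of
#' scored individuals `n_eff`, and the estimated frequency `q_hat` of the
#' recessive null allele under Hardy-Weinberg dominance (absent phenotype
#' frequency = q^2), with `p_hat = 1 - q_hat` the dominant (band) allele.
#'
#' @param m A [band_matrix()].
#' @param q_method Null-allele estimator, `"sqrt"` (the square-root of the
#'   absent fraction; the conventional choice for diversity statistics) or
#'   `"bayes_uniform"` (posterior mean under a uniform prior; see
#'   [estimate_null_allele_freq()]).
#' @return A tibble of class `freq_table` with columns `population`, `locus`,
#'   `f`, `n_eff`, `q_hat`, `p_hat`. Cells where a population has no scored
#'   individuals carry `NA` and are flagged in the `all_missing` column.
#' @export
band_frequencies <- function(m, q_method = c("sqrt", "bayes_uniform")) {
  q_method <- match.arg(q_method)
  bf <- band_freq_mats(m)
  n <- as.vector(bf$n)
  f <- as.vector(bf$f)
  f[n == 0] <- NA_real_
  absent <- round((1 - f) * n)
  q <- rep(NA_real_, length(f))
  ok <- n > 0
  q[ok] <- if (q_method == "sqrt") {
    sqrt(absent[ok] / n[ok])
  } else {
    qhat_bayes_cached(absent[ok], n[ok])
  }
  out <- tibble::tibble(
    population = rep(bf$populations, times = length(bf$loci)),
    locus = rep(bf$loci, each = length(bf$populations)),
    f = f,
    n_eff = as.integer(n),
    q_hat = q,
    p_hat = 1 - q,
    all_missing = n == 0
  )
  attr(out, "q_method") <- q_method
  class(out) <- c("freq_table", class(out))
  out
}

#' Pivot a frequency table to a populations-by-loci matrix
#'
#' @param ft A `freq_table` from [band_frequencies()].
#' @param value Column to spread, e.g. `"f"`, `"p_hat"`, `"q_hat"`, `"n_eff"`.
#' @return Numeric matrix with populations as rows, loci as columns.
#' @export
freq_matrix <- function(ft, value = "f") {
  pops <- unique(ft$population)
  loci <- unique(ft$locus)
  m <- matrix(NA_real_,
    nrow = length(pops), ncol = length(loci),
    dimnames = list(pops, loci)
  )
  m[cbind(match(ft$population, pops), match(ft$locus, loci))] <- ft[[value]]
  m
}

#' Estimate the null (recessive) allele frequency at a dominant locus
#'
#' Under Hardy-Weinberg equilibrium an individual lacks the band only when
#' homozygous for the null allele, so the absent count among `n` scored
#' individuals is Binomial(n, q^2). `"sqrt"` returns the method-of-moments
#' estimate `sqrt(absent/n)`. `"bayes_uniform"` returns the posterior mean of
#' `q` under a Uniform(0,1) prior, evaluated by adaptive numeric quadrature
#' (relative tolerance 1e-8); it is strictly inside (0,1) whenever
#' `0 < absent < n` and converges to the square-root estimate as `n` grows.
#'
#' @param absent Number of individuals without the band (vectorised).
#' @param n Number of scored individuals (vectorised).
#' @param method `"sqrt"` or `"bayes_uniform"`.
#' @return Estimated null-allele frequency, in `[0, 1]`.
#' @examples
#' estimate_null_allele_freq(25, 100) # exactly 0.5
#' estimate_null_allele_freq(5, 15, method = "bayes_uniform")
#' @export
estimate_null_allele_freq <- function(absent, n,
                                      method = c("sqrt", "bayes_uniform")) {
  method <- match.arg(method)
  if (any(n == 0)) abort("n = 0: null-allele frequency undefined")
  if (any(absent < 0 | absent > n)) abort("`absent` must lie in [0, n]")
  if (method == "sqrt") {
    return(sqrt(absent / n))
  }
  qhat_bayes_cached(absent, n)
}

# posterior mean of q with likelihood q^(2a) (1-q^2)^(n-a), uniform prior;
# cached because scans call this for every population x locus cell with a
# handful of distinct (absent, n) pairs
qhat_cache <- new.env(parent = emptyenv())

qhat_bayes_one <- function(a, n) {
  key <- paste0(a, "_", n)
  hit <- qhat_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  # log-scaled integrand for numerical stability at large n
  peak <- sqrt(a / n)
  lf <- function(q) 2 * a * log(q) + (n - a) * log1p(-q^2)
  lmax <- if (a == 0 || a == n) 0 else lf(peak)
  f0 <- function(q) exp(lf(q) - lmax)
  f1 <- function(q) q * exp(lf(q) - lmax)
  den <- stats::integrate(f0, 0, 1, rel.tol = 1e-10, subdivisions = 400L)$value
  num <- stats::integrate(f1, 0, 1, rel.tol = 1e-10, subdivisions = 400L)$value
  val <- num / den
  qhat_cache[[key]] <- val
  val
}

qhat_bayes_cached <- function(absent, n) {
  mapply(qhat_bayes_one, absent, n)
}

#' Genotyping error rate from replicated individuals
#'
#' The mismatch error rate of a dominant-marker assay: the number of
#' phenotype mismatches between each replicated individual and its original,
#' divided by the total number of jointly scored locus comparisons.
#'
#' @param m A [band_matrix()] containing at least one replicate pair
#'   (individuals whose `replicate_of` names another individual).
#' @return Error rate in `[0, 1]`.
#' @export
genotyping_error_rate <- function(m) {
  reps <- which(!is.na(m$replicate_of))
  if (length(reps) == 0) abort("no replicate pairs in this band matrix")
  orig <- match(m$replicate_of[reps], rownames(m$x))
  if (anyNA(orig)) {
    abort(paste0(
      "replicate_of refers to unknown individual: ",
      m$replicate_of[reps][is.na(orig)][1]
    ))
  }
  a <- m$x[reps, , drop = FALSE]
  b <- m$x[orig, , drop = FALSE]
  shared <- !is.na(a) & !is.na(b)
  mism <- sum(a != b, na.rm = TRUE)
  comp <- sum(shared)
  if (comp == 0) abort("replicate pairs share no scored loci")
  mism / comp
}

#' Soil specific surface area from hygroscopic moisture content
#'
#' Inverts the calibration line HMC = 0.025 x SSA + 0.488 relating hygroscopic
#' moisture content (% w/w) to soil specific surface area (m^2/g).
#'
#' @param hmc Hygroscopic moisture content, % w/w.
#' @return SSA in m^2/g; values of `hmc` below the intercept 0.488 are clipped
#'   to SSA = 0 with a warning.
#' @examples
#' ssa_from_hmc(1.813) # 53
#' @export
ssa_from_hmc <- function(hmc) {
  ssa <- (hmc - 0.488) / 0.025
  if (any(ssa < 0, na.rm = TRUE)) {
    warn("HMC below calibration intercept 0.488; SSA clipped to 0")
    ssa[!is.na(ssa) & ssa < 0] <- 0
  }
  ssa
}
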