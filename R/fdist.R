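# simulate one batch of neutral dominant loci under the symmetric Beta-model
# island approximation: ancestral dominant-allele frequency uniform on
# (lo, 1 - lo), population frequencies Balding-Nichols around it with
# differentiation f, dominant phenotypes binomial at the observed sample
# sizes, then the same estimation path as the real data
sim_neutral_batch <- function(f, L, n_j, lo, qtabs) {
  J <- length(n_j)
  p_anc <- runif(L, lo, 1 - lo)
  a <- p_anc * (1 - f) / f
  b <- (1 - p_anc) * (1 - f) / f
  pf <- matrix(rbeta(J * L, rep(a, each = J), rep(b, each = J)), nrow = J)
  band_p <- 1 - (1 - pf)^2
  k <- matrix(
    rbinom(J * L, rep(n_j, times = L), as.vector(band_p)),
    nrow = J
  )
  # polymorphism screen on the pooled sample, as applied to real data
  tot_abs <- colSums(n_j - k)
  p_tot <- 1 - sqrt(tot_abs / sum(n_j))
  keep <- p_tot > 0.01 & p_tot < 0.99
  k <- k[, keep, drop = FALSE]
  # cached Bayesian null-allele estimates, indexed by absent count per pop
  q <- matrix(0, nrow = J, ncol = ncol(k))
  for (j in seq_len(J)) {
    q[j, ] <- qtabs[[j]][n_j[j] - k[j, ] + 1L]
  }
  est <- wc_theta(1 - q, matrix(n_j, nrow = J, ncol = ncol(k)))
  list(fst = est$theta, he = est$he)
}

sim_neutral <- function(f, L, n_j, lo, qtabs) {
  fst <- numeric(0)
  he <- numeric(0)
  while (length(fst) < L) {
    batch <- sim_neutral_batch(f, max(L, 1000), n_j, lo, qtabs)
    fst <- c(fst, batch$fst)
    he <- c(he, batch$he)
  }
  list(fst = fst[seq_len(L)], he = he[seq_len(L)])
}

calibrate_f <- function(target, n_j, lo, qtabs, pilot = 4000, iters = 18) {
  f_lo <- 1e-4
  f_hi <- 0.7
  for (i in seq_len(iters)) {
    f_mid <- (f_lo + f_hi) / 2
    mu <- mean(sim_neutral(f_mid, pilot, n_j, lo, qtabs)$fst)
    if (mu < target) f_lo <- f_mid else f_hi <- f_mid
  }
  (f_lo + f_hi) / 2
}

# bin simulated (he, fst) pairs into roughly `n_bins` equal-width He bins,
# merging thin bins (< min_n simulations) with their neighbour, and take the
# envelope quantile per bin with isotonic (non-decreasing) smoothing
envelope_bins <- function(he, fst, quantile_hi, n_bins = 20, min_n = 1000) {
  br <- seq(min(he), max(he), length.out = n_bins + 1)
  br[1] <- -Inf
  br[length(br)] <- Inf
  bin <- cut(he, br, labels = FALSE)
  repeat {
    cnt <- tabulate(bin, nbins = max(bin))
    small <- which(cnt > 0 & cnt < min_n)
    if (!length(small) || length(unique(bin)) <= 1) break
    s <- small[1]
    neigh <- if (s == max(bin)) s - 1 else s + 1
    bin[bin == s] <- neigh
    bin <- match(bin, sort(unique(bin))) # relabel consecutively
  }
  levs <- sort(unique(bin))
  hi <- vapply(levs, function(b) quantile(fst[bin == b], quantile_hi, names = FALSE), 0)
  lo <- vapply(levs, function(b) quantile(fst[bin == b], 1 - quantile_hi, names = FALSE), 0)
  mid <- vapply(levs, function(b) mean(he[bin == b]), 0)
  n <- vapply(levs, function(b) sum(bin == b), 0)
  ord <- order(mid)
  hi_s <- stats::isoreg(mid[ord], hi[ord])$yf
  bounds <- vapply(levs, function(b) max(he[bin == b]), 0)
  list(
    table = tibble::tibble(
      bin = seq_along(levs), he_mid = mid[ord], he_max = sort(bounds),
      hi = hi_s, lo = lo[ord], n = n[ord]
    ),
    assign = function(h) {
      pmin(findInterval(h, sort(bounds), left.open = TRUE) + 1L, length(levs))
    },
    bin_of_sim = bin
  )
}

#' FST-outlier scan against a simulated neutral envelope
#'
#' Compares each locus's F_ST with the neutral expectation at its
#' heterozygosity. Neutral loci are simulated under a symmetric Beta-model
#' island approximation whose differentiation parameter is calibrated by
#' bisection so the simulated mean F_ST matches the observed untrimmed mean;
#' simulated loci pass through the identical estimation path (sampling at
#' the observed sizes, Bayesian null-allele estimation, the polymorphism
#' screen). The conditional upper `envelope_quantile` of F_ST given He -
#' computed in merged He bins and isotonically smoothed - defines the
#' candidate envelope; the per-locus p is the neutral tail mass (fraction of
#' simulations in the locus's He bin with F_ST at or above the observed
#' value). When `iterate_removal` is set, detected candidates are removed,
#' the target mean recomputed, and the scan repeated until no new candidate
#' appears (at most `max_rounds` rounds). Only upper-tail (divergent)
#' candidates are flagged; the lower envelope is reported for information.
#'
#' @param m A [band_matrix()].
#' @param cfg A [scan_config()].
#' @param seed Seed.
#' @return Tibble of class `fdist_scan`: `locus`, `fst`, `he`, `p`,
#'   `candidate`, `below_lower`, `round_detected`; attributes `envelope`
#'   (bin table), `f_calibrated`, `target_history`, `n_sim`, `mean_fst`.
#' @export
fdist_scan <- function(m, cfg = scan_config(), seed = NULL) {
  obs <- dominant_fst(m)
  n_j <- as.integer(table(m$population))
  lo_bound <- max(0.01, cfg$theta)
  qtabs <- lapply(n_j, function(n) {
    vapply(0:n, function(a) qhat_bayes_one(a, n), 0)
  })
  candidate <- rep(FALSE, nrow(obs))
  round_detected <- rep(NA_integer_, nrow(obs))
  target_history <- numeric(0)
  env <- NULL
  f_cal <- NA_real_
  p <- rep(NA_real_, nrow(obs))
  withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    for (round in seq_len(if (cfg$iterate_removal) cfg$max_rounds else 1L)) {
      target <- mean(obs$fst[!candidate])
      target_history <- c(target_history, target)
      f_cal <- calibrate_f(target, n_j, lo_bound, qtabs)
      sim <- sim_neutral(f_cal, cfg$n_sim, n_j, lo_bound, qtabs)
      env <- envelope_bins(sim$he, sim$fst, cfg$envelope_quantile)
      obs_bin <- env$assign(obs$he)
      p <- vapply(seq_len(nrow(obs)), function(i) {
        in_bin <- sim$fst[env$bin_of_sim == obs_bin[i]]
        mean(in_bin >= obs$fst[i])
      }, 0)
      hi_at <- env$table$hi[obs_bin]
      new_cand <- !candidate & obs$fst > hi_at
      if (!any(new_cand)) break
      round_detected[new_cand] <- round
      candidate <- candidate | new_cand
      if (!cfg$iterate_removal) break
    }
  })
  lo_at <- env$table$lo[env$assign(obs$he)]
  out <- tibble::tibble(
    locus = obs$locus, fst = obs$fst, he = obs$he, p = p,
    candidate = candidate, below_lower = obs$fst < lo_at,
    round_detected = round_detected
  )
  attr(out, "envelope") <- env$table
  attr(out, "f_calibrated") <- f_cal
  attr(out, "target_history") <- target_history
  attr(out, "n_sim") <- cfg$n_sim
  attr(out, "mean_fst") <- attr(obs, "mean_fst")
  attr(out, "n_excluded") <- attr(obs, "n_excluded")
  class(out) <- c("fdist_scan", class(out))
  out
}

#' Plot an FST-outlier scan
#'
#' Observed per-locus (He, F_ST) points over the simulated neutral envelope.
#'
#' @param object An `fdist_scan`.
#' @param ... Unused.
#' @export
autoplot.fdist_scan <- function(object, ...) {
  env <- attr(object, "envelope")
  ggplot2::ggplot(object, ggplot2::aes(.data$he, .data$fst)) +
    ggplot2::geom_step(
      data = env, ggplot2::aes(.data$he_mid, .data$hi),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_step(
      data = env, ggplot2::aes(.data$he_mid, .data$lo),
      linetype = 3, colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "He", y = expression(F[ST]), colour = "candidate") +
    ggplot2::theme_minimal()
}
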