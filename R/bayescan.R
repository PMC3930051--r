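# --- Bayesian decomposition of locus-population differentiation ---
# model: logit(F_ij) = alpha_i * delta_i + beta_j; population allele
# frequency p_ij ~ Beta(theta_ij * p_i, theta_ij * (1 - p_i)) with
# theta_ij = (1 - F_ij)/F_ij; absent counts a_ij ~ Binomial(n_j, (1-p_ij)^2).
# Reversible jump toggles each locus effect delta_i; the posterior inclusion
# probability feeds q-values.

bs_lbeta <- function(P, F_ij, p_anc) {
  th <- (1 - F_ij) / F_ij
  stats::dbeta(P, th * p_anc, th * (1 - p_anc), log = TRUE)
}

bs_lbin <- function(P, a, n) {
  q2 <- (1 - P)^2
  a * log(q2) + (n - a) * log1p(-q2)
}

clamp01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

bayescan_chain <- function(a, nmat, cfg, seed) {
  L <- nrow(a)
  J <- ncol(a)
  it <- cfg$mcmc$chain_length
  burn <- cfg$mcmc$burn_in
  thin <- cfg$mcmc$thin
  pi_incl <- cfg$mcmc$prior_odds / (1 + cfg$mcmc$prior_odds)
  withr::with_seed(seed, {
    # initial state from the data
    f_obs <- 1 - a / nmat # band frequency
    P <- clamp01(1 - sqrt(clamp01(a / nmat))) # allele freq of band allele
    p_anc <- clamp01(rowMeans(P))
    alpha <- rep(0, L)
    delta <- rep(FALSE, L)
    beta <- rep(-1, J)
    s_p <- 0.5
    s_anc <- 0.3
    s_alpha <- 0.5
    s_beta <- 0.3
    pam <- matrix(p_anc, L, J)
    Fm <- clamp01(stats::plogis(outer(alpha * delta, beta, `+`)), 1e-6)
    ll_cell <- bs_lbeta(P, Fm, pam) + bs_lbin(P, a, nmat)
    keep <- seq(burn + thin, it, by = thin)
    pip_acc <- numeric(L)
    alpha_acc <- numeric(L)
    beta_draws <- matrix(0, length(keep), J)
    kept <- 0L
    acc <- c(p = 0, anc = 0, alpha = 0, beta = 0)
    prop <- c(p = 0, anc = 0, alpha = 0, beta = 0)
    for (t in seq_len(it)) {
      # 1. latent population frequencies, logit random walk, all cells at once
      lp <- stats::qlogis(P) + rnorm(L * J, 0, s_p)
      Pn <- clamp01(stats::plogis(lp))
      ll_new <- bs_lbeta(Pn, Fm, pam) + bs_lbin(Pn, a, nmat)
      lr <- ll_new - ll_cell + log(Pn * (1 - Pn)) - log(P * (1 - P))
      accept <- log(runif(L * J)) < lr
      P[accept] <- Pn[accept]
      ll_cell[accept] <- ll_new[accept]
      acc["p"] <- acc["p"] + mean(accept)
      prop["p"] <- prop["p"] + 1
      # 2. ancestral frequencies, per locus
      pa_new <- clamp01(stats::plogis(stats::qlogis(p_anc) + rnorm(L, 0, s_anc)))
      lb_old <- rowSums(bs_lbeta(P, Fm, pam))
      pam_new <- matrix(pa_new, L, J)
      lb_new <- rowSums(bs_lbeta(P, Fm, pam_new))
      lr <- lb_new - lb_old +
        log(pa_new * (1 - pa_new)) - log(p_anc * (1 - p_anc))
      accept <- log(runif(L)) < lr
      p_anc[accept] <- pa_new[accept]
      pam[accept, ] <- pam_new[accept, ]
      acc["anc"] <- acc["anc"] + mean(accept)
      prop["anc"] <- prop["anc"] + 1
      # 3. locus effects (only where included)
      inc <- which(delta)
      if (length(inc)) {
        an <- alpha
        an[inc] <- alpha[inc] + rnorm(length(inc), 0, s_alpha)
        Fn <- clamp01(stats::plogis(outer(an * delta, beta, `+`)), 1e-6)
        lb_old <- rowSums(bs_lbeta(P, Fm, pam))
        lb_new <- rowSums(bs_lbeta(P, Fn, pam))
        lr <- (lb_new - lb_old +
          stats::dnorm(an, 0, 1, log = TRUE) -
          stats::dnorm(alpha, 0, 1, log = TRUE))[inc]
        accept <- inc[log(runif(length(inc))) < lr]
        alpha[accept] <- an[accept]
        Fm <- clamp01(stats::plogis(outer(alpha * delta, beta, `+`)), 1e-6)
        acc["alpha"] <- acc["alpha"] + length(accept) / length(inc)
        prop["alpha"] <- prop["alpha"] + 1
      }
      # 4. population effects, one at a time
      for (j in seq_len(J)) {
        bn <- beta[j] + rnorm(1, 0, s_beta)
        Fj <- clamp01(stats::plogis(alpha * delta + bn), 1e-6)
        lb_old <- sum(bs_lbeta(P[, j], Fm[, j], p_anc))
        lb_new <- sum(bs_lbeta(P[, j], Fj, p_anc))
        lr <- lb_new - lb_old +
          stats::dnorm(bn, -1, 1, log = TRUE) -
          stats::dnorm(beta[j], -1, 1, log = TRUE)
        if (log(runif(1)) < lr) {
          beta[j] <- bn
          Fm[, j] <- Fj
          acc["beta"] <- acc["beta"] + 1 / J
        }
      }
      prop["beta"] <- prop["beta"] + 1
      # 5. reversible-jump toggle of each locus effect; proposing alpha from
      # its N(0,1) prior cancels the prior/proposal ratio
      alpha_star <- ifelse(delta, 0, rnorm(L, 0, 1))
      a_on <- ifelse(delta, alpha, alpha_star)
      F_on <- clamp01(stats::plogis(outer(a_on, beta, `+`)), 1e-6)
      F_off <- clamp01(stats::plogis(outer(rep(0, L), beta, `+`)), 1e-6)
      ll_on <- rowSums(bs_lbeta(P, F_on, pam))
      ll_off <- rowSums(bs_lbeta(P, F_off, pam))
      lr <- ifelse(delta,
        ll_off - ll_on + log((1 - pi_incl) / pi_incl),
        ll_on - ll_off + log(pi_incl / (1 - pi_incl))
      )
      flip <- log(runif(L)) < lr
      delta[flip] <- !delta[flip]
      alpha[flip] <- ifelse(delta[flip], alpha_star[flip], 0)
      Fm <- clamp01(stats::plogis(outer(alpha * delta, beta, `+`)), 1e-6)
      ll_cell <- bs_lbeta(P, Fm, pam) + bs_lbin(P, a, nmat)
      # pilot adaptation of random-walk scales during burn-in
      if (t <= burn && t %% 100 == 0) {
        tune <- function(s, rate) s * exp(2 * (rate - 0.3))
        s_p <- tune(s_p, acc["p"] / prop["p"])
        s_anc <- tune(s_anc, acc["anc"] / prop["anc"])
        if (prop["alpha"] > 0) s_alpha <- tune(s_alpha, acc["alpha"] / prop["alpha"])
        s_beta <- tune(s_beta, acc["beta"] / prop["beta"])
        acc[] <- 0
        prop[] <- 0
      }
      if (t > burn && (t - burn) %% thin == 0) {
        kept <- kept + 1L
        pip_acc <- pip_acc + delta
        alpha_acc <- alpha_acc + alpha * delta
        beta_draws[kept, ] <- beta
      }
    }
  })
  list(
    pip = pip_acc / kept, alpha_mean = alpha_acc / kept,
    beta_draws = beta_draws[seq_len(kept), , drop = FALSE]
  )
}

split_rhat <- function(chains_mat) {
  # chains_mat: list of draws matrices (iterations x params); split each in 2
  halves <- list()
  for (ch in chains_mat) {
    m <- nrow(ch) %/% 2
    if (m < 2) next
    halves <- c(halves, list(ch[1:m, , drop = FALSE], ch[(m + 1):(2 * m), , drop = FALSE]))
  }
  if (length(halves) < 2) {
    return(NA_real_)
  }
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, var))
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  max(sqrt(((n - 1) / n * W + B / n) / W), na.rm = TRUE)
}

#' Bayesian locus-effect scan with q-values
#'
#' Decomposes locus-by-population differentiation into population-specific
#' effects (shared by all loci) and optional locus-specific effects, the
#' latter switched on and off by reversible-jump MCMC with configurable
#' prior inclusion odds (default 1:10). A locus whose effect is needed to
#' explain its differentiation accumulates posterior inclusion probability
#' (PIP); the q-value of a locus is the expected false-positive proportion
#' if every locus at least as included were called: the mean of `1 - PIP`
#' over loci with PIP at or above its own. Candidates satisfy `q <= 0.05`.
#' Monomorphic loci are excluded as in [dominant_fst()]. With more than one
#' chain, a split-R-hat diagnostic on the population effects above 1.2
#' attaches a mixing warning.
#'
#' @param m A [band_matrix()].
#' @param cfg A [scan_config()]; see its `mcmc` element.
#' @param seed Seed.
#' @param q_threshold Candidate threshold on the q-value.
#' @return Tibble of class `bayescan_scan`: `locus`, `fst`, `he`,
#'   `alpha_mean`, `pip`, `qvalue`, `candidate`; attributes `rhat`,
#'   `mixing_warning`, `chains`.
#' @export
bayescan_scan <- function(m, cfg = scan_config(), seed = NULL,
                          q_threshold = 0.05) {
  obs <- dominant_fst(m) # also defines the polymorphic locus set
  poly <- obs$locus
  keep <- colnames(m$x) %in% poly
  x <- m$x[, keep, drop = FALSE]
  pops <- sort(unique(m$population))
  g <- factor(m$population, levels = pops)
  pres <- rowsum(ifelse(is.na(x), 0L, x), g)
  nn <- rowsum((!is.na(x)) * 1L, g)
  a <- t(nn - pres) # absent counts, loci x pops
  n <- t(nn) # per-cell scored counts
  n[n == 0] <- 1L # empty cells carry no likelihood (a = 0 there too)
  seed <- seed %||% sample.int(2^31 - 1, 1)
  chains <- lapply(seq_len(cfg$mcmc$chains), function(ch) {
    bayescan_chain(a, n, cfg, sub_seed(seed, ch))
  })
  pip <- rowMeans(sapply(chains, `[[`, "pip"))
  alpha_mean <- rowMeans(sapply(chains, `[[`, "alpha_mean"))
  rhat <- split_rhat(lapply(chains, `[[`, "beta_draws"))
  ord <- order(pip, decreasing = TRUE)
  qv <- numeric(length(pip))
  qv[ord] <- cumsum(1 - pip[ord]) / seq_along(ord)
  # ties in PIP share the largest q of their tie group
  for (u in unique(pip)) qv[pip == u] <- max(qv[pip == u])
  out <- tibble::tibble(
    locus = obs$locus, fst = obs$fst, he = obs$he,
    alpha_mean = alpha_mean, pip = pip, qvalue = qv,
    candidate = qv <= q_threshold
  )
  mixing <- !is.na(rhat) && rhat > 1.2
  if (mixing) {
    warn(sprintf("population-effect split-R-hat %.3f > 1.2: chains may not have mixed", rhat))
  }
  attr(out, "rhat") <- rhat
  attr(out, "mixing_warning") <- mixing
  attr(out, "chains") <- cfg$mcmc$chains
  attr(out, "seed") <- seed
  class(out) <- c("bayescan_scan", class(out))
  out
}

#' @export
autoplot.bayescan_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(log10(pmax(.data$qvalue, 1e-4)), .data$fst)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate)) +
    ggplot2::geom_vline(xintercept = log10(0.05), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "log10 q-value", y = expression(F[ST]), colour = "candidate") +
    ggplot2::theme_minimal()
}
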