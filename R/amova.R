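# squared inter-individual distance for dominant band profiles: number of
# differing loci over jointly scored loci, rescaled by L / shared so profiles
# with missing data stay comparable (unbiased under missing-at-random)
individual_dist2 <- function(m) {
  M <- (!is.na(m$x)) * 1
  A <- ifelse(is.na(m$x), 0, m$x)
  shared <- M %*% t(M)
  am <- A %*% t(M)
  diff <- am + t(am) - 2 * (A %*% t(A))
  if (any(shared[lower.tri(shared)] == 0)) {
    abort("some individual pairs share no scored loci")
  }
  d2 <- diff / shared * ncol(m$x)
  diag(d2) <- 0
  d2
}

ss_within_sets <- function(D2, f) {
  out <- 0
  for (lev in unique(f)) {
    idx <- which(f == lev)
    out <- out + sum(D2[idx, idx]) / 2 / length(idx)
  }
  out
}

# variance components for the two AMOVA designs, from a fixed distance matrix
# and (permutable) stratum labels
amova_components <- function(D2, pop, pop_group = NULL) {
  N <- nrow(D2)
  ss_total <- sum(D2[lower.tri(D2)]) / N
  ss_wp <- ss_within_sets(D2, pop)
  n_p <- table(pop)
  P <- length(n_p)
  if (is.null(pop_group)) {
    df_ap <- P - 1
    df_wp <- N - P
    ss_ap <- ss_total - ss_wp
    ms_ap <- ss_ap / df_ap
    ms_wp <- if (df_wp > 0) ss_wp / df_wp else 0
    n_prime <- (N - sum(n_p^2) / N) / df_ap
    sig_w <- ms_wp
    sig_a <- (ms_ap - ms_wp) / n_prime
    tot <- sig_a + sig_w
    list(
      design = "two-level",
      stratum = c("among_populations", "within_populations"),
      df = c(df_ap, df_wp), ss = c(ss_ap, ss_wp), ms = c(ms_ap, ms_wp),
      sigma2 = c(sig_a, sig_w),
      phi = c(phi_st = if (tot > 0) sig_a / tot else 0)
    )
  } else {
    grp <- pop_group[pop] # individual-level group labels
    ss_wg <- ss_within_sets(D2, grp) # within groups (pops pooled)
    ss_ag <- ss_total - ss_wg
    ss_ap_wg <- ss_wg - ss_wp
    G <- length(unique(pop_group))
    df_ag <- G - 1
    df_ap <- P - G
    df_wp <- N - P
    ms_ag <- ss_ag / df_ag
    ms_ap <- ss_ap_wg / df_ap
    ms_wp <- if (df_wp > 0) ss_wp / df_wp else 0
    N_g <- tapply(as.vector(n_p[names(pop_group)]), pop_group, sum)
    sum_npg <- tapply(as.vector(n_p[names(pop_group)])^2, pop_group, sum)
    n1 <- (N - sum(sum_npg / N_g)) / df_ap
    n2 <- (sum(sum_npg / N_g) - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(N_g^2) / N) / df_ag
    sig_c <- ms_wp
    sig_b <- (ms_ap - ms_wp) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(
      design = "three-level",
      stratum = c(
        "among_groups", "among_populations_within_groups",
        "within_populations"
      ),
      df = c(df_ag, df_ap, df_wp),
      ss = c(ss_ag, ss_ap_wg, ss_wp),
      ms = c(ms_ag, ms_ap, ms_wp),
      sigma2 = c(sig_a, sig_b, sig_c),
      phi = c(
        phi_ct = if (tot > 0) sig_a / tot else 0,
        phi_sc = if ((sig_b + sig_c) > 0) sig_b / (sig_b + sig_c) else 0,
        phi_st = if (tot > 0) (sig_a + sig_b) / tot else 0
      )
    )
  }
}

#' Analysis of molecular variance on dominant band profiles
#'
#' Partitions squared inter-individual distances (differing loci over jointly
#' scored loci, rescaled to the full locus count) among strata. Without
#' `groups`, the design is two-level (among / within populations, Phi_ST);
#' with `groups` (a named vector mapping population to cluster), three-level
#' (among groups Phi_CT, among populations within groups Phi_SC, within
#' populations; Phi_ST combines the first two). Variance components equate
#' observed mean squares to their expectations with unequal-sample-size
#' coefficients. Significance uses the matching permutation scheme per
#' statistic: individuals among populations (Phi_ST), whole populations among
#' groups (Phi_CT), individuals among populations within groups (Phi_SC);
#' `p = (1 + #(perm >= obs)) / (n_perm + 1)`.
#'
#' @param m A [band_matrix()].
#' @param groups Optional named character vector, population -> group label.
#' @param n_perm Number of permutations (0 skips inference).
#' @param seed Seed for the permutations.
#' @return A list of class `amova_result`: `design`, `table` (tibble with df,
#'   SS, MS, variance components and percentages), `phi`, `p_values`,
#'   `n_perm`.
#' @export
amova <- function(m, groups = NULL, n_perm = 999, seed = NULL) {
  pops <- unique(m$population)
  if (length(pops) < 2) abort("need at least 2 populations")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || !all(pops %in% names(groups))) {
      abort("`groups` must be a named vector covering every population")
    }
    groups <- groups[pops]
    singleton <- names(table(groups))[table(groups) == 1]
    if (length(singleton)) {
      warn(paste0(
        "groups with a single population (phi_sc weakly informed): ",
        paste(singleton, collapse = ", ")
      ))
    }
  }
  D2 <- individual_dist2(m)
  obs <- amova_components(D2, m$population, groups)
  p_values <- setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  if (n_perm > 0) {
    exceed <- setNames(numeric(length(obs$phi)), names(obs$phi))
    withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
      for (b in seq_len(n_perm)) {
        # Phi_ST: individuals among populations (ignoring groups)
        perm_pop <- sample(m$population)
        if (is.null(groups)) {
          st <- amova_components(D2, perm_pop)$phi["phi_st"]
          exceed["phi_st"] <- exceed["phi_st"] + (st >= obs$phi["phi_st"])
        } else {
          st <- amova_components(D2, perm_pop, groups)$phi["phi_st"]
          exceed["phi_st"] <- exceed["phi_st"] + (st >= obs$phi["phi_st"])
          # Phi_CT: whole populations among groups
          pg <- setNames(sample(groups), names(groups))
          ct <- amova_components(D2, m$population, pg)$phi["phi_ct"]
          exceed["phi_ct"] <- exceed["phi_ct"] + (ct >= obs$phi["phi_ct"])
          # Phi_SC: individuals among populations within groups
          pop_sc <- m$population
          ind_grp <- groups[m$population]
          for (g in unique(groups)) {
            idx <- which(ind_grp == g)
            pop_sc[idx] <- sample(pop_sc[idx])
          }
          sc <- amova_components(D2, pop_sc, groups)$phi["phi_sc"]
          exceed["phi_sc"] <- exceed["phi_sc"] + (sc >= obs$phi["phi_sc"])
        }
      }
    })
    p_values <- (1 + exceed) / (n_perm + 1)
  }
  tot <- sum(obs$sigma2)
  structure(
    list(
      design = obs$design,
      table = tibble::tibble(
        stratum = obs$stratum, df = obs$df, SS = obs$ss, MS = obs$ms,
        sigma2 = obs$sigma2,
        percent = if (tot > 0) 100 * obs$sigma2 / tot else rep(NA_real_, length(obs$sigma2))
      ),
      phi = obs$phi,
      p_values = p_values,
      n_perm = n_perm
    ),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>", x$design, "design\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat("Phi: ", paste(sprintf("%s = %.4f", names(x$phi), x$phi), collapse = ", "), "\n")
  if (!all(is.na(x$p_values))) {
    cat("p:   ", paste(
      sprintf("%s = %.4g", names(x$p_values), x$p_values),
      collapse = ", "
    ), sprintf(" (%d permutations)\n", x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) {
  x$table
}

#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    !!!as.list(x$phi),
    !!!setNames(as.list(x$p_values), paste0("p_", names(x$p_values))),
    n_perm = x$n_perm
  )
}

#' Pairwise Phi_ST between populations
#'
#' Two-population AMOVA applied to every pair; negative estimates are kept
#' as-is (clamping, if needed, happens downstream at linearization).
#'
#' @param m A [band_matrix()].
#' @return Symmetric populations-by-populations Phi_ST matrix.
#' @export
pairwise_phist <- function(m) {
  pops <- sort(unique(m$population))
  if (length(pops) < 2) abort("need at least 2 populations")
  D2 <- individual_dist2(m)
  P <- length(pops)
  out <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      idx <- which(m$population %in% pops[c(i, j)])
      comp <- amova_components(D2[idx, idx], m$population[idx])
      # raw component ratio, unclamped (can be negative)
      tot <- sum(comp$sigma2)
      out[i, j] <- out[j, i] <- if (tot != 0) comp$sigma2[1] / tot else 0
    }
  }
  out
}
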