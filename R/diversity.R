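#' Percentage of polymorphic loci per population
#'
#' A locus counts as polymorphic in a population when its estimated
#' dominant-allele frequency `p_hat` lies strictly inside
#' `(1 - level, level)`; the default `level = 0.99` is the conventional
#' "99% criterion".
#'
#' @param ft A `freq_table` from [band_frequencies()].
#' @param level Polymorphism criterion in `(0.5, 1]`.
#' @return Tibble with columns `population`, `n_loci` (scored loci),
#'   `n_polymorphic`, `percent_polymorphic`.
#' @export
percent_polymorphic <- function(ft, level = 0.99) {
  ft |>
    dplyr::filter(!.data$all_missing) |>
    dplyr::group_by(population = .data$population) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      n_polymorphic = sum(.data$p_hat > 1 - level & .data$p_hat < level),
      percent_polymorphic = 100 * .data$n_polymorphic / .data$n_loci,
      .groups = "drop"
    )
}

#' Unbiased expected heterozygosity per population
#'
#' Per locus, expected heterozygosity under Hardy-Weinberg dominance is
#' `He = 2 * p_hat * q_hat`; the small-sample (unbiased) version multiplies by
#' `2n / (2n - 1)` with `n` the number of scored individuals. The population
#' value is the mean over loci; loci scored in at most one individual are
#' skipped with a warning.
#'
#' @param ft A `freq_table` computed with the `"sqrt"` estimator.
#' @return Tibble with columns `population`, `n_loci`, `uHe`.
#' @export
unbiased_heterozygosity <- function(ft) {
  skip <- !ft$all_missing & ft$n_eff <= 1
  if (any(skip)) {
    warn(sprintf("%d population x locus cells with n <= 1 skipped", sum(skip)))
  }
  ft |>
    dplyr::filter(!.data$all_missing, .data$n_eff > 1) |>
    dplyr::mutate(
      uhe = 2 * .data$p_hat * .data$q_hat * 2 * .data$n_eff / (2 * .data$n_eff - 1)
    ) |>
    dplyr::group_by(population = .data$population) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      uHe = mean(.data$uhe),
      .groups = "drop"
    )
}

#' Nei's standard genetic distance between populations
#'
#' Treats each dominant locus as biallelic with estimated frequencies
#' `(p, q)` per population and accumulates over jointly scored loci:
#' `Jxy = sum(px*py + qx*qy)`, `Jx = sum(px^2 + qx^2)` (likewise `Jy`),
#' `D = -ln(Jxy / sqrt(Jx * Jy))`.
#'
#' @param ft A `freq_table`.
#' @param max_distance Cap substituted when a pair shares no allele at some
#'   locus set (`Jxy = 0` would give infinite distance).
#' @return Symmetric populations-by-populations matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(ft, max_distance = 30) {
  p <- freq_matrix(ft, "p_hat")
  q <- 1 - p
  pops <- rownames(p)
  P <- length(pops)
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      ok <- !is.na(p[i, ]) & !is.na(p[j, ])
      if (!any(ok)) {
        abort(sprintf(
          "populations %s and %s share no scored loci", pops[i], pops[j]
        ))
      }
      jxy <- sum(p[i, ok] * p[j, ok] + q[i, ok] * q[j, ok])
      jx <- sum(p[i, ok]^2 + q[i, ok]^2)
      jy <- sum(p[j, ok]^2 + q[j, ok]^2)
      d <- if (jxy <= 0) max_distance else -log(jxy / sqrt(jx * jy))
      D[i, j] <- D[j, i] <- min(max(d, 0), max_distance)
    }
  }
  D
}

upgma_tree <- function(D) {
  # lexicographic population order makes tied merge heights deterministic
  ord <- order(rownames(D))
  hc <- stats::hclust(stats::as.dist(D[ord, ord]), method = "average")
  ape::as.phylo(hc)
}

#' UPGMA tree on Nei distances with locus bootstrap support
#'
#' Builds the UPGMA dendrogram of populations from Nei distances, then
#' resamples loci with replacement `B` times, recomputes distances and trees,
#' and reports for each internal bipartition of the original tree the
#' percentage of replicates containing it. Tied merge heights are broken by
#' lexicographic population order.
#'
#' @param m A [band_matrix()].
#' @param B Number of bootstrap replicates.
#' @param seed Seed.
#' @return A list of class `tree_result`: `tree` (an `ape::phylo` with node
#'   labels holding supports), `support` (per internal node, percent),
#'   `newick` (serialized form), `B`.
#' @export
upgma_with_bootstrap <- function(m, B = 1000, seed = NULL) {
  if (length(unique(m$population)) < 3) abort("need at least 3 populations")
  ft <- band_frequencies(m)
  tree <- upgma_tree(nei_distance_matrix(ft))
  L <- ncol(m$x)
  boot <- withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      mb <- band_matrix(
        m$x[, idx, drop = FALSE] |>
          (\(z) {
            colnames(z) <- paste0("b", seq_len(ncol(z)))
            z
          })(),
        population = m$population, replicate_of = m$replicate_of
      )
      upgma_tree(nei_distance_matrix(band_frequencies(mb)))
    })
  })
  cnt <- ape::prop.clades(tree, boot, rooted = TRUE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / B
  tree$node.label <- formatC(support, format = "f", digits = 1)
  structure(
    list(
      tree = tree, support = support,
      newick = ape::write.tree(tree), B = B
    ),
    class = "tree_result"
  )
}

#' @export
print.tree_result <- function(x, ...) {
  cat("<tree_result> UPGMA,", x$B, "bootstrap replicates\n")
  cat(x$newick, "\n")
  invisible(x)
}
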