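#' Assemble the explanatory and response distance matrices
#'
#' Builds the standard isolation-by-distance / isolation-by-adaptation
#' regression inputs over one common population ordering:
#' * genetic: linearized `Phi / (1 - Phi)` with Phi clamped to
#'   `[0, 0.999]` first (negative estimates are sampling noise);
#' * geographic: `ln` of great-circle distance in km, floored at 0.1 km so
#'   co-located sites stay finite;
#' * environmental: Euclidean distance over the first `k_axes` PCA scores;
#' * category: pair classes used as the mixed-model grouping variable -
#'   `"within"` (same cluster), `"between"` (different clusters), `"admixed"`
#'   (any pair involving an admixed population).
#'
#' @param phist Square Phi_ST matrix from [pairwise_phist()].
#' @param site_table Site table with `population`, `latitude`, `longitude`.
#' @param pca An [environment_pca()] result.
#' @param k_axes Number of PCA axes for the environmental distance.
#' @param cluster_labels Named vector population -> cluster.
#' @param admixed Character vector of admixed population names.
#' @param split_admixed If `TRUE`, admixed pairs are split by the cluster of
#'   the partner population (finer 5-level coding).
#' @return A list of class `distance_set`: matrices `genetic`, `geographic`,
#'   `environmental`, `category` (character), plus `populations`.
#' @export
build_distance_set <- function(phist, site_table, pca, k_axes = 4,
                               cluster_labels, admixed = character(0),
                               split_admixed = FALSE) {
  check_square(phist)
  pops <- rownames(phist)
  if (!all(pops %in% site_table$population)) {
    abort("site_table is missing populations present in the Phi matrix")
  }
  if (!all(pops %in% names(cluster_labels))) {
    abort("cluster_labels must cover every population")
  }
  if (!all(pops %in% rownames(pca$scores))) {
    abort("pca scores missing populations")
  }
  st <- site_table[match(pops, site_table$population), ]
  phi <- pmin(pmax(phist, 0), 0.999)
  genetic <- phi / (1 - phi)
  km <- geosphere::distm(
    cbind(st$longitude, st$latitude),
    fun = geosphere::distHaversine
  ) / 1000
  geographic <- log(pmax(km, 0.1))
  diag(geographic) <- 0
  k <- min(k_axes, ncol(pca$scores))
  sc <- pca$scores[pops, seq_len(k), drop = FALSE]
  environmental <- as.matrix(stats::dist(sc))
  cl <- cluster_labels[pops]
  P <- length(pops)
  category <- matrix(NA_character_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i == j) next
      adm <- pops[i] %in% admixed || pops[j] %in% admixed
      category[i, j] <- if (adm) {
        if (split_admixed) {
          other <- if (pops[i] %in% admixed) cl[j] else cl[i]
          paste0("admixed_", other)
        } else {
          "admixed"
        }
      } else if (cl[i] == cl[j]) "within" else "between"
    }
  }
  dimnames(genetic) <- dimnames(environmental) <- dimnames(phist)
  dimnames(geographic) <- dimnames(phist)
  structure(
    list(
      genetic = genetic, geographic = geographic,
      environmental = environmental, category = category,
      populations = pops
    ),
    class = "distance_set"
  )
}

#' @export
print.distance_set <- function(x, ...) {
  cats <- table(unfold_lower_chr(x$category))
  cat(
    "<distance_set>", length(x$populations), "populations,",
    sum(cats), "pairs (",
    paste(sprintf("%s: %d", names(cats), cats), collapse = ", "), ")\n"
  )
  invisible(x)
}

unfold_lower_chr <- function(m) m[lower.tri(m)]

#' Unfold a distance set into a pairwise tibble
#'
#' @param x A `distance_set`.
#' @param ... Unused.
#' @return Tibble with one row per unordered population pair.
#' @export
tidy.distance_set <- function(x, ...) {
  dplyr::bind_cols(
    pair_index(x$populations)[, c("pop1", "pop2")],
    tibble::tibble(
      genetic = unfold_lower(x$genetic),
      geographic = unfold_lower(x$geographic),
      environmental = unfold_lower(x$environmental),
      category = unfold_lower_chr(x$category)
    )
  )
}

#' Binary cluster dissimilarity matrix
#'
#' 0 for pairs in the same cluster, 1 between clusters; pairs involving an
#' admixed population receive `admixed_value` (default 0.5, reflecting their
#' mixed ancestry) to either cluster.
#'
#' @param cluster_labels Named vector population -> cluster.
#' @param admixed Character vector of admixed populations.
#' @param admixed_value Dissimilarity for admixed-involved pairs.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
cluster_distance_matrix <- function(cluster_labels, admixed = character(0),
                                    admixed_value = 0.5) {
  pops <- names(cluster_labels)
  out <- outer(cluster_labels, cluster_labels, FUN = `!=`) * 1
  adm <- pops %in% admixed
  out[adm, ] <- admixed_value
  out[, adm] <- admixed_value
  diag(out) <- 0
  dimnames(out) <- list(pops, pops)
  out
}
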