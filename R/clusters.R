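#' Assign population clusters by k-means on band-frequency profiles
#'
#' A clustering surrogate for use when no externally derived cluster labels
#' are available: k-means on the per-population band-frequency vectors over
#' a range of cluster counts, with K chosen by mean silhouette width. A
#' population whose distance to its nearest centroid exceeds `admix_ratio`
#' times its distance to the second-nearest is flagged admixed (it sits
#' between clusters); admixed populations still carry their primary cluster.
#' Downstream analyses always accept user-supplied labels instead.
#'
#' @param ft A `freq_table` from [band_frequencies()].
#' @param K_range Candidate numbers of clusters; `K = 1` is only honoured
#'   when it is the sole candidate (silhouette needs K >= 2).
#' @param admix_ratio Nearest/second-nearest centroid distance ratio above
#'   which a population is flagged admixed.
#' @param seed Seed (k-means starts).
#' @return Tibble of class `cluster_assignment` with columns `population`,
#'   `cluster`, `admixed`; attributes `K`, `method` (`"surrogate"`),
#'   `silhouette`.
#' @export
assign_clusters <- function(ft, K_range = 2:6, admix_ratio = 0.8, seed = NULL) {
  f <- freq_matrix(ft, "f")
  f[is.na(f)] <- mean(f, na.rm = TRUE)
  P <- nrow(f)
  if (any(K_range > P)) abort("K cannot exceed the number of populations")
  if (identical(as.integer(K_range), 1L)) {
    out <- tibble::tibble(
      population = rownames(f),
      cluster = "C1",
      admixed = FALSE
    )
    attr(out, "K") <- 1L
    attr(out, "method") <- "surrogate"
    attr(out, "silhouette") <- NA_real_
    class(out) <- c("cluster_assignment", class(out))
    return(out)
  }
  K_range <- K_range[K_range >= 2]
  d <- stats::dist(f)
  fits <- withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    lapply(K_range, function(K) {
      km <- stats::kmeans(f, centers = K, nstart = 25, iter.max = 50)
      sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      list(K = K, km = km, sil = sil)
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "sil"))]]
  km <- best$km
  # nearest / second-nearest centroid distance ratio with leave-one-out
  # centroids, so a population cannot mask its own intermediacy by pulling
  # the centroid of the cluster it was assigned to
  admixed <- vapply(seq_len(P), function(i) {
    d <- vapply(seq_len(best$K), function(k) {
      idx <- setdiff(which(km$cluster == k), i)
      cent <- if (length(idx)) {
        colMeans(f[idx, , drop = FALSE])
      } else {
        km$centers[k, ]
      }
      sqrt(sum((f[i, ] - cent)^2))
    }, 0)
    s <- sort(d)
    s[1] / s[2] > admix_ratio
  }, TRUE)
  out <- tibble::tibble(
    population = rownames(f),
    cluster = paste0("C", km$cluster),
    admixed = admixed
  )
  attr(out, "K") <- best$K
  attr(out, "method") <- "surrogate"
  attr(out, "silhouette") <- best$sil
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Convert a cluster assignment to a named label vector
#'
#' @param ca A `cluster_assignment` (or any tibble with `population` and
#'   `cluster` columns).
#' @return Named character vector, population -> cluster.
#' @export
cluster_labels <- function(ca) {
  setNames(ca$cluster, ca$population)
}

#' @rdname cluster_labels
#' @export
admixed_populations <- function(ca) {
  if (!"admixed" %in% names(ca)) {
    return(character(0))
  }
  ca$population[ca$admixed]
}

#' Write / read cluster labels as a two-column (plus flag) CSV
#'
#' @param ca A `cluster_assignment`.
#' @param path CSV path.
#' @export
write_cluster_assignment <- function(ca, path) {
  utils::write.csv(as.data.frame(ca), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_assignment
#' @export
read_cluster_assignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  if (!"admixed" %in% names(out)) out$admixed <- FALSE
  attr(out, "method") <- "user"
  attr(out, "K") <- length(unique(out$cluster))
  class(out) <- c("cluster_assignment", class(out))
  out
}
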