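#' Principal components of site environmental variables
#'
#' PCA on the correlation matrix: variables are z-scored, the correlation
#' matrix eigendecomposed, and scores obtained by projecting the standardized
#' data on the eigenvectors. Axes follow a deterministic sign convention:
#' each is oriented so that its largest-magnitude loading is positive.
#'
#' @param site_table Data frame with one row per site/population.
#' @param variables Character vector of (numeric) columns to use; default is
#'   every numeric column except coordinates.
#' @param id Column holding the site identifier (default `"population"`).
#' @return A list of class `env_pca`: `scores` (site x axis matrix),
#'   `loadings` (variable x axis), `variance_explained` (fractions summing
#'   to 1), `sdev`.
#' @export
environment_pca <- function(site_table, variables = NULL, id = "population") {
  if (is.null(variables)) {
    num <- vapply(site_table, is.numeric, logical(1))
    variables <- setdiff(names(site_table)[num], c("latitude", "longitude", id))
  }
  if (length(variables) < 2) abort("need at least 2 variables")
  X <- as.matrix(site_table[, variables, drop = FALSE])
  if (nrow(X) < 3) abort("need at least 3 sites")
  if (anyNA(X)) abort("missing values in environmental variables (imputation refused)")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant variable: ", paste(variables[sds == 0], collapse = ", ")))
  }
  Z <- scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # sign convention
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  scores <- Z %*% vecs
  dimnames(vecs) <- list(variables, paste0("PC", seq_len(ncol(vecs))))
  dimnames(scores) <- list(site_table[[id]], colnames(vecs))
  structure(
    list(
      scores = scores, loadings = vecs,
      variance_explained = vals / sum(vals),
      sdev = sqrt(vals)
    ),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat("<env_pca>", nrow(x$scores), "sites,", nrow(x$loadings), "variables\n")
  ve <- x$variance_explained
  cat(
    "variance explained:",
    paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @export
tidy.env_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "population") |>
    tidyr::pivot_longer(-"population", names_to = "axis", values_to = "score")
}

#' @rdname environment_pca
#' @param object,x An `env_pca`.
#' @param axes Pair of axes to plot.
#' @param ... Unused.
#' @export
autoplot.env_pca <- function(object, axes = c(1, 2), ...) {
  df <- tibble::as_tibble(object$scores[, axes, drop = FALSE],
    rownames = "population"
  )
  names(df)[2:3] <- c("x", "y")
  ve <- 100 * object$variance_explained[axes]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, label = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", axes[1], ve[1]),
      y = sprintf("PC%d (%.1f%%)", axes[2], ve[2])
    ) +
    ggplot2::theme_minimal()
}
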