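check_aligned <- function(mats) {
  labs <- rownames(mats[[1]])
  for (m in mats) {
    check_square(m)
    if (!identical(rownames(m), labs)) {
      abort("all matrices must share the same population labels and order")
    }
    if (max(abs(m - t(m))) > 1e-8) abort("matrices must be symmetric")
  }
  labs
}

mrm_ols <- function(yv, Xv) {
  fit <- stats::lm.fit(cbind(1, Xv), yv)
  list(
    coef = fit$coefficients,
    r2 = {
      tss <- sum((yv - mean(yv))^2)
      if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
    }
  )
}

#' Multiple regression on distance matrices
#'
#' Unfolds the lower triangles of the response and predictor matrices and
#' fits ordinary least squares. Significance comes from matrix-preserving
#' permutations: rows and columns of the response matrix are permuted
#' simultaneously, the model refitted, and
#' `p = (1 + #(|stat*| >= |stat|)) / (n_perm + 1)` computed for each
#' coefficient (two-sided on the coefficient) and for `R^2` (upper tail).
#'
#' @param y Square symmetric response distance matrix.
#' @param X Named list of square symmetric predictor matrices.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return A list of class `mrm_fit`: `coefficients` tibble (term, estimate,
#'   p.value), `r_squared`, `r_squared_p`, `n_perm`.
#' @export
mrm <- function(y, X, n_perm = 999, seed = NULL) {
  if (is.matrix(X)) X <- list(X)
  if (is.null(names(X)) || any(names(X) == "")) {
    names(X) <- paste0("X", seq_along(X))
  }
  labs <- check_aligned(c(list(y), X))
  yv <- unfold_lower(y)
  Xv <- vapply(X, unfold_lower, numeric(length(yv)))
  cn <- kappa(cbind(1, scale(Xv)), exact = TRUE)
  if (!is.finite(cn) || cn > 1e10) {
    abort(sprintf("collinear predictors (condition number %.3g)", cn))
  }
  obs <- mrm_ols(yv, Xv)
  n <- length(labs)
  exceed_b <- numeric(length(obs$coef))
  exceed_r2 <- 0
  withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      yp <- unfold_lower(y[pm, pm])
      perm <- mrm_ols(yp, Xv)
      exceed_b <- exceed_b + (abs(perm$coef) >= abs(obs$coef))
      exceed_r2 <- exceed_r2 + (perm$r2 >= obs$r2)
    }
  })
  pvals <- (1 + exceed_b) / (n_perm + 1)
  structure(
    list(
      coefficients = tibble::tibble(
        term = c("(Intercept)", names(X)),
        estimate = as.numeric(obs$coef),
        p.value = pvals
      ),
      r_squared = obs$r2,
      r_squared_p = (1 + exceed_r2) / (n_perm + 1),
      n_perm = n_perm
    ),
    class = "mrm_fit"
  )
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat("<mrm_fit>\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf(
    "R^2 = %.4f (p = %.4g, %d permutations)\n",
    x$r_squared, x$r_squared_p, x$n_perm
  ))
  invisible(x)
}

#' @export
tidy.mrm_fit <- function(x, ...) x$coefficients

#' @export
glance.mrm_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, p.value = x$r_squared_p, n_perm = x$n_perm
  )
}

#' Forward stepwise selection among candidate distance matrices
#'
#' Starting from an intercept-only model, repeatedly considers every
#' candidate matrix not yet selected, fits the augmented model, and measures
#' the increase in `R^2` together with its matrix-permutation p-value (the
#' response matrix permuted, both models refitted, tail probability of the
#' permuted increase). The candidate with the largest significant increase
#' (`p <= p_enter`) joins the model; selection stops when no candidate
#' qualifies.
#'
#' @param y Response distance matrix.
#' @param candidates Named list of candidate predictor matrices.
#' @param p_enter Permutation p-value required to enter.
#' @param n_perm Number of permutations per test.
#' @param seed Seed.
#' @return A list of class `stepwise_mrm`: `selected` (ordered names),
#'   `steps` tibble (candidate, delta_r2, p.value, entered per round), and
#'   `final` ([mrm()] fit on the selected set, `NULL` when empty).
#' @export
forward_stepwise <- function(y, candidates, p_enter = 0.05, n_perm = 999,
                             seed = NULL) {
  if (length(candidates) < 1) abort("need at least one candidate")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("X", seq_along(candidates))
  }
  labs <- check_aligned(c(list(y), candidates))
  n <- length(labs)
  selected <- character(0)
  steps <- list()
  seed <- seed %||% sample.int(2^31 - 1, 1)
  round <- 0L
  repeat {
    round <- round + 1L
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    Xin <- if (length(selected)) {
      vapply(candidates[selected], unfold_lower, numeric(n * (n - 1) / 2))
    } else {
      NULL
    }
    res <- purrr::map_dfr(remaining, function(cand) {
      Xcand <- cbind(Xin, unfold_lower(candidates[[cand]]))
      yv <- unfold_lower(y)
      r2_red <- if (is.null(Xin)) 0 else mrm_ols(yv, Xin)$r2
      d_obs <- mrm_ols(yv, Xcand)$r2 - r2_red
      exceed <- 0
      withr::with_seed(sub_seed(seed, round * 131 + match(cand, names(candidates))), {
        for (b in seq_len(n_perm)) {
          pm <- sample.int(n)
          yp <- unfold_lower(y[pm, pm])
          d_perm <- mrm_ols(yp, Xcand)$r2 -
            (if (is.null(Xin)) 0 else mrm_ols(yp, Xin)$r2)
          exceed <- exceed + (d_perm >= d_obs)
        }
      })
      tibble::tibble(
        round = round, candidate = cand, delta_r2 = d_obs,
        p.value = (1 + exceed) / (n_perm + 1)
      )
    })
    ok <- res$p.value <= p_enter
    if (!any(ok)) {
      res$entered <- FALSE
      steps[[round]] <- res
      break
    }
    pick <- res$candidate[ok][which.max(res$delta_r2[ok])]
    res$entered <- res$candidate == pick
    steps[[round]] <- res
    selected <- c(selected, pick)
  }
  final <- if (length(selected)) {
    mrm(y, candidates[selected], n_perm = n_perm, seed = sub_seed(seed, 9999))
  } else {
    NULL
  }
  structure(
    list(
      selected = selected,
      steps = dplyr::bind_rows(steps),
      final = final,
      p_enter = p_enter, n_perm = n_perm
    ),
    class = "stepwise_mrm"
  )
}

#' @export
print.stepwise_mrm <- function(x, ...) {
  cat(
    "<stepwise_mrm> selected:",
    if (length(x$selected)) paste(x$selected, collapse = " + ") else "(none)", "\n"
  )
  print(as.data.frame(x$steps), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mantel and partial Mantel tests
#'
#' Simple Mantel: Pearson correlation of the unfolded lower triangles of `A`
#' and `B`, significance by permuting the rows/columns of `A`. Partial
#' Mantel: `A` and `B` are each regressed on the unfolded control matrices,
#' and the correlation of their residuals is tested by permuting the
#' residualized `A` as a matrix (residual-permutation method).
#'
#' @param A,B Square symmetric distance matrices.
#' @param controls List of control matrices (empty for a simple Mantel test);
#'   may include a binary same/different-cluster matrix from
#'   [cluster_distance_matrix()].
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return A list of class `mantel_test`: `r`, `p_value`, `n_perm`,
#'   `controls` (names).
#' @export
partial_mantel <- function(A, B, controls = list(), n_perm = 999, seed = NULL) {
  labs <- check_aligned(c(list(A, B), controls))
  av <- unfold_lower(A)
  bv <- unfold_lower(B)
  n <- length(labs)
  if (length(controls)) {
    Cv <- vapply(controls, unfold_lower, numeric(length(av)))
    for (k in seq_len(ncol(Cv))) {
      if (isTRUE(all.equal(Cv[, k], av)) || isTRUE(all.equal(Cv[, k], bv))) {
        abort("a control matrix is identical to A or B")
      }
    }
    ra <- stats::lm.fit(cbind(1, Cv), av)$residuals
    rb <- stats::lm.fit(cbind(1, Cv), bv)$residuals
  } else {
    ra <- av
    rb <- bv
  }
  r_obs <- cor(ra, rb)
  RA <- fold_lower(ra, labs)
  exceed <- 0
  withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp <- unfold_lower(RA[pm, pm])
      exceed <- exceed + (abs(cor(rp, rb)) >= abs(r_obs))
    }
  })
  structure(
    list(
      r = r_obs,
      p_value = (1 + exceed) / (n_perm + 1),
      n_perm = n_perm,
      controls = names(controls) %||% character(0)
    ),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  kind <- if (length(x$controls)) {
    paste0("partial (", paste(x$controls, collapse = ", "), ")")
  } else {
    "simple"
  }
  cat(sprintf(
    "<mantel_test> %s: r = %.4f, p = %.4g (%d permutations)\n",
    kind, x$r, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(
    r = x$r, p.value = x$p_value, n_perm = x$n_perm,
    controls = paste(x$controls, collapse = "+")
  )
}
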