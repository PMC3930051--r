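# --- profiled-ML machinery for the random-intercept model on pairwise
# distances: y = X beta + Z u + e, u ~ N(0, su2) iid per pair category,
# e ~ N(0, s2). With lambda = su2/s2 and ZZ' = Q diag(d) Q', both beta and s2
# profile out in the rotated basis, leaving a 1-D likelihood in lambda.

lmm_prepare <- function(X, Z) {
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  Q <- eg$vectors
  d <- pmax(eg$values, 0)
  list(Q = Q, d = d, Xt = crossprod(Q, X), X = X, Z = Z, n = nrow(X))
}

lmm_profile <- function(lambda, prep, yt) {
  w <- 1 / (1 + lambda * prep$d)
  Xw <- prep$Xt * w
  xtx <- crossprod(prep$Xt, Xw)
  beta <- solve(xtx, crossprod(Xw, yt))
  r <- yt - prep$Xt %*% beta
  rss <- sum(w * r^2)
  n <- prep$n
  s2 <- rss / n
  ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) - 0.5 * sum(log1p(lambda * prep$d))
  list(loglik = ll, beta = drop(beta), s2 = s2)
}

lmm_fit_core <- function(prep, y, tol = 1e-10) {
  yt <- crossprod(prep$Q, y)
  obj <- function(logl) -lmm_profile(exp(logl), prep, yt)$loglik
  opt <- optimize(obj, interval = c(-12, 12), tol = tol)
  cand <- list(
    c(0, lmm_profile(0, prep, yt)$loglik),
    c(exp(opt$minimum), -opt$objective)
  )
  best <- cand[[which.max(vapply(cand, `[`, numeric(1), 2))]]
  lambda <- best[1]
  prof <- lmm_profile(lambda, prep, yt)
  s2 <- prof$s2
  su2 <- lambda * s2
  # BLUP of the category intercepts and fitted values on the original scale
  r <- y - prep$X %*% prof$beta
  w <- 1 / (1 + lambda * prep$d)
  vinv_r <- prep$Q %*% (w * crossprod(prep$Q, r))
  u <- lambda * crossprod(prep$Z, vinv_r)
  fitted <- drop(prep$X %*% prof$beta + prep$Z %*% u)
  r2 <- if (sd(fitted) > 0 && sd(y) > 0) cor(y, fitted)^2 else 0
  list(
    beta = prof$beta, sigma2 = s2, sigma_u2 = su2, lambda = lambda,
    loglik = prof$loglik, fitted = fitted, u = drop(u), r_squared = r2
  )
}

lmm_design <- function(ds, fixed) {
  bad <- setdiff(fixed, c("geo", "env"))
  if (length(bad)) abort(paste0("unknown fixed effect: ", paste(bad, collapse = ", ")))
  y <- unfold_lower(ds$genetic)
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if ("geo" %in% fixed) X <- cbind(X, geo = unfold_lower(ds$geographic))
  if ("env" %in% fixed) X <- cbind(X, env = unfold_lower(ds$environmental))
  cats <- factor(unfold_lower_chr(ds$category))
  if (nlevels(cats) < 2 || any(table(cats) < 2)) {
    abort("need at least 2 pair categories with at least 2 pairs each")
  }
  Z <- stats::model.matrix(~ 0 + cats)
  colnames(Z) <- levels(cats)
  list(y = y, X = X, Z = Z, category = cats)
}

#' Linear mixed model on unfolded pairwise distances
#'
#' Fits, by maximum likelihood, `genetic ~ fixed effects + (1 | pair
#' category) + error` on the unfolded lower triangles of a
#' [build_distance_set()]: the pair-category grouping absorbs the coarse
#' cluster structure so that any residual effect of geography or environment
#' is what the fixed effects measure. Estimation profiles both the fixed
#' effects and the residual variance out of the likelihood, leaving a
#' one-dimensional bounded optimization over the variance ratio
#' `sigma_u^2 / sigma^2` (tolerance 1e-10); the boundary `sigma_u^2 = 0` is
#' allowed. Fitted values include the predicted (BLUP) category effects, and
#' `R^2` is the squared correlation of observed and fitted values.
#'
#' @param ds A `distance_set`.
#' @param fixed Subset of `c("geo", "env")` (may be empty: intercept +
#'   category only).
#' @return An object of class `dist_lmm`.
#' @export
fit_distance_lmm <- function(ds, fixed = c("geo", "env")) {
  des <- lmm_design(ds, fixed)
  prep <- lmm_prepare(des$X, des$Z)
  fit <- tryCatch(
    lmm_fit_core(prep, des$y),
    error = function(e) {
      abort(paste0(
        "distance LMM did not converge: ", conditionMessage(e),
        " [n = ", length(des$y), ", fixed = ", paste(fixed, collapse = "+"), "]"
      ))
    }
  )
  structure(
    c(
      fit,
      list(
        fixed = fixed, observed = des$y, category = des$category,
        design = des, n = length(des$y)
      )
    ),
    class = "dist_lmm"
  )
}

#' @export
print.dist_lmm <- function(x, ...) {
  cat("<dist_lmm> ML fit on", x$n, "pairs\n")
  cat("fixed effects:\n")
  print(round(setNames(as.numeric(x$beta), colnames(x$design$X)), 5))
  cat(sprintf(
    "sigma_u^2 = %.5g  sigma^2 = %.5g  logLik = %.4f  R^2 = %.3f\n",
    x$sigma_u2, x$sigma2, x$loglik, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.dist_lmm <- function(x, ...) {
  tibble::tibble(
    term = colnames(x$design$X),
    estimate = as.numeric(x$beta)
  )
}

#' @export
glance.dist_lmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, sigma2 = x$sigma2, sigma_u2 = x$sigma_u2,
    r.squared = x$r_squared, nobs = x$n
  )
}

#' Parametric-bootstrap likelihood-ratio test for nested distance LMMs
#'
#' Fits the reduced model by ML, simulates the response `B` times from the
#' fitted null (drawing fresh category effects and residuals from the
#' estimated variances), refits both models to each simulated response, and
#' compares the observed likelihood-ratio statistic `2 * (logLik_full -
#' logLik_reduced)` with the simulated distribution:
#' `p = (1 + #(sim >= obs)) / (B + 1)`.
#'
#' @param ds A `distance_set`.
#' @param full_fixed,reduced_fixed Fixed-effect sets; `reduced_fixed` must be
#'   a subset of `full_fixed`.
#' @param B Number of bootstrap replicates.
#' @param seed Seed.
#' @return A list of class `boot_lrt`: `statistic`, `p_value`, `sim_stats`,
#'   `B`, `n_retries`, plus both fits.
#' @export
parametric_bootstrap_lrt <- function(ds, full_fixed = c("geo", "env"),
                                     reduced_fixed = character(0),
                                     B = 1000, seed = NULL) {
  if (!all(reduced_fixed %in% full_fixed)) {
    abort("reduced_fixed must be a subset of full_fixed")
  }
  des_f <- lmm_design(ds, full_fixed)
  des_r <- lmm_design(ds, reduced_fixed)
  prep_f <- lmm_prepare(des_f$X, des_f$Z)
  prep_r <- lmm_prepare(des_r$X, des_r$Z)
  fit_f <- lmm_fit_core(prep_f, des_f$y)
  fit_r <- lmm_fit_core(prep_r, des_r$y)
  obs <- max(0, 2 * (fit_f$loglik - fit_r$loglik))
  mu_r <- drop(des_r$X %*% fit_r$beta)
  Z <- des_r$Z
  q <- ncol(Z)
  n <- length(mu_r)
  n_retries <- 0L
  sim_stats <- numeric(B)
  withr::with_seed(seed %||% sample.int(2^31 - 1, 1), {
    for (b in seq_len(B)) {
      for (attempt in 1:4) {
        ystar <- mu_r + drop(Z %*% rnorm(q, 0, sqrt(fit_r$sigma_u2))) +
          rnorm(n, 0, sqrt(fit_r$sigma2))
        res <- tryCatch(
          {
            ff <- lmm_fit_core(prep_f, ystar)
            fr <- lmm_fit_core(prep_r, ystar)
            max(0, 2 * (ff$loglik - fr$loglik))
          },
          error = function(e) NULL
        )
        if (!is.null(res)) break
        n_retries <- n_retries + 1L
        if (attempt == 4) abort("bootstrap replicate failed after 3 retries")
      }
      sim_stats[b] <- res
    }
  })
  structure(
    list(
      statistic = obs,
      p_value = (1 + sum(sim_stats >= obs)) / (B + 1),
      sim_stats = sim_stats, B = B, n_retries = n_retries,
      full = structure(c(fit_f, list(fixed = full_fixed, design = des_f, n = n)),
        class = "dist_lmm"
      ),
      reduced = structure(c(fit_r, list(fixed = reduced_fixed, design = des_r, n = n)),
        class = "dist_lmm"
      )
    ),
    class = "boot_lrt"
  )
}

#' @export
print.boot_lrt <- function(x, ...) {
  cat(sprintf(
    "<boot_lrt> LR = %.4f, p = %.4g (B = %d, retries = %d)\n",
    x$statistic, x$p_value, x$B, x$n_retries
  ))
  invisible(x)
}

#' @export
glance.boot_lrt <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value, B = x$B,
    r.squared.full = x$full$r_squared, r.squared.reduced = x$reduced$r_squared
  )
}
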