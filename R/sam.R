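#' Logistic environmental-association scan for dominant markers
#'
#' For every polymorphic locus and every environmental predictor (site-level
#' values broadcast to the individuals of each population), fits a univariate
#' logistic regression of individual band presence on the predictor by
#' iteratively reweighted least squares (convergence tolerance 1e-8) and
#' computes both a Wald test on the slope and a likelihood-ratio G-test
#' against the intercept-only model (1 df). With `m = loci x predictors`
#' models in the family, an association is significant only when BOTH tests
#' fall below the Bonferroni threshold `alpha / m`. Loci showing complete
#' separation (divergent slope) are flagged unstable and excluded from the
#' significant set.
#'
#' @param m A [band_matrix()].
#' @param predictors Numeric matrix (or data frame) of site-level predictor
#'   values, row names (or a `population` column) naming the populations;
#'   typically the first PCA axes of the environmental variables.
#' @param alpha Family-wise significance level.
#' @return Tibble of class `sam_scan` with one row per locus x predictor:
#'   `locus`, `predictor`, `slope`, `wald_p`, `g_p`, `g_stat`, `unstable`,
#'   `significant`; attributes `n_models`, `threshold`, `alpha`,
#'   `n_polymorphic`.
#' @export
sam_scan <- function(m, predictors, alpha = 0.01) {
  if (is.data.frame(predictors)) {
    if ("population" %in% names(predictors)) {
      rn <- predictors$population
      predictors <- as.matrix(predictors[setdiff(names(predictors), "population")])
      rownames(predictors) <- rn
    } else {
      predictors <- as.matrix(predictors)
    }
  }
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("pred", seq_len(ncol(predictors)))
  }
  pops <- unique(m$population)
  if (!all(pops %in% rownames(predictors))) {
    abort("predictors must carry a value for every population")
  }
  const <- apply(predictors[pops, , drop = FALSE], 2, function(v) sd(v) == 0)
  if (any(const)) {
    abort(paste0(
      "predictor constant across populations: ",
      paste(colnames(predictors)[const], collapse = ", ")
    ))
  }
  poly <- polymorphic_loci(m)
  loci <- colnames(m$x)[poly]
  n_models <- length(loci) * ncol(predictors)
  threshold <- alpha / n_models
  xi <- predictors[m$population, , drop = FALSE]
  res <- vector("list", n_models)
  k <- 0L
  for (pr in colnames(predictors)) {
    for (lc in loci) {
      y <- m$x[, lc]
      ok <- !is.na(y)
      yv <- y[ok]
      xv <- xi[ok, pr]
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, xv), yv,
          family = stats::binomial(),
          control = stats::glm.control(epsilon = 1e-8, maxit = 50)
        )
      )
      b <- fit$coefficients[2]
      R <- qr.R(fit$qr)
      se <- tryCatch(sqrt(diag(chol2inv(R)))[2], error = function(e) Inf)
      pbar <- mean(yv)
      dev_null <- -2 * sum(yv * log(pbar) + (1 - yv) * log(1 - pbar))
      g <- max(0, dev_null - fit$deviance)
      unstable <- !fit$converged || !is.finite(se) || abs(b) > 15 || se > 100
      k <- k + 1L
      res[[k]] <- tibble::tibble(
        locus = lc, predictor = pr, slope = unname(b),
        wald_p = 2 * pnorm(-abs(b / se)),
        g_stat = g,
        g_p = pchisq(g, df = 1, lower.tail = FALSE),
        unstable = unstable
      )
    }
  }
  out <- dplyr::bind_rows(res)
  out$significant <- !out$unstable & out$wald_p < threshold & out$g_p < threshold
  attr(out, "n_models") <- n_models
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "n_polymorphic") <- length(loci)
  class(out) <- c("sam_scan", class(out))
  out
}

scan_candidates <- function(x) {
  if (is.character(x)) {
    return(unique(x))
  }
  if (inherits(x, "fdist_scan") || inherits(x, "bayescan_scan")) {
    return(x$locus[x$candidate])
  }
  if (inherits(x, "sam_scan")) {
    return(unique(x$locus[x$significant]))
  }
  abort("cannot extract candidate loci from this object")
}

#' Consensus table across candidate-locus methods
#'
#' Combines the candidate sets of any number of scans into a per-locus flag
#' table with the number of detecting methods, sorted by that count and then
#' by F_ST.
#'
#' @param scans Named list of scan results ([fdist_scan()],
#'   [bayescan_scan()], [sam_scan()]) or bare character vectors of loci.
#' @param fst Optional [dominant_fst()] table used for sorting and for the
#'   per-method percentages of polymorphic loci detected.
#' @return Tibble of class `consensus_outliers` with one row per candidate
#'   locus; attribute `percent_detected` when `fst` is supplied.
#' @export
consensus_outliers <- function(scans, fst = NULL) {
  if (length(scans) < 1) abort("need at least one method's output")
  if (is.null(names(scans))) names(scans) <- paste0("method", seq_along(scans))
  sets <- lapply(scans, scan_candidates)
  loci <- unique(unlist(sets))
  out <- tibble::tibble(locus = loci)
  for (nm in names(sets)) out[[nm]] <- loci %in% sets[[nm]]
  out$n_methods <- rowSums(as.matrix(out[names(sets)]))
  if (!is.null(fst)) {
    out <- dplyr::left_join(out, fst[, c("locus", "fst")], by = "locus")
    out <- dplyr::arrange(out, dplyr::desc(.data$n_methods), dplyr::desc(.data$fst))
    npoly <- nrow(fst)
    attr(out, "percent_detected") <- c(
      vapply(sets, function(s) 100 * length(s) / npoly, 0),
      overall = 100 * length(loci) / npoly
    )
  } else {
    out <- dplyr::arrange(out, dplyr::desc(.data$n_methods))
  }
  class(out) <- c("consensus_outliers", class(out))
  out
}

#' Correlate candidate-locus band frequencies with phenotype means
#'
#' Within each experiment, traits are first pruned for redundancy: while any
#' trait pair correlates above `r_prune` in absolute value, the trait with
#' the larger mean absolute correlation to the remaining traits is dropped.
#' Each (candidate locus, retained trait) pair is then tested with Pearson
#' correlation between the locus's per-population band frequencies and the
#' trait's population means (two-sided t-test), and the p-values corrected
#' across all tested pairs (`"holm"` default, `"bonferroni"` by flag).
#'
#' @param ft A `freq_table` from [band_frequencies()].
#' @param phenotypes Named list of phenotype tables (one per experiment, with
#'   a `population` column and numeric trait columns).
#' @param loci Candidate locus names to test.
#' @param r_prune Redundancy threshold on inter-trait correlation.
#' @param method Multiple-testing correction.
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble of class `trait_correlation`: `experiment`, `locus`,
#'   `trait`, `r`, `p`, `p_adj`, `significant`; attribute `pruned_traits`.
#' @export
locus_trait_correlation <- function(ft, phenotypes, loci, r_prune = 0.7,
                                    method = c("holm", "bonferroni"),
                                    alpha = 0.05) {
  method <- match.arg(method)
  if (!length(loci)) abort("no candidate loci supplied")
  f <- freq_matrix(ft, "f")
  rows <- list()
  pruned <- list()
  for (exp_label in names(phenotypes)) {
    tab <- phenotypes[[exp_label]]
    traits <- setdiff(
      names(tab)[vapply(tab, is.numeric, logical(1))],
      c("population", "experiment")
    )
    zv <- traits[vapply(traits, function(tr) sd(tab[[tr]]) == 0, logical(1))]
    if (length(zv)) {
      warn(paste0("zero-variance trait(s) dropped: ", paste(zv, collapse = ", ")))
      traits <- setdiff(traits, zv)
    }
    dropped <- character(0)
    repeat {
      if (length(traits) < 2) break
      cm <- abs(cor(as.matrix(tab[traits])))
      diag(cm) <- 0
      if (max(cm) <= r_prune) break
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- traits[worst]
      score <- rowMeans(cm)[pair]
      drop <- pair[which.max(score)]
      dropped <- c(dropped, drop)
      traits <- setdiff(traits, drop)
    }
    pruned[[exp_label]] <- dropped
    pops <- intersect(tab$population, rownames(f))
    if (length(pops) < 4) abort("need at least 4 populations with both trait means and frequencies")
    for (lc in intersect(loci, colnames(f))) {
      bf <- f[pops, lc]
      for (tr in traits) {
        tv <- tab[[tr]][match(pops, tab$population)]
        r <- cor(bf, tv)
        n <- length(pops)
        p <- if (abs(r) >= 1) {
          0
        } else {
          2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          experiment = exp_label, locus = lc, trait = tr, r = r, p = p, n = n
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_adj <= alpha
  out <- dplyr::arrange(out, .data$p_adj)
  attr(out, "pruned_traits") <- pruned
  class(out) <- c("trait_correlation", class(out))
  out
}
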