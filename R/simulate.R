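#' Configuration for the synthetic dominant-marker generator
#'
#' Bundles and validates every parameter of the generator. Defaults emulate a
#' two-cluster survey of nine annual-plant populations (about 15 individuals
#' each, 229 dominant loci) sampled along a steep aridity gradient, with one
#' admixed population at the geographic contact zone, moderate hierarchical
#' differentiation, a small set of loci under environment-driven divergent
#' selection, and population phenotype means driven by the environment plus
#' one trait-linked locus.
#'
#' @param n_clusters Number of genetic clusters.
#' @param pops_per_cluster Populations per cluster (admixed populations extra).
#' @param n_admixed Number of admixed populations (each a 50/50 frequency
#'   mixture of one population from each of two clusters).
#' @param n_individuals_per_pop Individuals sampled per population.
#' @param n_loci Number of dominant loci.
#' @param f_ct Differentiation among clusters (Balding-Nichols F), in `[0, 1)`.
#' @param f_sc Differentiation among populations within clusters, in `[0, 1)`.
#' @param ancestral_freq_prior Shape pair `(a, b)` of the Beta prior for each
#'   locus's ancestral dominant-allele frequency. The Uniform(0,1) default
#'   yields roughly 80% polymorphic loci at the sampled sizes.
#' @param n_selected_loci Loci placed under divergent selection.
#' @param selection_slope Logit shift in dominant-allele frequency per unit of
#'   standardized environment at selected loci.
#' @param env_gradient_strength Multiplier on the deterministic dependence of
#'   climatic/edaphic variables on latitude (0 removes the gradient).
#' @param edaphic_cor Cross-correlation in `[0, 1]` between the edaphic factor
#'   and the climatic gradient.
#' @param missing_rate Probability any entry is masked missing.
#' @param n_replicate_pairs Individuals re-genotyped as replicates.
#' @param genotyping_error Per-locus flip probability for replicates.
#' @param phenotype_env_coefs Named list: for each experiment, a named vector
#'   of per-trait slopes on the standardized environmental score. `NULL` uses
#'   built-in defaults covering phenology, size, trichome and herbivory traits.
#' @param phenotype_locus_coef Effect of the designated selected locus's band
#'   frequency on its linked traits (stem trichomes in the net house, late
#'   herbivory in the common garden).
#' @param noise_sd Multiplier on the built-in per-trait residual standard
#'   deviations of the population trait means (each trait carries a residual
#'   scale matched to its measurement scale: days of phenology, centimetres
#'   of height, 0-5 ordinal scores), so traits driven by the same gradient
#'   are correlated but not collinear. A named numeric vector instead sets
#'   absolute per-trait residual SDs.
#' @param seed Integer seed; the same config + seed reproduces the dataset
#'   exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 2,
                       pops_per_cluster = 4,
                       n_admixed = 1,
                       n_individuals_per_pop = 15,
                       n_loci = 229,
                       f_ct = 0.08,
                       f_sc = 0.06,
                       ancestral_freq_prior = c(1, 1),
                       n_selected_loci = 5,
                       selection_slope = 2,
                       env_gradient_strength = 1,
                       edaphic_cor = 0.5,
                       missing_rate = 0.02,
                       n_replicate_pairs = 15,
                       genotyping_error = 0.0078,
                       phenotype_env_coefs = NULL,
                       phenotype_locus_coef = 2,
                       noise_sd = 1,
                       seed = 1L) {
  stopifnot(
    is_count(n_clusters), is_count(pops_per_cluster),
    is_count(n_individuals_per_pop), is_count(n_loci),
    n_admixed >= 0, n_admixed == floor(n_admixed),
    n_selected_loci >= 0, n_selected_loci == floor(n_selected_loci),
    n_replicate_pairs >= 0, n_replicate_pairs == floor(n_replicate_pairs)
  )
  if (!is_prob(f_ct) || f_ct >= 1) abort("f_ct must lie in [0, 1)")
  if (!is_prob(f_sc) || f_sc >= 1) abort("f_sc must lie in [0, 1)")
  if (!is_prob(missing_rate)) abort("missing_rate must lie in [0, 1]")
  if (!is_prob(genotyping_error)) abort("genotyping_error must lie in [0, 1]")
  if (!is_prob(edaphic_cor)) abort("edaphic_cor must lie in [0, 1]")
  if (length(ancestral_freq_prior) != 2 || any(ancestral_freq_prior <= 0)) {
    abort("ancestral_freq_prior must be two positive Beta shapes")
  }
  if (n_selected_loci > n_loci) abort("n_selected_loci exceeds n_loci")
  if (n_admixed > 0 && n_clusters < 2) {
    abort("admixed populations need at least two clusters")
  }
  n_pops <- n_clusters * pops_per_cluster + n_admixed
  if (n_replicate_pairs > n_pops * n_individuals_per_pop) {
    abort("more replicate pairs than individuals")
  }
  if (is.null(phenotype_env_coefs)) {
    phenotype_env_coefs <- list(
      net_house = c(
        bolting_day = 0, flowering_day = 0, stalk_height = 0,
        rosette_leaves = 0, rosette_diameter = 0, inflorescences = 0,
        bud_trichomes = 0.15, stem_trichomes = 0.3
      ),
      common_garden = c(
        bolting_day = -5, flowering_day = -6, stalk_height = -4,
        bud_trichomes = 0.3, stem_trichomes = 0.3,
        herbivory_early = -0.4, herbivory_late = -0.4,
        flower_pigmentation = 0.2
      )
    )
  }
  structure(
    list(
      n_clusters = n_clusters, pops_per_cluster = pops_per_cluster,
      n_admixed = n_admixed, n_individuals_per_pop = n_individuals_per_pop,
      n_loci = n_loci, f_ct = f_ct, f_sc = f_sc,
      ancestral_freq_prior = ancestral_freq_prior,
      n_selected_loci = n_selected_loci, selection_slope = selection_slope,
      env_gradient_strength = env_gradient_strength,
      edaphic_cor = edaphic_cor,
      missing_rate = missing_rate, n_replicate_pairs = n_replicate_pairs,
      genotyping_error = genotyping_error,
      phenotype_env_coefs = phenotype_env_coefs,
      phenotype_locus_coef = phenotype_locus_coef,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# population bookkeeping: cluster 1 in the north, admixed population(s) at the
# contact zone, remaining clusters southwards; order = latitude order
sim_populations <- function(config) {
  k <- config$pops_per_cluster
  cl <- rep(paste0("C", seq_len(config$n_clusters)), each = k)
  admix <- rep(FALSE, length(cl))
  if (config$n_admixed > 0) {
    pos <- k # insert after cluster 1
    cl <- append(cl, rep("ADM", config$n_admixed), after = pos)
    admix <- append(admix, rep(TRUE, config$n_admixed), after = pos)
  }
  tibble::tibble(
    population = sprintf("P%02d", seq_along(cl)),
    cluster = cl,
    admixed = admix
  )
}

bn_draw <- function(p, f) {
  # Balding-Nichols Beta draw around p with differentiation f; f = 0 is the
  # degenerate no-differentiation path (copy, no draw)
  if (f == 0) {
    return(p)
  }
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  out <- rbeta(length(p), a, b)
  # Beta(0, b) / Beta(a, 0) are point masses at 0 / 1
  out[a == 0] <- 0
  out[b == 0] <- 1
  out
}

#' Simulate hierarchical dominant-allele frequencies
#'
#' Two-level Balding-Nichols cascade: each locus draws an ancestral
#' dominant-allele frequency from the configured Beta prior; each cluster
#' draws its frequency around the ancestral value with differentiation
#' `f_ct`; each population draws around its cluster value with `f_sc`.
#' Admixed populations receive the 50/50 mean of one donor population from
#' each of the first two clusters (the geographically adjacent ones).
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to a stream derived from `config$seed`.
#' @return A list of class `freq_sim`: `freq` (populations x loci matrix of
#'   dominant-allele frequencies), `ancestral`, `cluster_freq`, `populations`
#'   (tibble with cluster labels and admixture flags), `donors`.
#' @export
simulate_hierarchical_frequencies <- function(config,
                                              seed = sub_seed(config$seed, 1)) {
  pops <- sim_populations(config)
  withr::with_seed(seed, {
    L <- config$n_loci
    p_anc <- rbeta(L, config$ancestral_freq_prior[1], config$ancestral_freq_prior[2])
    cluster_ids <- paste0("C", seq_len(config$n_clusters))
    cf <- do.call(rbind, lapply(cluster_ids, function(cl) bn_draw(p_anc, config$f_ct)))
    rownames(cf) <- cluster_ids
    freq <- matrix(NA_real_, nrow(pops), L,
      dimnames = list(pops$population, paste0("L", seq_len(L)))
    )
    for (i in seq_len(nrow(pops))) {
      if (!pops$admixed[i]) {
        freq[i, ] <- bn_draw(cf[pops$cluster[i], ], config$f_sc)
      }
    }
    donors <- NULL
    if (any(pops$admixed)) {
      # donors: last population of cluster 1 and first of cluster 2,
      # i.e. the populations flanking the contact zone
      d1 <- pops$population[max(which(pops$cluster == "C1"))]
      d2 <- pops$population[min(which(pops$cluster == "C2"))]
      donors <- c(d1, d2)
      for (i in which(pops$admixed)) {
        freq[i, ] <- (freq[d1, ] + freq[d2, ]) / 2
      }
    }
  })
  structure(
    list(
      freq = freq, ancestral = p_anc, cluster_freq = cf,
      populations = pops, donors = donors
    ),
    class = "freq_sim"
  )
}

#' Plant divergently selected loci along an environmental gradient
#'
#' Replaces the population frequencies of `n_selected_loci` randomly chosen
#' loci (among loci with intermediate ancestral frequency, so the logit is
#' finite and the signal realisable) by
#' `plogis(qlogis(p_ancestral) + selection_slope * env)`, where `env` is the
#' standardized per-population environmental value. Returns the modified
#' frequencies together with the ground truth needed for recovery tests.
#'
#' @param fs A `freq_sim` from [simulate_hierarchical_frequencies()].
#' @param env_values Standardized (mean 0, sd 1) environmental value per
#'   population, in the row order of `fs$freq`.
#' @param config A [sim_config()].
#' @param seed Seed for the choice of loci.
#' @return A list: `freq_sim` (modified), `truth` (class `sim_truth`).
#' @export
plant_selected_loci <- function(fs, env_values, config,
                                seed = sub_seed(config$seed, 2)) {
  if (length(env_values) != nrow(fs$freq)) {
    abort("need one env value per population")
  }
  if (config$n_selected_loci > ncol(fs$freq)) {
    abort("n_selected_loci exceeds the number of loci")
  }
  sel <- character(0)
  if (config$n_selected_loci > 0) {
    eligible <- which(fs$ancestral > 0.1 & fs$ancestral < 0.9)
    if (length(eligible) < config$n_selected_loci) {
      abort("too few loci with intermediate ancestral frequency to plant")
    }
    withr::with_seed(seed, {
      sel_idx <- sort(sample(eligible, config$n_selected_loci))
    })
    sel <- colnames(fs$freq)[sel_idx]
    shift <- outer(env_values, rep(config$selection_slope, length(sel_idx)))
    fs$freq[, sel_idx] <- stats::plogis(
      stats::qlogis(fs$ancestral[sel_idx])[col(shift)] + shift
    )
  }
  truth <- structure(
    list(
      selected_loci = sel,
      selection_slope = config$selection_slope,
      designated_locus = if (length(sel)) sel[1] else NA_character_,
      phenotype_locus_coef = config$phenotype_locus_coef,
      env_values = setNames(env_values, rownames(fs$freq)),
      f_ct = config$f_ct, f_sc = config$f_sc,
      seed = config$seed
    ),
    class = "sim_truth"
  )
  list(freq_sim = fs, truth = truth)
}

#' Simulate a band matrix from population allele frequencies
#'
#' With dominant-allele frequency `p` and null frequency `q = 1 - p`, each
#' individual shows the band with probability `1 - q^2` (Hardy-Weinberg
#' dominance). Entries are masked missing independently at `missing_rate`;
#' `n_replicate_pairs` individuals (spread round-robin across populations)
#' are duplicated with an independent per-locus flip probability
#' `genotyping_error`, the duplicate id gaining a `_rep` suffix and a
#' `replicate_of` annotation.
#'
#' @param fs A `freq_sim`, or a bare populations-x-loci frequency matrix.
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return A [band_matrix()].
#' @export
simulate_band_matrix <- function(fs, config, seed = sub_seed(config$seed, 3)) {
  freq <- if (inherits(fs, "freq_sim")) fs$freq else as.matrix(fs)
  if (any(freq < 0 | freq > 1)) abort("frequencies must lie in [0, 1]")
  n_ind <- config$n_individuals_per_pop
  pops <- rownames(freq)
  withr::with_seed(seed, {
    band_p <- 1 - (1 - freq)^2
    rows <- lapply(seq_along(pops), function(j) {
      matrix(
        rbinom(n_ind * ncol(freq), 1L, rep(band_p[j, ], each = n_ind)),
        nrow = n_ind
      )
    })
    x <- do.call(rbind, rows)
    population <- rep(pops, each = n_ind)
    ids <- paste0(population, "_i", sprintf("%02d", sequence(rep(n_ind, length(pops)))))
    rownames(x) <- ids
    colnames(x) <- colnames(freq)
    replicate_of <- rep(NA_character_, nrow(x))
    if (config$n_replicate_pairs > 0) {
      # round-robin across populations: first individual of each, then second...
      ord <- order(sequence(rep(n_ind, length(pops))))
      take <- ord[seq_len(config$n_replicate_pairs)]
      flips <- matrix(
        rbinom(length(take) * ncol(x), 1L, config$genotyping_error),
        nrow = length(take)
      )
      xr <- abs(x[take, , drop = FALSE] - flips)
      rownames(xr) <- paste0(ids[take], "_rep")
      x <- rbind(x, xr)
      population <- c(population, population[take])
      replicate_of <- c(replicate_of, ids[take])
    }
    if (config$missing_rate > 0) {
      miss <- matrix(
        runif(length(x)) < config$missing_rate,
        nrow = nrow(x)
      )
      # keep the per-locus "at least one scored" invariant
      full_cols <- colSums(!miss) == 0
      miss[1, full_cols] <- FALSE
      x[miss] <- NA_integer_
    }
  })
  band_matrix(x, population = population, replicate_of = replicate_of)
}

#' Simulate site environments along a latitudinal gradient
#'
#' Populations are placed on a one-dimensional north-south latitude gradient;
#' climatic variables (mean growing-season temperature, annual rainfall,
#' altitude) are linear in latitude plus noise, topography is weakly
#' structured, and edaphic variables (EC, pH, CaCO3, HMC/SSA, LOI, stoniness)
#' load on a soil factor only partially correlated (`edaphic_cor`) with the
#' climatic gradient. Raw variables are returned, not PCA scores.
#'
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return A `site_table` tibble, one row per population, with the
#'   standardized gradient score attached as attribute `"gradient"`.
#' @export
simulate_environment <- function(config, seed = sub_seed(config$seed, 4)) {
  pops <- sim_populations(config)
  P <- nrow(pops)
  withr::with_seed(seed, {
    lat <- seq(32.8, 31.9, length.out = P)
    lon <- 35.5 + rnorm(P, 0, 0.05)
    g <- as.numeric(scale(lat)) # +north, -south
    s <- config$env_gradient_strength
    e <- config$edaphic_cor * g * s +
      sqrt(1 - config$edaphic_cor^2) * rnorm(P) # soil factor
    site <- tibble::tibble(
      population = pops$population,
      latitude = lat,
      longitude = lon,
      altitude = -120 + 170 * g * s + rnorm(P, 0, 60),
      mean_temp = 12.8 - 1.0 * g * s + rnorm(P, 0, 0.2),
      rainfall = 300 + 120 * g * s + rnorm(P, 0, 25),
      slope_deg = pmax(0.5, 4 + 2 * rnorm(P)),
      aspect = runif(P, 0, 360),
      ec = pmax(0.05, 1.6 - 0.6 * e + rnorm(P, 0, 0.25)),
      ph = 7.8 + rnorm(P, 0, 0.12),
      caco3 = pmax(1, 28 - 9 * e + rnorm(P, 0, 4)),
      hmc = pmax(0.5, 2.6 - 0.9 * e + rnorm(P, 0, 0.25)),
      loi = pmax(0.5, 4 + rnorm(P, 0, 0.8)),
      stoniness = pmax(0.5, 18 + 10 * e + rnorm(P, 0, 4))
    )
    site$ssa <- ssa_from_hmc(site$hmc)
  })
  attr(site, "gradient") <- setNames(g, pops$population)
  site
}

#' Simulate population phenotype means for two experiments
#'
#' Each trait's population mean is
#' `intercept + env_coef * env_score + locus_coef * band_freq + noise`, where
#' `env_score` is the standardized rainfall of the site (the observable face
#' of the gradient) and the locus term applies only to the designated
#' trait/experiment pairs: stem trichomes in the insect-free net house and
#' late herbivory in the common garden, both tied to the first planted locus.
#' Environment-responsive (plastic) traits carry their environmental slope
#' only in the common-garden experiment.
#'
#' @param site_table From [simulate_environment()].
#' @param fs A `freq_sim` (post-planting).
#' @param truth A `sim_truth` from [plant_selected_loci()].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return Named list of two `phenotype_table` tibbles
#'   (`net_house`, `common_garden`), one row per population.
#' @export
simulate_phenotypes <- function(site_table, fs, truth, config,
                                seed = sub_seed(config$seed, 5)) {
  freq <- if (inherits(fs, "freq_sim")) fs$freq else as.matrix(fs)
  env <- as.numeric(scale(site_table$rainfall))
  if (sd(site_table$rainfall) == 0) env <- rep(0, nrow(site_table))
  locus_bf <- if (!is.na(truth$designated_locus)) {
    p <- freq[site_table$population, truth$designated_locus]
    1 - (1 - p)^2
  } else {
    rep(0, nrow(site_table))
  }
  intercepts <- c(
    bolting_day = 45, flowering_day = 62, stalk_height = 75,
    rosette_leaves = 12, rosette_diameter = 20, inflorescences = 8,
    bud_trichomes = 2.2, stem_trichomes = 1.2,
    herbivory_early = 2.5, herbivory_late = 1.2, flower_pigmentation = 2.5
  )
  # residual SD of a population trait mean, on each trait's own scale
  trait_scale <- c(
    bolting_day = 4, flowering_day = 4.5, stalk_height = 4,
    rosette_leaves = 1, rosette_diameter = 2, inflorescences = 1.5,
    bud_trichomes = 0.35, stem_trichomes = 0.25,
    herbivory_early = 0.4, herbivory_late = 0.25, flower_pigmentation = 0.3
  )
  noise_for <- function(tr) {
    ns <- config$noise_sd
    if (!is.null(names(ns))) {
      return(ns[[tr]] %||% trait_scale[[tr]])
    }
    ns * trait_scale[[tr]]
  }
  locus_trait <- c(net_house = "stem_trichomes", common_garden = "herbivory_late")
  withr::with_seed(seed, {
    out <- lapply(names(config$phenotype_env_coefs), function(exp_label) {
      coefs <- config$phenotype_env_coefs[[exp_label]]
      tab <- tibble::tibble(population = site_table$population)
      for (tr in names(coefs)) {
        mu <- intercepts[[tr]] + coefs[[tr]] * env
        if (!is.na(truth$designated_locus) && identical(locus_trait[[exp_label]], tr)) {
          mu <- mu + truth$phenotype_locus_coef * locus_bf
        }
        tab[[tr]] <- mu + rnorm(nrow(tab), 0, noise_for(tr))
      }
      tab$experiment <- exp_label
      tab
    })
  })
  setNames(out, names(config$phenotype_env_coefs))
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Runs the whole generator: environments, hierarchical frequencies, planted
#' selected loci, band matrix, and phenotype tables, each stage on its own
#' seed stream derived from `config$seed` so the dataset is byte-identical
#' across calls.
#'
#' @param config A [sim_config()].
#' @return A list of class `aflp_sim` with elements `band_matrix`,
#'   `site_table`, `phenotypes`, `freq_sim`, `truth`, `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_loci = 50, seed = 7))
#' sim$band_matrix
#' @export
simulate_dataset <- function(config = sim_config()) {
  site <- simulate_environment(config)
  g <- attr(site, "gradient")
  fs <- simulate_hierarchical_frequencies(config)
  planted <- plant_selected_loci(fs, g, config)
  bm <- simulate_band_matrix(planted$freq_sim, config)
  ph <- simulate_phenotypes(site, planted$freq_sim, planted$truth, config)
  structure(
    list(
      band_matrix = bm, site_table = site, phenotypes = ph,
      freq_sim = planted$freq_sim, truth = planted$truth, config = config
    ),
    class = "aflp_sim"
  )
}

#' @export
print.aflp_sim <- function(x, ...) {
  cat(sprintf(
    "<aflp_sim> %d populations, %d loci, %d selected, seed %d\n",
    nrow(x$freq_sim$freq), ncol(x$freq_sim$freq),
    length(x$truth$selected_loci), x$config$seed
  ))
  invisible(x)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path JSON path.
#' @return `read_truth` returns the `sim_truth`; `write_truth` returns `path`.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$env_values <- as.list(obj$env_values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$selected_loci <- as.character(raw$selected_loci %||% character(0))
  raw$env_values <- unlist(raw$env_values)
  structure(raw, class = "sim_truth")
}
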