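#' Configuration for the full analysis pipeline
#'
#' @param simulate A [sim_config()] to generate the inputs, or `NULL` to load
#'   them from files.
#' @param band_matrix_path,site_table_path,phenotype_paths Input paths used
#'   when `simulate` is `NULL` (`phenotype_paths` is a named character
#'   vector, one CSV per experiment).
#' @param stages Stages to run, in pipeline order; any subset of
#'   `c("diversity", "clusters", "amova", "distances", "lmm", "mrm", "scan",
#'   "correlate")` (the simulate/load stage always runs).
#' @param cluster_assignment Optional path to externally derived cluster
#'   labels (CSV, see [read_cluster_assignment()]); otherwise the k-means
#'   surrogate is used.
#' @param n_perm Permutations for AMOVA/MRM/Mantel.
#' @param B Bootstrap replicates for the distance-LMM tests.
#' @param k_axes PCA axes defining environmental distance.
#' @param p_enter Stepwise entry threshold.
#' @param scan A [scan_config()].
#' @param tree_bootstrap Locus-bootstrap replicates for the UPGMA tree.
#' @param seed Global seed, propagated to every stochastic stage.
#' @param outdir Output directory for per-stage artifacts.
#' @param resume Skip stages whose artifacts already exist in `outdir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            band_matrix_path = NULL,
                            site_table_path = NULL,
                            phenotype_paths = NULL,
                            stages = c(
                              "diversity", "clusters", "amova", "distances",
                              "lmm", "mrm", "scan", "correlate"
                            ),
                            cluster_assignment = NULL,
                            n_perm = 999, B = 199, k_axes = 4,
                            p_enter = 0.05,
                            scan = scan_config(n_sim = 10000),
                            tree_bootstrap = 200,
                            seed = 1L, outdir = tempfile("aflpscape_run_"),
                            resume = FALSE) {
  if (is.null(simulate)) {
    for (p in c(band_matrix_path, site_table_path, phenotype_paths)) {
      if (!file.exists(p)) abort(paste0("input file not found: ", p))
    }
  }
  structure(
    list(
      simulate = simulate, band_matrix_path = band_matrix_path,
      site_table_path = site_table_path, phenotype_paths = phenotype_paths,
      stages = stages, cluster_assignment = cluster_assignment,
      n_perm = n_perm, B = B, k_axes = k_axes, p_enter = p_enter,
      scan = scan, tree_bootstrap = tree_bootstrap,
      seed = as.integer(seed), outdir = outdir, resume = resume
    ),
    class = "pipeline_config"
  )
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

pl_log <- function(state, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[aflpscape] ", msg)
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg, "\n",
    file = state$logfile, append = TRUE
  )
}

#' Run the full landscape-genetics pipeline
#'
#' Orchestrates, on simulated or loaded data: diversity statistics and the
#' UPGMA tree; cluster assignment (surrogate or user labels); nonhierarchical
#' and hierarchical AMOVA; the distance set; the distance LMM with
#' parametric-bootstrap tests (cluster-only vs +geography vs +environment);
#' MRM, stepwise selection and partial Mantel tests for genetic and both
#' phenotype-distance responses; the three candidate-locus scans with their
#' consensus; and locus-trait correlations. Per-stage artifacts (CSV/JSON)
#' and a combined JSON report are written to the output directory; a stage
#' failure halts with a stage-named error, preserving completed artifacts.
#' With `resume = TRUE`, stages whose artifacts already exist are reloaded
#' instead of recomputed.
#'
#' @param cfg A [pipeline_config()].
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$logfile <- file.path(cfg$outdir, "pipeline.log")
  report <- list(seed = cfg$seed, stages = cfg$stages)
  art <- function(name) file.path(cfg$outdir, name)
  run_stage <- function(name, artifacts, compute, load) {
    t0 <- Sys.time()
    if (cfg$resume && all(file.exists(art(artifacts)))) {
      pl_log(state, "stage %s: resumed from artifacts", name)
      return(load())
    }
    out <- tryCatch(compute(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    pl_log(
      state, "stage %s: done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    out
  }

  # ---- inputs ----
  if (!is.null(cfg$simulate)) {
    sim <- run_stage(
      "simulate",
      c("band_matrix.csv", "site_table.csv", "truth.json"),
      compute = function() {
        s <- simulate_dataset(cfg$simulate)
        write_band_matrix(s$band_matrix, art("band_matrix.csv"))
        utils::write.csv(as.data.frame(s$site_table), art("site_table.csv"),
          row.names = FALSE
        )
        for (nm in names(s$phenotypes)) {
          utils::write.csv(as.data.frame(s$phenotypes[[nm]]),
            art(paste0("phenotypes_", nm, ".csv")),
            row.names = FALSE
          )
        }
        write_truth(s$truth, art("truth.json"))
        s
      },
      load = function() {
        list(
          band_matrix = read_band_matrix(art("band_matrix.csv")),
          site_table = tibble::as_tibble(utils::read.csv(art("site_table.csv"))),
          phenotypes = {
            fl <- list.files(cfg$outdir, "^phenotypes_.*\\.csv$", full.names = TRUE)
            setNames(
              lapply(fl, function(p) tibble::as_tibble(utils::read.csv(p))),
              sub("^phenotypes_(.*)\\.csv$", "\\1", basename(fl))
            )
          },
          truth = read_truth(art("truth.json"))
        )
      }
    )
    bm_full <- sim$band_matrix
    site <- sim$site_table
    phen <- sim$phenotypes
    report$truth <- list(
      selected_loci = sim$truth$selected_loci,
      designated_locus = sim$truth$designated_locus
    )
  } else {
    bm_full <- read_band_matrix(cfg$band_matrix_path)
    site <- tibble::as_tibble(utils::read.csv(cfg$site_table_path))
    phen <- lapply(cfg$phenotype_paths, function(p) {
      tibble::as_tibble(utils::read.csv(p))
    })
  }
  bm <- drop_replicates(bm_full)
  ft <- band_frequencies(bm)
  report$data <- list(
    n_individuals = nrow(bm$x), n_loci = ncol(bm$x),
    n_populations = length(unique(bm$population)),
    error_rate = if (any(!is.na(bm_full$replicate_of))) {
      genotyping_error_rate(bm_full)
    } else {
      NULL
    }
  )

  # ---- diversity ----
  if ("diversity" %in% cfg$stages) {
    div <- run_stage(
      "diversity", c("diversity.csv", "upgma.nwk"),
      compute = function() {
        tab <- dplyr::left_join(
          percent_polymorphic(ft),
          unbiased_heterozygosity(ft)[, c("population", "uHe")],
          by = "population"
        )
        utils::write.csv(as.data.frame(tab), art("diversity.csv"), row.names = FALSE)
        tr <- upgma_with_bootstrap(bm,
          B = cfg$tree_bootstrap,
          seed = sub_seed(cfg$seed, 11)
        )
        writeLines(tr$newick, art("upgma.nwk"))
        list(tab = tab, tree = tr)
      },
      load = function() {
        list(
          tab = tibble::as_tibble(utils::read.csv(art("diversity.csv"))),
          tree = list(newick = readLines(art("upgma.nwk")))
        )
      }
    )
    report$diversity <- list(
      mean_percent_polymorphic = mean(div$tab$percent_polymorphic),
      mean_uHe = mean(div$tab$uHe),
      tree = div$tree$newick
    )
  }

  # ---- clusters ----
  ca <- NULL
  if ("clusters" %in% cfg$stages) {
    ca <- run_stage(
      "clusters", "clusters.csv",
      compute = function() {
        out <- if (!is.null(cfg$cluster_assignment)) {
          read_cluster_assignment(cfg$cluster_assignment)
        } else {
          assign_clusters(ft, seed = sub_seed(cfg$seed, 12))
        }
        write_cluster_assignment(out, art("clusters.csv"))
        out
      },
      load = function() read_cluster_assignment(art("clusters.csv"))
    )
    report$clusters <- list(
      K = attr(ca, "K"),
      assignment = setNames(as.list(ca$cluster), ca$population),
      admixed = ca$population[ca$admixed]
    )
  }

  # ---- amova ----
  if ("amova" %in% cfg$stages) {
    am <- run_stage(
      "amova", "amova.json",
      compute = function() {
        res <- list(nonhierarchical = amova(bm,
          n_perm = cfg$n_perm,
          seed = sub_seed(cfg$seed, 13)
        ))
        if (!is.null(ca) && attr(ca, "K") >= 2) {
          res$hierarchical <- amova(bm,
            groups = cluster_labels(ca),
            n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, 14)
          )
        }
        json <- lapply(res, function(a) {
          list(
            design = a$design, table = a$table, phi = as.list(a$phi),
            p_values = as.list(a$p_values), n_perm = a$n_perm
          )
        })
        jsonlite::write_json(json, art("amova.json"), auto_unbox = TRUE, digits = NA)
        res
      },
      load = function() {
        raw <- jsonlite::read_json(art("amova.json"), simplifyVector = TRUE)
        lapply(raw, function(a) {
          a$table <- tibble::as_tibble(a$table)
          a
        })
      }
    )
    report$amova <- lapply(am, function(a) {
      list(
        percent = setNames(as.list(a$table$percent), a$table$stratum),
        phi = as.list(a$phi), p = as.list(a$p_values)
      )
    })
  }

  # ---- distances ----
  ds <- NULL
  pca <- NULL
  if ("distances" %in% cfg$stages) {
    if (is.null(ca)) abort("stage 'distances' needs stage 'clusters'")
    dsl <- run_stage(
      "distances",
      c(
        "phist.csv", "pca_scores.csv", "dist_genetic.csv",
        "dist_geographic.csv", "dist_environmental.csv", "dist_category.csv"
      ),
      compute = function() {
        phist <- pairwise_phist(bm)
        pca <- environment_pca(site)
        ds <- build_distance_set(
          phist, site, pca,
          k_axes = cfg$k_axes,
          cluster_labels = cluster_labels(ca),
          admixed = admixed_populations(ca)
        )
        write_matrix_csv(phist, art("phist.csv"))
        write_matrix_csv(pca$scores, art("pca_scores.csv"))
        write_matrix_csv(ds$genetic, art("dist_genetic.csv"))
        write_matrix_csv(ds$geographic, art("dist_geographic.csv"))
        write_matrix_csv(ds$environmental, art("dist_environmental.csv"))
        write_matrix_csv(ds$category, art("dist_category.csv"))
        list(ds = ds, pca = pca, phist = phist)
      },
      load = function() {
        ds <- structure(
          list(
            genetic = read_matrix_csv(art("dist_genetic.csv")),
            geographic = read_matrix_csv(art("dist_geographic.csv")),
            environmental = read_matrix_csv(art("dist_environmental.csv")),
            category = read_matrix_csv(art("dist_category.csv"))
          ),
          class = "distance_set"
        )
        ds$populations <- rownames(ds$genetic)
        list(
          ds = ds,
          pca = list(scores = read_matrix_csv(art("pca_scores.csv"))),
          phist = read_matrix_csv(art("phist.csv"))
        )
      }
    )
    ds <- dsl$ds
    pca <- dsl$pca
    report$distances <- list(
      mean_phist = mean(unfold_lower(dsl$phist)),
      pair_categories = as.list(table(unfold_lower_chr(ds$category)))
    )
  }

  # ---- distance LMM ----
  if ("lmm" %in% cfg$stages) {
    if (is.null(ds)) abort("stage 'lmm' needs stage 'distances'")
    lmm_res <- run_stage(
      "lmm", "lmm.json",
      compute = function() {
        base <- fit_distance_lmm(ds, fixed = character(0))
        geo <- parametric_bootstrap_lrt(ds, "geo", character(0),
          B = cfg$B, seed = sub_seed(cfg$seed, 15)
        )
        env <- parametric_bootstrap_lrt(ds, c("geo", "env"), "geo",
          B = cfg$B, seed = sub_seed(cfg$seed, 16)
        )
        out <- list(
          baseline = list(r_squared = base$r_squared, loglik = base$loglik),
          add_geographic = list(
            r_squared = geo$full$r_squared,
            statistic = geo$statistic, p = geo$p_value
          ),
          add_environmental = list(
            r_squared = env$full$r_squared,
            statistic = env$statistic, p = env$p_value
          ),
          B = cfg$B
        )
        jsonlite::write_json(out, art("lmm.json"), auto_unbox = TRUE, digits = NA)
        out
      },
      load = function() jsonlite::read_json(art("lmm.json"), simplifyVector = TRUE)
    )
    report$lmm <- lmm_res
  }

  # ---- MRM / stepwise / partial Mantel ----
  if ("mrm" %in% cfg$stages) {
    if (is.null(ds)) abort("stage 'mrm' needs stage 'distances'")
    mrm_res <- run_stage(
      "mrm", "mrm.json",
      compute = function() {
        preds <- list(environmental = ds$environmental, geographic = ds$geographic)
        out <- list()
        responses <- list(genetic = ds$genetic)
        for (nm in names(phen)) {
          ptab <- phen[[nm]]
          traits <- setdiff(
            names(ptab)[vapply(ptab, is.numeric, logical(1))], "population"
          )
          ppca <- environment_pca(ptab, variables = traits)
          k <- min(cfg$k_axes, ncol(ppca$scores))
          pd <- as.matrix(stats::dist(ppca$scores[ds$populations, 1:k]))
          responses[[paste0("phenotype_", nm)]] <- pd
        }
        for (rn in names(responses)) {
          y <- responses[[rn]]
          fit <- mrm(y, preds, n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, 17))
          st <- forward_stepwise(y, preds,
            p_enter = cfg$p_enter,
            n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, 18)
          )
          out[[rn]] <- list(
            coefficients = fit$coefficients,
            r_squared = fit$r_squared, r_squared_p = fit$r_squared_p,
            stepwise_selected = st$selected
          )
        }
        # climatic vs edaphic partial Mantel on the common-garden response,
        # controlling geography and cluster
        clim <- intersect(
          c("altitude", "mean_temp", "rainfall", "slope_deg", "aspect"),
          names(site)
        )
        edaph <- intersect(
          c("ec", "ph", "caco3", "hmc", "ssa", "loi", "stoniness"),
          names(site)
        )
        if (length(clim) >= 2 && length(edaph) >= 2 &&
          "phenotype_common_garden" %in% names(responses)) {
          ctrl <- list(
            geographic = ds$geographic,
            cluster = cluster_distance_matrix(
              cluster_labels(ca), admixed_populations(ca)
            )[ds$populations, ds$populations]
          )
          y <- responses$phenotype_common_garden
          for (sub in list(
            list(name = "climatic", vars = clim),
            list(name = "edaphic", vars = edaph)
          )) {
            spca <- environment_pca(site, variables = sub$vars)
            k <- min(cfg$k_axes, ncol(spca$scores))
            sd_mat <- as.matrix(stats::dist(spca$scores[ds$populations, 1:k]))
            mt <- partial_mantel(y, sd_mat, ctrl,
              n_perm = cfg$n_perm,
              seed = sub_seed(cfg$seed, 19)
            )
            out[[paste0("partial_mantel_", sub$name)]] <-
              list(r = mt$r, p = mt$p_value)
          }
        }
        jsonlite::write_json(out, art("mrm.json"), auto_unbox = TRUE, digits = NA)
        out
      },
      load = function() jsonlite::read_json(art("mrm.json"), simplifyVector = TRUE)
    )
    report$mrm <- mrm_res
  }

  # ---- candidate-locus scans ----
  scans <- NULL
  fst_tab <- NULL
  if ("scan" %in% cfg$stages) {
    if (is.null(pca)) abort("stage 'scan' needs stage 'distances'")
    scans <- run_stage(
      "scan", c("scan_fdist.csv", "scan_bayescan.csv", "scan_sam.csv", "scan_consensus.csv"),
      compute = function() {
        fd <- fdist_scan(bm, cfg$scan, seed = sub_seed(cfg$seed, 20))
        bs <- bayescan_scan(bm, cfg$scan, seed = sub_seed(cfg$seed, 21))
        sam <- sam_scan(bm, pca$scores[, 1:2, drop = FALSE],
          alpha = cfg$scan$sam_alpha
        )
        fst_tab <- dominant_fst(bm)
        cons <- consensus_outliers(
          list(fdist = fd, bayescan = bs, sam = sam),
          fst = fst_tab
        )
        utils::write.csv(as.data.frame(fd), art("scan_fdist.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(bs), art("scan_bayescan.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(sam), art("scan_sam.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(cons), art("scan_consensus.csv"), row.names = FALSE)
        list(fdist = fd, bayescan = bs, sam = sam, consensus = cons, fst = fst_tab)
      },
      load = function() {
        list(
          fdist = tibble::as_tibble(utils::read.csv(art("scan_fdist.csv"))),
          bayescan = tibble::as_tibble(utils::read.csv(art("scan_bayescan.csv"))),
          sam = tibble::as_tibble(utils::read.csv(art("scan_sam.csv"))),
          consensus = tibble::as_tibble(utils::read.csv(art("scan_consensus.csv"))),
          fst = NULL
        )
      }
    )
    fst_tab <- scans$fst
    cons <- scans$consensus
    report$scan <- list(
      mean_fst = if (!is.null(fst_tab)) attr(fst_tab, "mean_fst") else NULL,
      n_polymorphic = if (!is.null(fst_tab)) nrow(fst_tab) else NULL,
      n_candidates = list(
        fdist = sum(scans$fdist$candidate),
        bayescan = sum(scans$bayescan$candidate),
        sam = length(unique(scans$sam$locus[scans$sam$significant]))
      ),
      consensus_loci = cons$locus[cons$n_methods >= 2]
    )
  }

  # ---- locus-trait correlations ----
  if ("correlate" %in% cfg$stages) {
    if (is.null(scans)) abort("stage 'correlate' needs stage 'scan'")
    cand <- unique(scans$consensus$locus)
    if (length(cand)) {
      tc <- run_stage(
        "correlate", "trait_correlations.csv",
        compute = function() {
          out <- locus_trait_correlation(ft, phen, cand)
          utils::write.csv(as.data.frame(out), art("trait_correlations.csv"),
            row.names = FALSE
          )
          out
        },
        load = function() {
          tibble::as_tibble(utils::read.csv(art("trait_correlations.csv")))
        }
      )
      report$trait_correlations <- list(
        n_tested = nrow(tc),
        significant = tc[tc$significant, c("experiment", "locus", "trait", "r", "p_adj")]
      )
    } else {
      report$trait_correlations <- list(n_tested = 0)
    }
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  pl_log(state, "pipeline complete: %s", cfg$outdir)
  invisible(report)
}
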