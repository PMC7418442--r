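#' Pipeline configuration
#'
#' Assembles every stage parameter of the end-to-end analysis with its
#' default. Exactly one genotype source may be set: a file path
#' (`genotypes` + `genotype_format`) or the synthetic generator
#' (`synthetic`, a [sim_params()]). The stage list controls which parts
#' run; stages communicate only through the returned results and the
#' on-disk artefacts.
#'
#' MCMC-flavoured stages default to desk-scale problem sizes (documented in
#' the methods vignette); full-size settings are plain config values.
#'
#' @param synthetic A [sim_params()] or `NULL`.
#' @param genotypes Optional genotype file path.
#' @param genotype_format Format for `genotypes`.
#' @param sites Site coordinate tibble (`site`, `lon`, `lat`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "stats", "outliers", "structure", "dapc", "distances",
#'   "dispersal", "mantel", "gea")`.
#' @param thresholds [filter_thresholds()].
#' @param fst_n_perm,amova_n_perm,mantel_n_perm Permutation counts.
#' @param fdist Settings list for [fdist_null()] (`n_sim`, `n_demes`,
#'   `max_he`).
#' @param fmodel Settings list for [fmodel_scan()] (`n_iter`, `burn_in`,
#'   `thin`, `prior_odds`).
#' @param structure Settings list (`k_range`, `n_reps`, `n_iter`,
#'   `burn_in`).
#' @param dapc_n_pc,dapc_n_df DAPC dimensions.
#' @param dispersal Settings list (`scenario`, `config` =
#'   [dispersal_config()], `field` = [field_spec()] or `NULL` to build a
#'   coastal-retention field around the sites).
#' @param gea Settings list (`temp_sites` = sites with temperature loggers,
#'   `grid_spec`).
#' @param seed Global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @param out_dir Output directory for artefacts.
#' @return A `pipeline_config` list (validate with [validate_config()]).
#' @export
pipeline_config <- function(synthetic = sim_params(),
                            genotypes = NULL,
                            genotype_format = "structure",
                            sites = NULL,
                            stages = c("filter", "stats", "outliers",
                                       "structure", "dapc", "distances",
                                       "dispersal", "mantel", "gea"),
                            thresholds = filter_thresholds(),
                            fst_n_perm = 199,
                            amova_n_perm = 1999,
                            mantel_n_perm = 9999,
                            fdist = list(n_sim = 20000, n_demes = 500,
                                         max_he = 0.5),
                            fmodel = list(n_iter = 6000, burn_in = 2000,
                                          thin = 5, prior_odds = 10),
                            structure = list(k_range = 1:4, n_reps = 2,
                                             n_iter = 600, burn_in = 200),
                            dapc_n_pc = 30, dapc_n_df = 2,
                            dispersal = list(scenario = "conservative",
                                             config = dispersal_config(
                                               propagules_per_event = 5),
                                             field = NULL),
                            gea = list(temp_sites = NULL,
                                       grid_spec = list(n = 201,
                                                        half_width = 5,
                                                        prior_sd = 1)),
                            seed = 1,
                            out_dir = tempfile("seascapr_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults, resolves the site table, and enforces cross-stage
#' consistency (exactly one genotype source; dispersal checkpoints within
#' the maximum PLD; GEA temperature sites a subset of the genotype sites).
#'
#' @param cfg A [pipeline_config()].
#' @return The normalised config.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$genotypes) && !is.null(cfg$synthetic)) {
    abort("set either `genotypes` or `synthetic`, not both",
          class = "seascapr_config_error")
  }
  if (is.null(cfg$genotypes) && is.null(cfg$synthetic)) {
    abort("one of `genotypes` or `synthetic` is required",
          class = "seascapr_config_error")
  }
  if (!is.null(cfg$genotypes) && !file.exists(cfg$genotypes)) {
    abort(sprintf("genotype file not found: %s", cfg$genotypes),
          class = "seascapr_config_error")
  }
  dc <- cfg$dispersal$config %||% dispersal_config()
  if (any(dc$checkpoints_weeks > dc$max_pld_weeks)) {
    abort("dispersal checkpoints exceed the maximum PLD",
          class = "seascapr_config_error")
  }
  if (is.null(cfg$sites)) {
    n <- if (!is.null(cfg$synthetic)) cfg$synthetic$n_sites else 9
    cfg$sites <- synthetic_sites(n)
  }
  if (is.null(cfg$gea$temp_sites)) {
    cfg$gea$temp_sites <- head(cfg$sites$site, 6)
  }
  if (!all(cfg$gea$temp_sites %in% cfg$sites$site)) {
    abort("gea$temp_sites must be a subset of the site table",
          class = "seascapr_config_error")
  }
  if (is.null(cfg$dispersal$field)) {
    cfg$dispersal$field <- field_spec(flow_kind = "coastal_retention",
                                      reef_sites = cfg$sites)
  }
  cfg$dispersal$config <- dc
  cfg
}

#' Run the end-to-end seascape-genomics pipeline
#'
#' Stage order: genotype acquisition, locus filters, summary statistics and
#' AMOVA, the dual outlier scan with consensus calling, the neutral/outlier
#' split (downstream population-structure and seascape analyses use the
#' neutral panel), Bayesian clustering with Evanno delta-K, DAPC,
#' geographic and least-cost sea distances with isolation-by-distance
#' Mantel tests, larval dispersal with connectivity/resistance, the
#' FST-vs-resistance Mantel tests, and the thermal GEA scan. Every stage
#' draws its seed from the global seed via [stage_seed()]; artefacts are
#' written as TSV under `out_dir` and listed in the manifest.
#'
#' @param cfg A [pipeline_config()] (validated internally).
#' @return A `run_report`: `manifest` tibble, `results` list, `timings`,
#'   `warnings`, and the echoed config.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble(stage = character(), artifact = character(),
                     path = character())
  results <- list()
  timings <- list()
  warns <- character()
  emit <- function(stage, artifact, obj, writer = readr::write_tsv) {
    path <- file.path(cfg$out_dir, paste0(artifact, ".tsv"))
    writer(obj, path)
    manifest <<- bind_rows(manifest, tibble(stage = stage,
                                            artifact = artifact, path = path))
  }
  run_stage <- function(name, code) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(force(code), error = function(e) {
        emit("manifest", "manifest", manifest)
        abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              class = "seascapr_stage_error", parent = e)
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }
  num <- function(x) round(x, 6)

  ## genotypes
  g <- run_stage("acquire", {
    if (!is.null(cfg$genotypes)) {
      read_genotypes(cfg$genotypes, cfg$genotype_format)
    } else {
      sp <- cfg$synthetic
      sp$seed <- stage_seed(cfg$seed, "simulate")
      simulate_genotypes(sp)
    }
  })
  results$genotypes <- g

  if ("filter" %in% cfg$stages) {
    fl <- run_stage("filter", filter_loci(g, locus_meta(g), cfg$thresholds))
    g <- fl$genotypes
    results$filter_report <- fl$report
    emit("filter", "filter_report", fl$report)
  }

  if ("stats" %in% cfg$stages) {
    ss <- run_stage("stats", {
      s <- summary_stats(g)
      mutate(s, across(dplyr::where(is.numeric), num))
    })
    results$summary_stats <- ss
    emit("stats", "summary_stats", ss)
    am <- run_stage("stats", amova(g, n_perm = cfg$amova_n_perm,
                                   seed = stage_seed(cfg$seed, "amova")))
    results$amova <- am
    emit("stats", "amova", mutate(tidy(am), across(dplyr::where(is.numeric),
                                                   num)))
  }

  neutral <- g
  if ("outliers" %in% cfg$stages) {
    out <- run_stage("outliers", {
      lf <- locus_fst_he(g)
      target <- max(median(lf$fst), 0.01)
      sizes <- as.integer(table(factor(g$site, levels = unique(g$site))))
      null <- fdist_null(target, sizes, n_sim = cfg$fdist$n_sim,
                         n_demes = cfg$fdist$n_demes,
                         max_he = cfg$fdist$max_he,
                         seed = stage_seed(cfg$seed, "fdist"))
      fd <- fdist_pvalues(lf, null)
      fm <- fmodel_scan(g, mcmc = cfg$fmodel[c("n_iter", "burn_in", "thin")],
                        prior_odds = cfg$fmodel$prior_odds,
                        seed = stage_seed(cfg$seed, "fmodel"))
      cons <- consensus_outliers(fd, fm, total_loci = n_loci(g))
      list(fdist = fd, fmodel = fm, consensus = cons)
    })
    results$outliers <- out
    tab <- out$fdist |>
      left_join(out$fmodel$loci, by = "locus", suffix = c("_fdist", "_fmodel")) |>
      mutate(consensus = .data$locus %in% out$consensus$consensus$locus,
             across(dplyr::where(is.numeric), num))
    emit("outliers", "outlier_scan", tab)
    keep <- setdiff(geno_loci(g)$locus, out$consensus$consensus$locus)
    neutral <- select_loci(g, keep)
    results$neutral <- neutral
  }

  if ("structure" %in% cfg$stages) {
    st <- cfg$structure
    runs <- run_stage("structure", {
      rs <- list()
      for (K in st$k_range) {
        for (rep in seq_len(st$n_reps)) {
          rs[[length(rs) + 1L]] <- admixture_gibbs(
            g, K, n_iter = st$n_iter, burn_in = st$burn_in,
            seed = stage_seed(cfg$seed, sprintf("structure_K%d_r%d", K, rep)))
        }
      }
      rs
    })
    results$cluster_runs <- runs
    ev <- run_stage("structure", evanno_deltaK(runs))
    results$evanno <- ev
    emit("structure", "evanno",
         mutate(as_tibble(ev), across(dplyr::where(is.numeric), num)))
    bestk <- attr(ev, "best_k")
    best_run <- runs[[which(map_int(runs, "K") == bestk)[1]]]
    results$best_run <- best_run
    emit("structure", "q_matrix",
         mutate(tidy(best_run), across(dplyr::where(is.numeric), num)))
  }

  if ("dapc" %in% cfg$stages) {
    dp <- run_stage("dapc", dapc(neutral, n_pc = cfg$dapc_n_pc,
                                 n_df = cfg$dapc_n_df))
    results$dapc <- dp
    emit("dapc", "dapc_coords",
         mutate(tidy(dp), across(dplyr::where(is.numeric), num)))
  }

  fstm <- NULL
  if (any(c("distances", "mantel") %in% cfg$stages)) {
    fstm <- run_stage("distances",
                      pairwise_fst(neutral, n_perm = cfg$fst_n_perm,
                                   seed = stage_seed(cfg$seed, "fst")))
    results$fst <- fstm
    emit("distances", "pairwise_fst",
         mutate(tidy(fstm), across(dplyr::where(is.numeric), num)))
  }

  if ("distances" %in% cfg$stages) {
    km <- run_stage("distances", greatcircle_distances(cfg$sites))
    results$km <- km
    emit("distances", "greatcircle_km",
         mutate(tidy(km), across(dplyr::where(is.numeric), num)))
    ibd <- run_stage("mantel", {
      fst0 <- fstm$values; fst0[fst0 < 0] <- 0
      mantel(pairwise_mat(fst0, "fst"), km, n_perm = cfg$mantel_n_perm,
             seed = stage_seed(cfg$seed, "mantel_ibd"))
    })
    results$mantel_ibd <- ibd
    emit("mantel", "mantel_ibd", glance(ibd))
    nj <- run_stage("distances", {
      fst0 <- fstm$values; fst0[fst0 < 0] <- 0
      nj_tree(pairwise_mat(fst0, "fst"))
    })
    results$nj <- nj
    njp <- file.path(cfg$out_dir, "nj_fst.nwk")
    ape::write.tree(nj, njp)
    manifest <- bind_rows(manifest, tibble(stage = "distances",
                                           artifact = "nj_fst", path = njp))
  }

  if ("dispersal" %in% cfg$stages) {
    disp <- run_stage("dispersal", {
      fld <- make_velocity_field(cfg$dispersal$field)
      dcfg <- cfg$dispersal$config
      dcfg$seed <- stage_seed(cfg$seed, "dispersal")
      sched <- build_release_schedule(cfg$dispersal$scenario, cfg$sites)
      traj <- advect_particles(fld, sched, dcfg)
      cm <- settle_and_count(traj, cfg$sites, dcfg)
      list(field = fld, traj = traj, connectivity = cm)
    })
    results$dispersal <- disp
    emit("dispersal", "connectivity",
         mutate(tidy(disp$connectivity), across(dplyr::where(is.numeric), num)))
    emit("dispersal", "self_recruitment",
         mutate(disp$connectivity$self_recruitment,
                across(dplyr::where(is.numeric), num)))
    for (cw in disp$connectivity$checkpoints_weeks) {
      rm_ <- resistance(disp$connectivity, cw)
      results$resistance[[paste0("wk", cw)]] <- rm_
      emit("dispersal", sprintf("resistance_wk%d", cw),
           mutate(tidy(rm_), across(dplyr::where(is.numeric), num)))
    }
  }

  if ("mantel" %in% cfg$stages && !is.null(results$resistance)) {
    mr <- run_stage("mantel", {
      fst0 <- fstm$values; fst0[fst0 < 0] <- 0
      out <- list()
      for (nm in names(results$resistance)) {
        out[[nm]] <- mantel(pairwise_mat(fst0, "fst"),
                            results$resistance[[nm]],
                            n_perm = cfg$mantel_n_perm,
                            seed = stage_seed(cfg$seed, paste0("mantel_", nm)))
      }
      out
    })
    results$mantel_resistance <- mr
    emit("mantel", "mantel_resistance",
         bind_rows(imap(mr, function(m, nm) mutate(glance(m), checkpoint = nm,
                                                   .before = 1))))
  }

  if ("gea" %in% cfg$stages) {
    gr <- run_stage("gea", {
      temps <- list()
      for (i in seq_along(cfg$gea$temp_sites)) {
        s <- cfg$gea$temp_sites[i]
        lat <- cfg$sites$lat[match(s, cfg$sites$site)]
        prof <- temp_profile(mean = 26 - 0.3 * lat)
        temps[[s]] <- simulate_temperature(
          prof, seed = stage_seed(cfg$seed, paste0("temp_", s)))
      }
      tm <- thermal_metrics_by_site(temps)
      cov <- estimate_covariance(neutral)
      scan <- bayes_factor_scan(g, tm, cov, grid_spec = cfg$gea$grid_spec)
      list(thermal = tm, cov = cov, scan = scan)
    })
    results$gea <- gr
    emit("gea", "thermal_metrics",
         mutate(gr$thermal, across(dplyr::where(is.numeric), num)))
    emit("gea", "gea_scan",
         mutate(as_tibble(gr$scan), across(dplyr::where(is.numeric), num)))
  }

  emit("manifest", "manifest", manifest)
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing)) abort("manifest lists files missing on disk")
  structure(list(manifest = manifest, results = results, timings = timings,
                 warnings = warns, config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d artefacts in %s\n", nrow(x$manifest),
              x$config$out_dir))
  print(as.data.frame(x$manifest[, c("stage", "artifact")]))
  invisible(x)
}
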