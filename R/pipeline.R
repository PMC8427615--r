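# Whole-study orchestration: score -> filter -> classify -> diversity ->
# AMOVA suite -> Mantel suite -> outlier/environment scans -> ordination,
# driven by a YAML config, with CSV outputs and a reproducibility manifest.

#' Read and validate a pipeline configuration
#'
#' The YAML file may either point at scored input files (`inputs:` with
#' `aflp`, `msap_hpa`, `msap_msp`, optional `soil`, optional `dialect`) or
#' request a synthetic dataset (`simulate:` with [sim_params()] fields).
#' Defaults: 9999 AMOVA and pairwise permutations, 10000 Mantel and 100000
#' partial-Mantel randomisations, locus-AMOVA alpha 0.01, envelope quantiles
#' (0.005, 0.995), epsilon 0.05. Seeds are mandatory.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A config list (as from YAML).
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(
    n_perm_amova = 9999, n_perm_mantel = 10000, n_perm_partial = 100000,
    n_perm_locus = 999, n_perm_distlm = 9999, n_boot_upgma = 1000,
    alpha_locus = 0.01, envelope_quantiles = c(0.005, 0.995),
    n_sim_envelope = 20000, epsilon = 0.05, alpha_env = 0.05,
    filters = list(min_carriers = 4, size_range = c(150, 500)),
    grouping = "habitat"
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$seed)) abort("config must set `seed`")
  if (is.null(cfg$output_dir)) abort("config must set `output_dir`")
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulate)
  if (!has_inputs && !has_sim) {
    abort("config must provide `inputs:` paths or a `simulate:` block")
  }
  if (has_inputs) {
    req <- c("aflp", "msap_hpa", "msap_msp")
    miss <- req[!req %in% names(cfg$inputs)]
    if (length(miss)) abort(sprintf("inputs missing: %s",
                                    paste(miss, collapse = ", ")))
    for (f in unlist(cfg$inputs[c(req, "soil")])) {
      if (!is.null(f) && !file.exists(f)) abort(sprintf("input not found: %s", f))
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

log_stage <- function(log, stage, t0) {
  elapsed <- round(as.numeric(Sys.time()) - t0, 2)
  inform(sprintf("[msapop] stage %-16s done in %.2fs", stage, elapsed))
  c(log, stats::setNames(list(elapsed), stage))
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  path
}

write_matrix_csv <- function(m, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's tables as
#' CSV under `output_dir` and a JSON manifest (versions, seeds, parameters,
#' per-stage wall time) sufficient to reproduce the run. A stage failure
#' halts with the stage name; outputs of completed stages are preserved.
#' Soil-dependent stages (Mantel suite, environmental scan, RDA) are skipped
#' with a logged reason when no soil table is available.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(unclass(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("msapop")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("inputs", "simulate"))],
    stages = list(), skipped = list(), outputs = character(0)
  )
  timing <- list()
  stage <- "load"
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timing <<- log_stage(timing, name, t0)
    out
  }

  dat <- run_stage("load", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(cfg$seed, 0)
      sp <- do.call(sim_params, sim_args)
      sim <- simulate_dataset(sp)
      list(aflp = sim$aflp, msap = sim$msap, soil = sim$soil, truth = sim$truth)
    } else {
      dialect <- cfg$inputs$dialect %||% "wide"
      list(
        aflp = read_band_matrix(cfg$inputs$aflp, dialect),
        msap = read_msap_pair(cfg$inputs$msap_hpa, cfg$inputs$msap_msp,
                              dialect),
        soil = if (!is.null(cfg$inputs$soil)) read_soil_table(cfg$inputs$soil),
        truth = NULL
      )
    }
  })
  has_soil <- !is.null(dat$soil)

  filtered <- run_stage("filter", {
    fl <- cfg$filters
    aflp <- apply_band_filters(dat$aflp, min_carriers = fl$min_carriers,
                               size_range = fl$size_range)
    write_stage_csv(attr(aflp, "filter_log"), cfg$output_dir,
                    "filter_log_aflp")
    aflp
  })

  scored <- run_stage("score", {
    m <- score_methylation_states(dat$msap)
    cls <- classify_loci(m, epsilon = cfg$epsilon)
    parts <- split_msap(dat$msap, m, cls)
    write_stage_csv(cls, cfg$output_dir, "msl_classification")
    write_stage_csv(methylation_state_profile(m, by = "habitat"),
                    cfg$output_dir, "methylation_state_profile")
    list(m = m, cls = cls, msl = parts$msl, nml = parts$nml)
  })

  run_stage("diversity", {
    div_aflp <- diversity_indices(filtered, grouping = "site")
    div_msl <- diversity_indices(scored$msl, grouping = "site")
    write_stage_csv(div_aflp, cfg$output_dir, "diversity_aflp")
    write_stage_csv(div_msl, cfg$output_dir, "diversity_msl")
    li_msl <- diversity_indices(scored$msl, grouping = "site", level = "locus")
    li_nml <- diversity_indices(scored$nml, grouping = "site", level = "locus")
    cmp <- rank_sum_compare(li_msl$shannon[li_msl$x0 > 0 & li_msl$x0 < 1],
                            li_nml$shannon[li_nml$x0 > 0 & li_nml$x0 < 1])
    write_stage_csv(cmp, cfg$output_dir, "shannon_msl_vs_nml")
  })

  dists <- run_stage("distances", {
    d_aflp <- squared_distance_matrix(filtered)
    d_msl <- squared_distance_matrix(scored$msl)
    write_matrix_csv(d_aflp, cfg$output_dir, "sq_distance_aflp")
    write_matrix_csv(d_msl, cfg$output_dir, "sq_distance_msl")
    list(aflp = d_aflp, msl = d_msl)
  })

  run_stage("amova", {
    for (nm in names(dists)) {
      one <- amova(dists[[nm]], filtered$samples$habitat,
                   n_perm = cfg$n_perm_amova, seed = derive_seed(cfg$seed, 11))
      two <- amova(dists[[nm]], filtered$samples$habitat,
                   subgroups = filtered$samples$site,
                   n_perm = cfg$n_perm_amova, seed = derive_seed(cfg$seed, 12))
      write_stage_csv(dplyr::bind_rows(
        dplyr::mutate(tidy(one), design = "one-level"),
        dplyr::mutate(tidy(two), design = "two-level")),
        cfg$output_dir, paste0("amova_", nm))
      write_stage_csv(dplyr::bind_rows(
        dplyr::mutate(one$phi, design = "one-level"),
        dplyr::mutate(two$phi, design = "two-level")),
        cfg$output_dir, paste0("amova_phi_", nm))
      pw <- pairwise_amova(dists[[nm]], filtered$samples$habitat,
                           n_perm = cfg$n_perm_amova,
                           seed = derive_seed(cfg$seed, 13))
      write_stage_csv(tidy(pw), cfg$output_dir, paste0("pairwise_amova_", nm))
    }
    lba <- locus_by_locus_amova(scored$msl, "habitat",
                                n_perm = cfg$n_perm_locus,
                                alpha = cfg$alpha_locus,
                                seed = derive_seed(cfg$seed, 14))
    write_stage_csv(lba, cfg$output_dir, "locus_amova_msl")
  })

  if (has_soil) {
    run_stage("mantel", {
      mt <- mantel(dists$aflp, dists$msl, n_perm = cfg$n_perm_mantel,
                   seed = derive_seed(cfg$seed, 21))
      rows <- list(dplyr::mutate(mt, comparison = "genetic~epigenetic",
                                 conditioning = ""))
      assign <- stats::setNames(filtered$samples$site,
                                filtered$samples$sample)
      for (v in setdiff(names(dat$soil), "site")) {
        sd_m <- soil_difference_matrix(dat$soil, v, assign)
        if (stats::sd(offdiag(sd_m)) == 0) next
        rows <- c(rows, list(
          dplyr::mutate(partial_mantel(dists$aflp, sd_m, dists$msl,
                                       n_perm = cfg$n_perm_partial,
                                       seed = derive_seed(cfg$seed, 22)),
                        comparison = paste0("genetic~", v),
                        conditioning = "epigenetic"),
          dplyr::mutate(partial_mantel(dists$msl, sd_m, dists$aflp,
                                       n_perm = cfg$n_perm_partial,
                                       seed = derive_seed(cfg$seed, 23)),
                        comparison = paste0("epigenetic~", v),
                        conditioning = "genetic")))
      }
      write_stage_csv(dplyr::bind_rows(rows), cfg$output_dir, "mantel_suite")
    })
  } else {
    manifest$skipped$mantel <- "no soil table"
    inform("[msapop] stage mantel skipped: no soil table")
  }

  run_stage("fdist", {
    scan <- fdist_scan(filtered, groups = cfg$grouping,
                       n_sim = cfg$n_sim_envelope,
                       quantiles = cfg$envelope_quantiles,
                       seed = derive_seed(cfg$seed, 31))
    write_stage_csv(scan$records, cfg$output_dir, "fdist_records")
    write_stage_csv(scan$envelope, cfg$output_dir, "fdist_envelope")
  })

  if (has_soil) {
    run_stage("env_scan", {
      es <- env_logistic_scan(filtered, dat$soil, alpha = cfg$alpha_env)
      write_stage_csv(es, cfg$output_dir, "env_scan")
    })
    run_stage("rda", {
      rr <- rda_forward(filtered, dat$soil, n_perm = 999,
                        seed = derive_seed(cfg$seed, 32))
      write_stage_csv(rr$global, cfg$output_dir, "rda_global")
      write_stage_csv(rr$selection, cfg$output_dir, "rda_selection")
    })
  } else {
    manifest$skipped$env_scan <- manifest$skipped$rda <- "no soil table"
    inform("[msapop] stages env_scan, rda skipped: no soil table")
  }

  run_stage("ordination", {
    for (nm in names(dists)) {
      pc <- pcoa(sqrt(dists[[nm]]))
      write_stage_csv(tidy(pc), cfg$output_dir, paste0("pcoa_", nm))
    }
    tree <- upgma(sqrt(dists$aflp), b = filtered, n_boot = cfg$n_boot_upgma,
                  seed = derive_seed(cfg$seed, 41))
    ape::write.tree(tree, file.path(cfg$output_dir, "upgma_aflp.nwk"))
  })

  manifest$stages <- timing
  manifest$outputs <- list.files(cfg$output_dir)
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
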