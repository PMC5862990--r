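#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with a
#' flat stage hierarchy:
#'
#' ```yaml
#' seed: 1
#' out_dir: results
#' stages: [simulate, estimate_dcp, window_scan]
#' simulate:
#'   preset: mall_like        # or ksi_like
#'   n_replicates: 10
#'   n_frames: 45000
#' estimate_dcp:
#'   reactant_manifest: results/reactant/manifest.csv
#'   ts_manifest: results/ts_analogue/manifest.csv
#'   method: moving_window
#'   window_ns: 70
#' window_scan:
#'   windows_ns: [5, 10, 20, 30, 40, 50, 60, 70, 80]
#' fit_kinetics:
#'   rate_file: rates.csv
#' partial_dcp:
#'   region: lid
#'   method: moving_window
#'   window_ns: 70
#' cluster:
#'   coords: traj.xyz
#'   atoms: atoms.csv
#'   method: kmeans           # or hierarchical
#'   k: 2
#'   epsilon: 2.1
#' rmsf:
#'   coords: traj.xyz
#'   atoms: atoms.csv
#'   window_ps: 10000
#' ```
#'
#' @param config path to a YAML file or a named list.
#' @return Validated configuration list (class `"pipeline_config"`), with
#'   attribute `"config_md5"` when read from a file.
#' @export
pipeline_config <- function(config) {
  md5 <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    md5 <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config must request at least one stage")
  }
  known <- c("simulate", "fit_kinetics", "estimate_dcp", "window_scan",
             "partial_dcp", "cluster", "rmsf")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  if (is.null(config$out_dir)) config$out_dir <- "."
  if (is.null(config$seed)) config$seed <- 1L
  structure(config, class = "pipeline_config", config_md5 = md5)
}

.stage_file <- function(cfg, stage, key) {
  path <- cfg[[stage]][[key]]
  if (is.null(path)) {
    stop("stage '", stage, "' needs config entry '", key, "'")
  }
  if (!file.exists(path)) {
    stop("stage '", stage, "': file referenced by '", key,
         "' not found: ", path)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`simulate`,
#' `fit_kinetics`, `estimate_dcp`, `window_scan`, `partial_dcp`, `cluster`,
#' `rmsf`), writing stage tables as delimited text under `out_dir` and a
#' JSON run report (`report.json`) with provenance (seed, package version,
#' config hash). The same configuration and seed give an identical report.
#' If a stage fails, the partial report written so far is saved before the
#' error is re-signalled.
#'
#' @param config a [pipeline_config()], YAML path or list.
#' @param seed optional seed override.
#' @param out_dir optional output directory override.
#' @param quiet suppress progress messages.
#' @return Invisibly, the run report (class `"run_report"`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S"),
                                           " [", ..1, "] ", ..2)
  prov <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("mmrtcp")),
    stages = cfg$stages)
  if (!is.na(attr(cfg, "config_md5"))) {
    prov$config_md5 <- attr(cfg, "config_md5")
  }
  report <- list(provenance = prov)
  set.seed(cfg$seed)

  order <- c("simulate", "fit_kinetics", "estimate_dcp", "window_scan",
             "partial_dcp", "cluster", "rmsf")
  stages <- order[order %in% cfg$stages]
  finish <- function() {
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  for (stage in stages) {
    say(stage, "running")
    result <- tryCatch(
      .run_stage(stage, cfg),
      error = function(e) {
        report$failed_stage <<- stage
        finish()
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    report[[stage]] <- result
  }
  finish()
  say("report", paste0("written to ", file.path(cfg$out_dir, "report.json")))
  invisible(structure(report, class = "run_report"))
}

.run_stage <- function(stage, cfg) {
  switch(stage,
    simulate = .stage_simulate(cfg),
    fit_kinetics = .stage_fit_kinetics(cfg),
    estimate_dcp = .stage_estimate_dcp(cfg),
    window_scan = .stage_window_scan(cfg),
    partial_dcp = .stage_partial_dcp(cfg),
    cluster = .stage_cluster(cfg),
    rmsf = .stage_rmsf(cfg))
}

.stage_simulate <- function(cfg) {
  p <- cfg$simulate
  if (is.null(p)) p <- list()
  preset <- if (is.null(p$preset)) "mall_like" else p$preset
  args <- p[setdiff(names(p), "preset")]
  args$seed <- cfg$seed
  exp <- switch(preset,
    mall_like = do.call(mall_like_experiment, args),
    ksi_like = do.call(ksi_like_experiment, args),
    stop("unknown simulate preset '", preset,
         "' (use 'mall_like' or 'ksi_like')"))
  rs_dir <- file.path(cfg$out_dir, "reactant")
  ts_dir <- file.path(cfg$out_dir, "ts_analogue")
  write_state_ensemble(exp$reactant, rs_dir)
  write_state_ensemble(exp$ts_analogue, ts_dir)
  jsonlite::write_json(exp$truth, file.path(cfg$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  # manifest paths are reported relative to out_dir so that identical runs
  # in different directories produce identical reports
  list(preset = preset,
       reactant_manifest = file.path("reactant", "manifest.csv"),
       ts_manifest = file.path("ts_analogue", "manifest.csv"),
       truth = exp$truth)
}

.stage_fit_kinetics <- function(cfg) {
  prof <- read_rate_profile(.stage_file(cfg, "fit_kinetics", "rate_file"))
  fit <- fit_mmrt(prof)
  write_fit_report(fit, file.path(cfg$out_dir, "mmrt_fit.json"))
  list(dCp = fit$params$dCp, dCp_sd = fit$param_sd[["dCp"]],
       dH_T0 = fit$params$dH_T0, dS_T0 = fit$params$dS_T0,
       T0 = fit$params$T0,
       topt = if (is.na(fit$topt)) "none" else fit$topt,
       residual_sd = fit$residual_sd, n_iter_T0 = fit$n_iter_T0)
}

.load_pair <- function(cfg, stage) {
  burn <- if (is.null(cfg[[stage]]$burn_in)) 0.1 else cfg[[stage]]$burn_in
  list(rs = read_state_ensemble(.stage_file(cfg, stage, "reactant_manifest"),
                                burn_in_fraction = burn),
       ts = read_state_ensemble(.stage_file(cfg, stage, "ts_manifest"),
                                burn_in_fraction = burn))
}

.win_frames <- function(ens, window_ns) {
  as.integer(round(window_ns * 1000 / ens$trajectories[[1L]]$time_step_ps))
}

.stage_estimate_dcp <- function(cfg) {
  p <- cfg$estimate_dcp
  pair <- .load_pair(cfg, "estimate_dcp")
  method <- if (is.null(p$method)) "moving_window" else p$method
  window <- if (!is.null(p$window_ns)) .win_frames(pair$rs, p$window_ns) else
    p$window
  rs <- state_variance(pair$rs, method = method, window = window,
                       stride = p$stride)
  ts <- state_variance(pair$ts, method = method, window = window,
                       stride = p$stride)
  est <- delta_cp(rs, ts)
  write_dcp_report(est, file.path(cfg$out_dir, "delta_cp.json"),
                   reactant = rs, ts_analogue = ts)
  list(delta_cp = est$value, sd = est$sd, method = est$method,
       temperature_K = est$temperature_K, n_replicates = est$n_replicates)
}

.stage_window_scan <- function(cfg) {
  p <- cfg$window_scan
  pair <- .load_pair(cfg, "window_scan")
  windows <- if (is.null(p$windows_ns)) c(5, 10, 20, 30, 40, 50, 60, 70, 80)
    else as.numeric(unlist(p$windows_ns))
  scan <- window_scan(pair$rs, pair$ts, windows_ns = windows,
                      stride_frac = if (is.null(p$stride_frac)) 0.1 else
                        p$stride_frac)
  utils::write.table(scan$scan, file.path(cfg$out_dir, "window_scan.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  list(scan = scan$scan,
       plateau_value = if (is.na(scan$plateau_value)) "none" else
         scan$plateau_value,
       plateau_range = scan$plateau_range)
}

.stage_partial_dcp <- function(cfg) {
  p <- cfg$partial_dcp
  pair <- .load_pair(cfg, "partial_dcp")
  if (is.null(p$region)) stop("stage 'partial_dcp' needs a 'region'")
  method <- if (is.null(p$method)) "moving_window" else p$method
  window <- if (!is.null(p$window_ns)) .win_frames(pair$rs, p$window_ns) else
    p$window
  est <- partial_cp(pair$rs, pair$ts, region = p$region, method = method,
                    window = window)
  list(region = est$region, delta_cp = est$value, sd = est$sd,
       method = est$method)
}

.load_traj <- function(cfg, stage) {
  p <- cfg[[stage]]
  coords <- .stage_file(cfg, stage, "coords")
  dt <- if (is.null(p$time_step_ps)) 10 else p$time_step_ps
  if (grepl("\\.pdb$", coords, ignore.case = TRUE)) {
    read_pdb_trajectory(coords, time_step_ps = dt)
  } else {
    read_xyz_frames(coords, .stage_file(cfg, stage, "atoms"),
                    time_step_ps = dt)
  }
}

.stage_cluster <- function(cfg) {
  p <- cfg$cluster
  traj <- .load_traj(cfg, "cluster")
  rmat <- pairwise_rmsd(traj, exclude_residues = p$exclude_residues)
  method <- if (is.null(p$method)) "kmeans" else p$method
  res <- switch(method,
    kmeans = kmeans_cluster(rmat, k = if (is.null(p$k)) 2L else p$k,
                            seed = cfg$seed),
    hierarchical = hierarchical_cluster(
      rmat, epsilon = if (is.null(p$epsilon)) 2.1 else p$epsilon),
    stop("unknown cluster method '", method, "'"))
  utils::write.table(
    data.frame(frame = seq_along(res$labels), cluster = res$labels),
    file.path(cfg$out_dir, "cluster_labels.csv"),
    sep = ",", row.names = FALSE, quote = FALSE)
  list(method = method, occupancy = res$occupancy,
       n_clusters = nrow(res$occupancy))
}

.stage_rmsf <- function(cfg) {
  p <- cfg$rmsf
  traj <- .load_traj(cfg, "rmsf")
  prof <- running_average_rmsf(
    traj, window_ps = if (is.null(p$window_ps)) 10000 else p$window_ps)
  utils::write.table(prof, file.path(cfg$out_dir, "rmsf.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  list(n_residues = nrow(prof), mean_rmsf = mean(prof$rmsf),
       max_rmsf = max(prof$rmsf))
}
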