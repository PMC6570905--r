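#' Run the inducer-sweep simulation from a config
#'
#' Orchestrates [sweep_inducer()] from a config list (typically parsed
#' from YAML, see Details) and writes `sweep.tsv` (long-format
#' distribution table), `summary.tsv` (per-concentration statistics) and
#' `metadata.json` into `outdir`.
#'
#' @details Config blocks: `rates` (arguments of [rate_params()], using
#'   `c_diff` for the diffusion rate; missing block is an error),
#'   `inducer` (`grid_ng_per_ml`, optional `volume_fl`), `simulation`
#'   (`t_end`, `burn_in`, `replicates`, `seed`, optional `n_max`,
#'   `method`, `coord`), `variant` (`unbinding_mode`). Numeric settings belong in
#'   the config, not in function flags.
#'
#' @param config config list or path to a YAML/JSON file.
#' @param outdir output directory (created if needed).
#' @return The [sweep_inducer()] result, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  cfg <- load_config(config)
  if (is.null(cfg$rates))
    stop("config error: missing 'rates' block", call. = FALSE)
  rates <- cfg$rates
  if (!is.null(cfg$variant$unbinding_mode))
    rates$unbinding_mode <- cfg$variant$unbinding_mode
  params <- do.call(rate_params, rates)
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  grid <- cfg$inducer$grid_ng_per_ml
  if (is.null(grid))
    stop("config error: missing 'inducer$grid_ng_per_ml'", call. = FALSE)
  sw <- sweep_inducer(
    params, inducer_grid = as.numeric(grid),
    replicates = sim$replicates %||% 1,
    seed = sim$seed %||% 1,
    method = sim$method %||% "ssa",
    t_end = sim$t_end %||% 5e5,
    burn_in = sim$burn_in %||% 5e4,
    n_max = if (is.null(sim$n_max)) 1500 else unlist(sim$n_max),
    coord = sim$coord %||% "total")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sw$table, file.path(outdir, "sweep.tsv"))
  write_tsv(sw$summary, file.path(outdir, "summary.tsv"))
  write_metadata(file.path(outdir, "metadata.json"), cfg,
                 sim$seed %||% 1)
  invisible(sw)
}

#' Generate synthetic data from a config
#'
#' Drives the synthetic-data module: writes `trajectories.tsv` with a
#' `truth.tsv` sidecar (hidden state per frame) and/or `snapshots.tsv`,
#' plus `metadata.json`.
#'
#' @details Config blocks: `trajectories` (arguments of
#'   [trajectory_gen_config()] except `model`, plus optional `hmm` list
#'   with `transition` (row-major length-4), `means`, `variances`);
#'   `snapshots` (arguments of [snapshot_gen_config()]); either block may
#'   be omitted. `seed` at the top level seeds both.
#'
#' @inheritParams run_simulate
#' @return List with the generated objects, invisibly.
#' @export
run_generate <- function(config, outdir) {
  cfg <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  seed <- cfg$seed %||% 1
  if (!is.null(cfg$trajectories)) {
    tc <- cfg$trajectories
    model <- if (!is.null(tc$hmm))
      two_state_hmm(matrix(unlist(tc$hmm$transition), 2, byrow = TRUE),
                    unlist(tc$hmm$means), unlist(tc$hmm$variances))
    else default_trajectory_hmm()
    gcfg <- trajectory_gen_config(
      n_trajectories = tc$n_trajectories %||% 163,
      frames_min = tc$frames_min %||% 40,
      frames_max = tc$frames_max %||% 60,
      dt = tc$dt %||% 5, model = model,
      seed = tc$seed %||% seed)
    g <- gen_trajectories(gcfg)
    write_trajectories(g$trajectories, file.path(outdir,
                                                 "trajectories.tsv"))
    truth <- do.call(rbind, Map(function(tr, st)
      data.frame(cell_id = tr$cell_id, t_min = tr$t_min,
                 state = c("low", "high")[st]),
      g$trajectories, g$truth))
    write_tsv(truth, file.path(outdir, "truth.tsv"))
    out$trajectories <- g
  }
  if (!is.null(cfg$snapshots)) {
    sc <- cfg$snapshots
    scfg <- snapshot_gen_config(
      atc_grid = as.numeric(sc$atc_grid %||%
                              seq(300, 1500, length.out = 7)),
      cells_per_level = sc$cells_per_level %||% 3000,
      mechanism = sc$mechanism %||% "hmm_mixture",
      seed = sc$seed %||% seed)
    snaps <- gen_snapshots(scfg)
    write_snapshots(snaps, file.path(outdir, "snapshots.tsv"))
    out$snapshots <- snaps
  }
  if (length(out) == 0)
    stop("config error: need a 'trajectories' or 'snapshots' block",
         call. = FALSE)
  write_metadata(file.path(outdir, "metadata.json"), cfg, seed)
  invisible(out)
}

#' Run the analysis pipeline from a config
#'
#' Fits the two-state HMM to trajectory data, decodes, estimates
#' residence times and occupancies, computes snapshot statistics, and
#' writes `hmm_model.json`, `segments.tsv`, `residence.tsv`, `stats.tsv`
#' (when snapshots are provided) and an aggregate `report.json` with the
#' fitted peak centres, variances, transition probabilities, occupancies,
#' residence-time brackets and fit-quality correlation.
#'
#' @details Config blocks: `analyze` with `trajectories` (TSV path) and
#'   optionally `snapshots` (TSV path), `restarts`, `seed`,
#'   `inhibition_threshold`. Either input may instead be generated
#'   in-memory by passing the objects directly via the `data` argument.
#'
#' @inheritParams run_simulate
#' @param data optional list with elements `trajectories` (list of
#'   [fluor_trajectory()]) and/or `snapshots`, bypassing file input.
#' @return List with `fit`, `segmentations`, `residence`, `weights`,
#'   `quality`, and (if snapshots) `stats`, invisibly.
#' @export
run_analyze <- function(config, outdir, data = NULL) {
  cfg <- load_config(config)
  an <- cfg$analyze %||% cfg
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- an$seed %||% 1

  trajectories <- data$trajectories
  if (is.null(trajectories)) {
    if (is.null(an$trajectories))
      stop("config error: missing 'analyze$trajectories'", call. = FALSE)
    trajectories <- read_trajectories(an$trajectories)
  }
  fit <- fit_hmm(trajectories, restarts = an$restarts %||% 10,
                 seed = seed)
  segs <- lapply(trajectories, decode, model = fit$model)
  res <- residence_times(segs)
  wts <- mixture_weights(fit$model, segs)
  qual <- hmm_fit_quality(trajectories, fit$model, seed = seed)

  write_hmm_json(fit, file.path(outdir, "hmm_model.json"))
  seg_tab <- do.call(rbind, lapply(segs, function(s)
    cbind(cell_id = s$cell_id, s$segments)))
  write_tsv(seg_tab, file.path(outdir, "segments.tsv"))
  write_tsv(res, file.path(outdir, "residence.tsv"))

  report <- list(
    emission_means = fit$model$means,
    emission_variances = fit$model$variances,
    transition = fit$model$transition,
    occupancy_stationary = wts$stationary,
    occupancy_empirical = wts$empirical,
    residence_minutes = res,
    fit_correlation = qual$correlation,
    loglik = fit$loglik, seed = seed)

  out <- list(fit = fit, segmentations = segs, residence = res,
              weights = wts, quality = qual)
  snaps <- data$snapshots
  if (is.null(snaps) && !is.null(an$snapshots))
    snaps <- read_snapshots(an$snapshots, min_cells = 1)
  if (!is.null(snaps)) {
    stats_tab <- snapshot_stats_table(snaps,
                                      threshold = an$inhibition_threshold)
    write_tsv(stats_tab, file.path(outdir, "stats.tsv"))
    report$snapshot_stats <- stats_tab
    out$stats <- stats_tab
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, matrix = "rowmajor", dataframe = "rows")
  write_metadata(file.path(outdir, "metadata.json"), cfg, seed)
  invisible(out)
}

#' @rdname run_analyze
#' @export
run_all <- function(config, outdir) {
  cfg <- load_config(config)
  gen <- run_generate(cfg, outdir)
  if (!is.null(cfg$rates)) run_simulate(cfg, outdir)
  run_analyze(cfg, outdir,
              data = list(trajectories = gen$trajectories$trajectories,
                          snapshots = gen$snapshots))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config error: need a list or a file path", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
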