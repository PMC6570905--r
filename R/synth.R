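#' Configuration for synthetic trajectory generation
#'
#' Defaults emulate the time-lapse study conditions this package targets:
#' 163 single-cell trajectories sampled every 5 minutes, lengths drawn
#' uniformly between 40 and 60 frames so the pooled count is about 8200
#' points, emissions from the reference two-state model
#' ([default_trajectory_hmm()]), and division marks at uniform 40-60 min
#' intervals (a typical E. coli cell cycle in these conditions).
#'
#' @param n_trajectories number of cells (default 163).
#' @param frames_min,frames_max trajectory length range in frames
#'   (default 40-60; set equal for fixed-length trajectories).
#' @param dt frame interval, minutes (default 5).
#' @param model generating [two_state_hmm()].
#' @param division_interval length-2 vector, uniform range of division
#'   intervals in minutes (default `c(40, 60)`).
#' @param seed integer root seed.
#' @return List of class `trajectory_gen_config`.
#' @export
trajectory_gen_config <- function(n_trajectories = 163, frames_min = 40,
                                  frames_max = 60, dt = 5,
                                  model = default_trajectory_hmm(),
                                  division_interval = c(40, 60),
                                  seed = 1) {
  stopifnot(n_trajectories >= 1, frames_min >= 2,
            frames_max >= frames_min, dt > 0,
            inherits(model, "two_state_hmm"),
            length(division_interval) == 2,
            division_interval[1] > 0,
            division_interval[2] >= division_interval[1])
  structure(list(n_trajectories = as.integer(n_trajectories),
                 frames_min = as.integer(frames_min),
                 frames_max = as.integer(frames_max), dt = dt,
                 model = model, division_interval = division_interval,
                 seed = as.integer(seed)),
            class = "trajectory_gen_config")
}

#' Generate synthetic single-cell trajectories
#'
#' Draws hidden state paths from the configured two-state Markov chain
#' (initial state from its stationary distribution), Gaussian emissions
#' on the log10 fluorescence scale, and division flags at random
#' intervals. Ground-truth state paths are retained so every downstream
#' estimator (fitting, decoding, residence times) can be scored. The
#' generator is bit-reproducible for a fixed seed.
#'
#' @param cfg a [trajectory_gen_config()].
#' @return List with `trajectories` (list of [fluor_trajectory()]) and
#'   `truth` (list of integer state paths, 1 = low, 2 = high).
#' @examples
#' g <- gen_trajectories(trajectory_gen_config(n_trajectories = 5, seed = 7))
#' length(g$trajectories)
#' @export
gen_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "trajectory_gen_config"))
  set.seed(cfg$seed)
  lens <- if (cfg$frames_max > cfg$frames_min)
    sample(cfg$frames_min:cfg$frames_max, cfg$n_trajectories,
           replace = TRUE)
  else rep(cfg$frames_min, cfg$n_trajectories)
  trajectories <- vector("list", cfg$n_trajectories)
  truth <- vector("list", cfg$n_trajectories)
  for (i in seq_len(cfg$n_trajectories)) {
    sim <- simulate_hmm(cfg$model, lens[i])
    t_total <- (lens[i] - 1) * cfg$dt
    div_t <- numeric(0)
    t_div <- runif(1, cfg$division_interval[1], cfg$division_interval[2])
    while (t_div < t_total) {
      div_t <- c(div_t, t_div)
      t_div <- t_div + runif(1, cfg$division_interval[1],
                             cfg$division_interval[2])
    }
    frames <- (seq_len(lens[i]) - 1) * cfg$dt
    division <- frames %in% (round(div_t / cfg$dt) * cfg$dt)
    trajectories[[i]] <- fluor_trajectory(sim$y, dt = cfg$dt,
                                          cell_id = sprintf("cell%03d", i),
                                          division = division)
    truth[[i]] <- sim$states
  }
  list(trajectories = trajectories, truth = truth)
}

#' Configuration for synthetic population snapshots
#'
#' Defaults emulate steady-state microscopy snapshots across an inducer
#' gradient: seven aTc levels from 300 to 1500 ng/mL with about 3000
#' cells per level. The `hmm_mixture` mechanism draws per-cell
#' fluorescence from a two-component log-normal mixture (Gaussian on
#' log10) whose component means rise and whose low-component weight
#' grows across the top of the grid, reproducing the observed
#' unimodal-low -> rising -> bimodal sequence; the `ssa` mechanism runs
#' the reaction-network sweep instead. The weight/mean schedule is an
#' explicit config table and qualitative by design.
#'
#' @param atc_grid inducer levels in ng/mL (validity range capped at 1900
#'   ng/mL, beyond which inducer toxicity makes snapshots meaningless).
#' @param cells_per_level cells per snapshot (default 3000).
#' @param mechanism `"hmm_mixture"` or `"ssa"`.
#' @param schedule data.frame with columns `atc`, `w_low`, `mu_low`,
#'   `mu_high`, `sd_low`, `sd_high` (log10 scale); `NULL` uses the built-in
#'   default schedule interpolated onto `atc_grid`.
#' @param params [rate_params()] used by the `ssa` mechanism.
#' @param seed integer root seed.
#' @return List of class `snapshot_gen_config`.
#' @export
snapshot_gen_config <- function(atc_grid = seq(300, 1500, length.out = 7),
                                cells_per_level = 3000,
                                mechanism = c("hmm_mixture", "ssa"),
                                schedule = NULL, params = NULL, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(atc_grid) >= 1, all(atc_grid >= 0),
            cells_per_level >= 1)
  if (any(atc_grid > 1900))
    stop("aTc grid exceeds the documented validity range (1900 ng/mL)",
         call. = FALSE)
  if (is.null(schedule)) schedule <- default_snapshot_schedule(atc_grid)
  structure(list(atc_grid = atc_grid,
                 cells_per_level = as.integer(cells_per_level),
                 mechanism = mechanism, schedule = schedule,
                 params = params, seed = as.integer(seed)),
            class = "snapshot_gen_config")
}

# Qualitative mixture schedule across the inducer gradient: expression
# rises with aTc; the population stays effectively unimodal until the two
# highest levels, where a separated low mode appears and gains weight.
default_snapshot_schedule <- function(atc_grid) {
  ref <- data.frame(
    atc    = c(300, 500, 700, 900, 1100, 1300, 1500),
    w_low  = c(1.00, 1.00, 0.95, 0.60, 0.30, 0.35, 0.45),
    mu_low = c(1.60, 1.75, 1.95, 2.20, 2.45, 2.55, 2.69),
    mu_high= c(2.00, 2.10, 2.30, 2.55, 2.80, 2.90, 2.933),
    sd_low = c(0.15, 0.15, 0.15, 0.15, 0.13, 0.08, 0.07),
    sd_high= c(0.15, 0.15, 0.15, 0.14, 0.12, 0.08, 0.07))
  out <- data.frame(atc = atc_grid)
  for (col in names(ref)[-1])
    out[[col]] <- stats::approx(ref$atc, ref[[col]], xout = atc_grid,
                                rule = 2)$y
  out
}

#' Generate steady-state population snapshots
#'
#' One [population_snapshot()] per inducer level, per the configured
#' mechanism (see [snapshot_gen_config()]).
#'
#' @param cfg a [snapshot_gen_config()].
#' @param ssa_control for the `ssa` mechanism: list with `t_end`,
#'   `burn_in`, `n_max` forwarded to [ssa_stationary()], and `scale`,
#'   `noise_cv` for the count-to-fluorescence mapping.
#' @return Named list of snapshots (names = aTc levels), with the
#'   generating schedule attached as attribute `schedule`.
#' @export
gen_snapshots <- function(cfg, ssa_control = list()) {
  stopifnot(inherits(cfg, "snapshot_gen_config"))
  set.seed(cfg$seed)
  out <- vector("list", length(cfg$atc_grid))
  names(out) <- as.character(cfg$atc_grid)
  if (cfg$mechanism == "hmm_mixture") {
    for (i in seq_along(cfg$atc_grid)) {
      sc <- cfg$schedule[i, ]
      comp <- runif(cfg$cells_per_level) < sc$w_low
      lx <- ifelse(comp, rnorm(cfg$cells_per_level, sc$mu_low, sc$sd_low),
                   rnorm(cfg$cells_per_level, sc$mu_high, sc$sd_high))
      out[[i]] <- population_snapshot(10^lx, cfg$atc_grid[i],
                                      min_cells = 1)
    }
  } else {
    ctl <- modifyList(list(t_end = 5e5, burn_in = 5e4, n_max = 1500,
                           scale = 1, noise_cv = 0.05), ssa_control)
    params <- cfg$params
    if (is.null(params)) params <- default_rate_params()
    for (i in seq_along(cfg$atc_grid)) {
      p <- params
      p$E_aTc <- atc_to_molecules(cfg$atc_grid[i])
      d <- ssa_stationary(system_state("A00", n_tetr = 10), p,
                          t_end = ctl$t_end, burn_in = ctl$burn_in,
                          coord = "total", n_max = ctl$n_max)
      counts <- sample(as.integer(names(d)), cfg$cells_per_level,
                       replace = TRUE, prob = as.numeric(d))
      fl <- pmax(counts, 0.5) * ctl$scale
      if (ctl$noise_cv > 0) {
        sdlog <- sqrt(log(1 + ctl$noise_cv^2))
        fl <- fl * rlnorm(length(fl), -sdlog^2 / 2, sdlog)
      }
      out[[i]] <- population_snapshot(fl, cfg$atc_grid[i], min_cells = 1)
    }
  }
  attr(out, "schedule") <- cfg$schedule
  out
}

#' Convert an SSA trajectory into a fluorescence trajectory
#'
#' Venus is fused to TetR, so free monomers, inducer-bound complexes and
#' DNA-bound monomers all fluoresce. The total TetR-Venus count is
#' sampled at fixed frame boundaries, scaled into fluorescence units, and
#' blurred with multiplicative log-normal measurement noise of the given
#' coefficient of variation; log10 values are returned.
#'
#' @param traj an `ssa_trajectory` from [ssa_simulate()].
#' @param frame_dt frame interval in minutes (default 5).
#' @param scale fluorescence units per molecule (> 0, default 1).
#' @param noise_cv measurement-noise CV (default 0.05; 0 disables noise).
#' @param seed integer seed for the noise draw.
#' @param cell_id identifier for the output trajectory.
#' @return A [fluor_trajectory()].
#' @export
ssa_to_fluorescence <- function(traj, frame_dt = 5, scale = 1,
                                noise_cv = 0.05, seed = NULL,
                                cell_id = "ssa_cell") {
  stopifnot(inherits(traj, "ssa_trajectory"), scale > 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  ev <- traj$events
  t_end <- max(ev$t)
  frames <- seq(0, t_end, by = frame_dt)
  if (length(frames) < 2)
    stop("trajectory shorter than two frames", call. = FALSE)
  idx <- findInterval(frames, ev$t)
  total <- ev$total_venus[idx]
  fl <- pmax(total, 0.5) * scale  # half-count floor keeps log finite
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fl <- fl * rlnorm(length(fl), -sdlog^2 / 2, sdlog)
  }
  fluor_trajectory(log10(fl), dt = frame_dt, cell_id = cell_id)
}
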