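#' Two-state Gaussian-emission hidden Markov model
#'
#' Container for the HMM used to segment single-cell log-fluorescence
#' trajectories into a low- and a high-expression state. State 1 is
#' always the low-mean state (`mu[1] < mu[2]`), which fixes the label
#' ordering across fits and makes all downstream quantities invariant to
#' label switching.
#'
#' @param transition 2x2 row-stochastic transition matrix (row/col order:
#'   low, high) over one frame interval.
#' @param means emission means on log10 fluorescence, `c(low, high)`.
#' @param variances emission variances (> 0), `c(low, high)`.
#' @param initial initial state distribution; default = stationary
#'   distribution of `transition`.
#' @return Object of class `two_state_hmm`.
#' @examples
#' default_trajectory_hmm()
#' @export
two_state_hmm <- function(transition, means, variances, initial = NULL) {
  transition <- as.matrix(transition)
  stopifnot(all(dim(transition) == c(2, 2)), length(means) == 2,
            length(variances) == 2)
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (any(transition < 0) || any(variances <= 0))
    stop("transition probabilities must be >= 0 and variances > 0",
         call. = FALSE)
  if (means[1] >= means[2]) {  # enforce low/high ordering
    transition <- transition[2:1, 2:1]
    means <- means[2:1]
    variances <- variances[2:1]
    if (!is.null(initial)) initial <- initial[2:1]
  }
  if (is.null(initial)) initial <- hmm_stationary(transition)
  initial <- initial / sum(initial)
  structure(list(transition = unname(transition), means = unname(means),
                 variances = unname(variances),
                 initial = unname(initial)),
            class = "two_state_hmm")
}

#' @export
print.two_state_hmm <- function(x, ...) {
  cat("two_state_hmm (state 1 = low, state 2 = high)\n")
  cat(sprintf("  means: %.3f / %.3f   variances: %.3f / %.3f\n",
              x$means[1], x$means[2], x$variances[1], x$variances[2]))
  cat(sprintf("  self-transitions: %.3f / %.3f\n",
              x$transition[1, 1], x$transition[2, 2]))
  invisible(x)
}

# stationary distribution of a 2x2 chain; NA-flag when reducible
hmm_stationary <- function(T) {
  a <- T[1, 2]; b <- T[2, 1]
  if (a + b == 0) return(c(NA_real_, NA_real_))  # reducible chain
  c(b, a) / (a + b)
}

#' Reference two-state model for a bimodal induction experiment
#'
#' The default generating model of the synthetic-trajectory module: a
#' two-state Gaussian HMM on log10 fluorescence representative of a
#' TetR-Venus self-repressor time-lapse at strong induction, with
#' low/high emission peaks at 2.690/2.933, peak variances 0.085/0.080,
#' high-state self-transition 0.963 (per 5-min frame), high-to-low
#' switching 0.037 and low-to-high switching 0.023.
#'
#' @return A [two_state_hmm()].
#' @export
default_trajectory_hmm <- function() {
  two_state_hmm(transition = rbind(c(0.977, 0.023), c(0.037, 0.963)),
                means = c(2.690, 2.933), variances = c(0.085, 0.080))
}

#' Single-cell fluorescence trajectory
#'
#' Evenly sampled log10 mean-fluorescence series for one tracked cell
#' lineage. Division frames are flagged but are not breakpoints: the HMM
#' runs across divisions, divisions are carried for reporting only.
#'
#' @param log10_fluor log10 fluorescence per frame (>= 2 finite values).
#' @param dt frame interval in minutes (default 5).
#' @param cell_id identifier.
#' @param division logical division flag per frame.
#' @param t_min explicit frame times; default `0, dt, 2*dt, ...`.
#' @return Object of class `fluor_trajectory`.
#' @export
fluor_trajectory <- function(log10_fluor, dt = 5, cell_id = "cell",
                             division = NULL, t_min = NULL) {
  y <- as.numeric(log10_fluor)
  if (length(y) < 2 || any(!is.finite(y)))
    stop("trajectory needs >= 2 finite frames", call. = FALSE)
  if (is.null(t_min)) t_min <- (seq_along(y) - 1) * dt
  if (length(t_min) != length(y) ||
      any(abs(diff(t_min) - dt) > 1e-8))
    stop("frame times must be uniform with spacing dt", call. = FALSE)
  if (is.null(division)) division <- rep(FALSE, length(y))
  structure(list(cell_id = cell_id, t_min = t_min, log10_fluor = y,
                 dt = dt, division = as.logical(division)),
            class = "fluor_trajectory")
}

pool_trajectories <- function(trajectories) {
  stopifnot(length(trajectories) > 0)
  y <- unlist(lapply(trajectories, `[[`, "log10_fluor"), use.names = FALSE)
  lengths <- vapply(trajectories, function(tr) length(tr$log10_fluor),
                    integer(1))
  list(y = y, lengths = lengths)
}

#' Fit the two-state HMM by Baum-Welch EM
#'
#' Maximum-likelihood fit of a shared two-state Gaussian HMM across a set
#' of trajectories. Initialisation: 2-means clustering of the pooled
#' emissions for the means/variances plus a sticky transition matrix
#' `[[0.9, 0.1], [0.1, 0.9]]`; `restarts` additional starts jitter that
#' initialisation. EM iterates until the relative log-likelihood change
#' drops below `tol` or `max_iter` iterations; the log-likelihood is
#' asserted non-decreasing on every step. A fit in which one state
#' captures fewer than 2 frames of expected occupancy is treated as
#' degenerate and the restart discarded; if every restart degenerates an
#' error is raised.
#'
#' @param trajectories list of [fluor_trajectory()] (pooled frames >= 50).
#' @param restarts number of EM restarts (default 10).
#' @param seed integer seed for the jittered restarts.
#' @param max_iter,tol EM stopping rule (default 500 iterations, relative
#'   tolerance 1e-8).
#' @return List with `model` (the best [two_state_hmm()]), `loglik`,
#'   `loglik_trace` of the winning restart, `per_trajectory_loglik`, and
#'   `n_iter`.
#' @export
fit_hmm <- function(trajectories, restarts = 10, seed = NULL,
                    max_iter = 500, tol = 1e-8) {
  pooled <- pool_trajectories(trajectories)
  if (length(pooled$y) < 50)
    stop("need >= 50 pooled frames to fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  km <- kmeans(pooled$y, centers = 2, nstart = 5)
  ord <- order(km$centers)
  mu0 <- as.numeric(km$centers[ord])
  v0 <- vapply(ord, function(k) {
    xs <- pooled$y[km$cluster == k]
    max(pop_var(xs), 1e-6)
  }, numeric(1))

  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- if (r == 1) mu0 else mu0 + rnorm(2, 0, 0.25 * abs(diff(mu0)))
    v <- if (r == 1) v0 else v0 * exp(rnorm(2, 0, 0.3))
    fit <- tryCatch(
      baum_welch(pooled$y, pooled$lengths, mu = sort(mu), v = v,
                 T0 = rbind(c(0.9, 0.1), c(0.1, 0.9)),
                 max_iter = max_iter, tol = tol),
      degenerate_fit = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop(paste("EM degenerated on every restart (a state captured < 2",
               "frames); the data may not support two states"),
         call. = FALSE)

  model <- two_state_hmm(best$T, best$mu, best$v, best$pi)
  per_tr <- hmm_loglik_per_trajectory(trajectories, model)
  list(model = model, loglik = best$loglik,
       loglik_trace = best$trace, per_trajectory_loglik = per_tr,
       n_iter = length(best$trace))
}

baum_welch <- function(y, lengths, mu, v, T0, max_iter, tol,
                       pi0 = c(0.5, 0.5)) {
  T <- T0; pi <- pi0
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- cpp_hmm_estep(y, as.integer(lengths), T, mu, v, pi)
    if (es$loglik < prev - 1e-6 * max(1, abs(prev)))
      stop("EM log-likelihood decreased (numerical failure)",
           call. = FALSE)
    trace <- c(trace, es$loglik)
    if (any(es$occ < 2))
      stop(structure(class = c("degenerate_fit", "error", "condition"),
                     list(message = "degenerate state", call = NULL)))
    # M-step
    T <- es$xi / rowSums(es$xi)
    pi <- es$gamma1 / sum(es$gamma1)
    mu <- es$sy / es$occ
    v <- pmax(es$syy / es$occ - mu^2, 1e-8)
    if (it > 1 && (es$loglik - prev) < tol * abs(prev)) break
    prev <- es$loglik
  }
  list(T = T, mu = mu, v = v, pi = pi, loglik = trace[length(trace)],
       trace = trace)
}

hmm_loglik_per_trajectory <- function(trajectories, model) {
  vapply(trajectories, function(tr) {
    cpp_hmm_estep(tr$log10_fluor, length(tr$log10_fluor),
                  model$transition, model$means, model$variances,
                  model$initial)$loglik
  }, numeric(1))
}

#' Viterbi segmentation of a trajectory
#'
#' Decodes the most likely state path and collapses it into contiguous
#' dwell segments. The first and last segments are flagged censored: the
#' trajectory starts/ends inside them, so their true dwell time is only
#' bounded from below.
#'
#' @param traj a [fluor_trajectory()].
#' @param model a fitted [two_state_hmm()].
#' @return Object of class `segmentation`: list with `states` (per-frame,
#'   `"low"`/`"high"`), `segments` data.frame (`state`, `start_frame`,
#'   `length`, `censored`), `dt`, `cell_id`.
#' @export
decode <- function(traj, model) {
  stopifnot(inherits(traj, "fluor_trajectory"),
            inherits(model, "two_state_hmm"))
  path <- cpp_viterbi(traj$log10_fluor, model$transition, model$means,
                      model$variances, model$initial) + 1L
  lab <- c("low", "high")[path]
  r <- rle(lab)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  segs <- data.frame(state = r$values, start_frame = starts,
                     length = r$lengths,
                     censored = seq_along(r$values) %in%
                       c(1L, length(r$values)))
  structure(list(states = lab, segments = segs, dt = traj$dt,
                 cell_id = traj$cell_id),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation of %s: %d frames, %d segments\n", x$cell_id,
              length(x$states), nrow(x$segments)))
  invisible(x)
}

#' Mean residence times of the expression states
#'
#' The mean residence (dwell) time of a state is the total time spent in
#' it divided by the number of exits from it. Because trajectories are
#' finite, the first and last dwell segments are censored; the estimate
#' is therefore bracketed by the two censoring conventions: excluding
#' censored segments (fewer, complete dwells) and including them
#' (additional time but no additional exits). Both brackets and the
#' exclude-censored point estimate are reported, emulating the
#' finite-trajectory ranges this statistic carries in practice. A state
#' with zero observed exits gets a lower-bound-only estimate (total
#' observed time in that state).
#'
#' @param segmentations list of [decode()] results.
#' @param dt frame interval in minutes; default taken from the first
#'   segmentation.
#' @return data.frame with one row per state: `state`, `mean_minutes`
#'   (exclude-censored convention), `lower`, `upper`, `n_exits`,
#'   `total_minutes`, `lower_bound_only`.
#' @export
residence_times <- function(segmentations, dt = NULL) {
  stopifnot(length(segmentations) > 0)
  if (is.null(dt)) dt <- segmentations[[1]]$dt
  segs <- do.call(rbind, lapply(segmentations, function(sg) {
    s <- sg$segments
    s$exits <- seq_len(nrow(s)) < nrow(s)  # the final segment never exits
    s
  }))
  out <- lapply(c("low", "high"), function(st) {
    s <- segs[segs$state == st, , drop = FALSE]
    if (nrow(s) == 0)
      return(data.frame(state = st, mean_minutes = NA_real_,
                        lower = NA_real_, upper = NA_real_, n_exits = 0L,
                        total_minutes = 0, lower_bound_only = TRUE))
    compl <- s[!s$censored, , drop = FALSE]   # complete dwells
    t_compl <- sum(compl$length) * dt
    t_all <- sum(s$length) * dt
    n_exits_compl <- nrow(compl)              # each complete dwell exits
    n_exits_all <- sum(s$exits)
    if (n_exits_compl == 0 && n_exits_all == 0)
      return(data.frame(state = st, mean_minutes = NA_real_,
                        lower = t_all, upper = NA_real_, n_exits = 0L,
                        total_minutes = t_all, lower_bound_only = TRUE))
    point <- if (n_exits_compl > 0) t_compl / n_exits_compl else NA_real_
    incl <- t_all / n_exits_all
    brackets <- range(c(point, incl), na.rm = TRUE)
    data.frame(state = st,
               mean_minutes = if (is.na(point)) incl else point,
               lower = brackets[1], upper = brackets[2],
               n_exits = n_exits_compl, total_minutes = t_all,
               lower_bound_only = FALSE)
  })
  do.call(rbind, out)
}

#' State occupancy: stationary and empirical mixture weights
#'
#' Returns both the stationary distribution of the fitted transition
#' matrix and the empirical frame-occupancy fractions of the decoded
#' paths. The two differ in finite samples and both are informative; for
#' a reducible (identity) transition matrix the stationary distribution
#' is undefined and flagged `NA` while the empirical occupancy is still
#' returned.
#'
#' @param model a [two_state_hmm()].
#' @param segmentations list of [decode()] results (optional; empirical
#'   occupancies are `NA` when absent).
#' @return List with `stationary = c(p_low, p_high)` and
#'   `empirical = c(p_low, p_high)`.
#' @examples
#' m <- default_trajectory_hmm()
#' mixture_weights(m)$stationary  # about 0.617 / 0.383
#' @export
mixture_weights <- function(model, segmentations = NULL) {
  stopifnot(inherits(model, "two_state_hmm"))
  st <- hmm_stationary(model$transition)
  emp <- c(NA_real_, NA_real_)
  if (!is.null(segmentations) && length(segmentations) > 0) {
    states <- unlist(lapply(segmentations, `[[`, "states"),
                     use.names = FALSE)
    emp <- c(mean(states == "low"), mean(states == "high"))
  }
  list(stationary = setNames(st, c("low", "high")),
       empirical = setNames(emp, c("low", "high")))
}

#' Goodness of fit of the HMM to the pooled intensity distribution
#'
#' Simulates surrogate trajectories from the fitted model, matched in
#' number and length to the data, and compares the pooled intensity
#' distributions by the Pearson correlation of the sorted pooled values
#' (a quantile-quantile agreement score; invariant to trajectory order).
#' Also returns the model's two-Gaussian mixture density for overlaying
#' on the data histogram.
#'
#' @param trajectories list of [fluor_trajectory()].
#' @param model a fitted [two_state_hmm()].
#' @param seed integer seed for the surrogate simulation.
#' @return List with `correlation`, `mixture_density` (function of log10
#'   fluorescence), and `surrogate` (pooled surrogate emissions).
#' @export
hmm_fit_quality <- function(trajectories, model, seed = NULL) {
  stopifnot(inherits(model, "two_state_hmm"))
  if (!is.null(seed)) set.seed(seed)
  pooled <- pool_trajectories(trajectories)
  # lengths are sorted so the score is invariant to trajectory order
  surr <- unlist(lapply(sort(pooled$lengths), function(n)
    simulate_hmm(model, n)$y), use.names = FALSE)
  qq_cor <- cor(sort(pooled$y), sort(surr))
  w <- hmm_stationary(model$transition)
  if (anyNA(w)) w <- c(0.5, 0.5)
  dens <- function(x)
    w[1] * stats::dnorm(x, model$means[1], sqrt(model$variances[1])) +
    w[2] * stats::dnorm(x, model$means[2], sqrt(model$variances[2]))
  list(correlation = qq_cor, mixture_density = dens, surrogate = surr)
}

# draw one state path + emissions from the model (internal workhorse)
simulate_hmm <- function(model, n_frames, init = NULL) {
  if (is.null(init)) {
    init <- hmm_stationary(model$transition)
    if (anyNA(init)) init <- model$initial
  }
  s <- integer(n_frames)
  s[1] <- sample.int(2, 1, prob = init)
  if (n_frames > 1)
    for (t in 2:n_frames)
      s[t] <- sample.int(2, 1, prob = model$transition[s[t - 1], ])
  y <- rnorm(n_frames, model$means[s], sqrt(model$variances[s]))
  list(states = s, y = y)
}

#' Export a fitted model as JSON
#'
#' Writes transition matrix, emission parameters, initial distribution
#' and log-likelihood to `hmm_model.json`.
#'
#' @param fit result of [fit_hmm()].
#' @param path output file.
#' @export
write_hmm_json <- function(fit, path) {
  m <- fit$model
  jsonlite::write_json(list(
    transition = m$transition, means = m$means, variances = m$variances,
    initial = m$initial, loglik = fit$loglik, n_iter = fit$n_iter,
    state_order = c("low", "high")), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
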