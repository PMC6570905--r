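#' Parameter-recovery benchmark for the two-state HMM
#'
#' Generate-and-refit experiment: draws synthetic trajectory sets from a
#' known two-state HMM ([default_trajectory_hmm()] unless overridden),
#' refits a fresh model to each replicate with [fit_hmm()], and reports
#' the per-replicate fitted parameters plus their medians. This is the
#' package's standard check that Baum-Welch recovers transition
#' probabilities and emission parameters at realistic trajectory numbers
#' and lengths.
#'
#' @param n_replicates number of generate-and-refit replicates
#'   (default 20).
#' @param seed integer root seed; replicate seeds are derived by counter.
#' @param cfg generating [trajectory_gen_config()] template; its `seed`
#'   field is replaced per replicate.
#' @param restarts EM restarts per fit.
#' @return List with `replicates` (data.frame, one row per replicate:
#'   `p_ll`, `p_lh`, `p_hl`, `p_hh`, `mu_low`, `mu_high`, `var_low`,
#'   `var_high`) and `median` (named vector of column medians).
#' @export
benchmark_hmm_recovery <- function(n_replicates = 20, seed = 1,
                                   cfg = trajectory_gen_config(),
                                   restarts = 10) {
  stopifnot(n_replicates >= 1)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- seed + 1000L * r
    g <- gen_trajectories(cfg_r)
    fit <- fit_hmm(g$trajectories, restarts = restarts,
                   seed = seed + 1000L * r + 500L)
    m <- fit$model
    rows[[r]] <- data.frame(
      p_ll = m$transition[1, 1], p_lh = m$transition[1, 2],
      p_hl = m$transition[2, 1], p_hh = m$transition[2, 2],
      mu_low = m$means[1], mu_high = m$means[2],
      var_low = m$variances[1], var_high = m$variances[2],
      loglik = fit$loglik)
  }
  reps <- do.call(rbind, rows)
  med <- vapply(reps, median, numeric(1))
  list(replicates = reps, median = med,
       n_frames = with(cfg, n_trajectories * mean(c(frames_min,
                                                    frames_max))))
}

#' Mixture-weight recovery benchmark
#'
#' Draws `n_values` emissions from a two-component Gaussian mixture with
#' the given component parameters and weights, refits the mixing weight
#' by EM ([fit_gaussian_mixture()] with the component shapes held fixed),
#' and reports per-replicate fitted weights and their medians. The
#' components are held at their generating values because under the
#' strong overlap of the two expression states (separation of the means
#' comparable to the component standard deviations) a free two-Gaussian
#' fit leaves the weight unidentified; in the analysis pipeline the
#' component shapes come from the HMM fit, where temporal persistence
#' identifies them.
#'
#' @param n_replicates replicates (default 20).
#' @param seed integer root seed.
#' @param weights generating weights `c(low, high)` (default the
#'   occupancy split of the reference trajectory model, 0.599/0.401).
#' @param means,variances generating component parameters, low first.
#' @param n_values sample size per replicate (default 8200).
#' @return List with `replicates` (data.frame `w_low`, `w_high`) and
#'   `median`.
#' @export
benchmark_mixture_recovery <- function(n_replicates = 20, seed = 1,
                                       weights = c(0.599, 0.401),
                                       means = c(2.690, 2.933),
                                       variances = c(0.085, 0.080),
                                       n_values = 8200) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, length(means) == 2)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + 1000L * r)
    comp <- 1L + (runif(n_values) >= weights[1])
    x <- rnorm(n_values, means[comp], sqrt(variances[comp]))
    fit <- fit_gaussian_mixture(
      x, components = list(means = means, variances = variances))
    rows[[r]] <- data.frame(w_low = fit$weights[1],
                            w_high = fit$weights[2])
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       median = vapply(reps, median, numeric(1)))
}
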