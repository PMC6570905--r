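#' Two-component Gaussian mixture fit by EM
#'
#' Static (no temporal structure) counterpart of the two-state HMM, used
#' for steady-state snapshot populations on the log10 fluorescence scale.
#'
#' Two modes of operation:
#' * **Free fit** (default): weights, means and variances all estimated,
#'   best of `restarts` initialisations. Beware that when the two
#'   components overlap strongly (separation comparable to the component
#'   standard deviations) the likelihood is almost flat along a ridge
#'   trading weight against shape, and the fitted weight of a free
#'   two-Gaussian mixture is effectively unidentified -- EM converges
#'   extremely slowly and different samples give wildly different
#'   weights. This is a property of the model, not of the optimiser.
#' * **Fixed components** (`components` supplied): only the mixing weight
#'   is estimated, with the component means/variances held at values
#'   identified elsewhere (typically by the two-state HMM, where temporal
#'   persistence pins the components down). This weight is
#'   well-identified even under heavy overlap and is the estimator used
#'   by the recovery benchmarks.
#'
#' @param values emissions on the fitted scale (e.g. log10 fluorescence).
#' @param components optional list with `means` and `variances` (low
#'   component first); when given, only the weight is fitted.
#' @param restarts EM restarts for the free fit (default 10).
#' @param seed integer seed (free fit only; the fixed-component fit is
#'   deterministic).
#' @param max_iter,tol stopping rule: absolute log-likelihood change
#'   below `tol` or `max_iter` iterations.
#' @return List with `weights`, `means`, `variances` (low component
#'   first), `loglik`, `n_iter`.
#' @examples
#' x <- c(rnorm(600, 0, 1), rnorm(400, 5, 1))
#' fit_gaussian_mixture(x, seed = 1)$weights      # about 0.6 / 0.4
#' @export
fit_gaussian_mixture <- function(values, components = NULL, restarts = 10,
                                 seed = NULL, max_iter = 200000,
                                 tol = 1e-10) {
  x <- as.numeric(values)
  stopifnot(length(x) >= 10, all(is.finite(x)))
  if (!is.null(components)) {
    stopifnot(length(components$means) == 2,
              length(components$variances) == 2,
              all(components$variances > 0))
    ord <- order(components$means)
    mu <- components$means[ord]
    v <- components$variances[ord]
    fit <- weight_em(x, mu, v, max_iter = max_iter)
    return(list(weights = c(fit$w, 1 - fit$w), means = mu, variances = v,
                loglik = fit$loglik, n_iter = fit$n_iter))
  }
  if (!is.null(seed)) set.seed(seed)
  med <- median(x)
  mu0 <- c(mean(x[x < med]), mean(x[x >= med]))
  v0 <- pmax(c(pop_var(x[x < med]), pop_var(x[x >= med])), 1e-8)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- if (r == 1) mu0 else mu0 + rnorm(2, 0, 0.25 * abs(diff(mu0)))
    v <- if (r == 1) v0 else v0 * exp(rnorm(2, 0, 0.3))
    fit <- cpp_gmm_em(x, c(0.5, 0.5), sort(mu), v, as.integer(max_iter),
                      tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  list(weights = best$w[ord], means = best$mu[ord],
       variances = best$v[ord], loglik = best$loglik,
       n_iter = best$n_iter)
}

# EM on the mixing weight alone; the component densities are constants,
# so each iteration is one posterior average
weight_em <- function(x, mu, v, w0 = 0.5, max_iter = 10000, tol = 1e-12) {
  d1 <- stats::dnorm(x, mu[1], sqrt(v[1]))
  d2 <- stats::dnorm(x, mu[2], sqrt(v[2]))
  w <- w0
  for (it in seq_len(max_iter)) {
    r <- w * d1 / (w * d1 + (1 - w) * d2)
    w_new <- mean(r)
    if (abs(w_new - w) < tol) { w <- w_new; break }
    w <- w_new
  }
  list(w = w, loglik = sum(log(w * d1 + (1 - w) * d2)), n_iter = it)
}
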