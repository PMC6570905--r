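test_that("free EM recovers a well-separated mixture", {
  set.seed(51)
  x <- c(rnorm(1200, 0, 0.5), rnorm(800, 4, 0.5))
  fit <- fit_gaussian_mixture(x, restarts = 3, seed = 52,
                              max_iter = 5000)
  expect_equal(fit$weights[1], 0.6, tolerance = 0.03)
  expect_equal(fit$means, c(0, 4), tolerance = 0.1)
  expect_equal(fit$variances, c(0.25, 0.25), tolerance = 0.05)
})

test_that("free EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(53)
  x <- c(rnorm(700, 1, 0.4), rnorm(500, 3.5, 0.6))
  fit <- fit_gaussian_mixture(x, restarts = 3, seed = 54,
                              max_iter = 20000)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_equal(fit$means, unname(mc$parameters$mean[ord]),
               tolerance = 0.02)
  expect_equal(fit$weights, mc$parameters$pro[ord], tolerance = 0.02)
})

test_that("fixed-component EM identifies the weight under heavy overlap", {
  # at the reference emission parameters the components overlap so much
  # that the free fit cannot pin the weight down; the fixed-component
  # weight remains identifiable
  set.seed(55)
  means <- c(2.690, 2.933); vars <- c(0.085, 0.080)
  comp <- 1L + (runif(8200) >= 0.599)
  x <- rnorm(8200, means[comp], sqrt(vars[comp]))
  fit <- fit_gaussian_mixture(x, components = list(means = means,
                                                   variances = vars))
  expect_equal(fit$weights[1], 0.599, tolerance = 0.05)
  expect_equal(fit$means, means)  # untouched
})

test_that("benchmark medians recover the generating weights", {
  r <- benchmark_mixture_recovery(n_replicates = 8, seed = 77)
  expect_lt(abs(r$median[["w_low"]] - 0.599), 0.03)
  expect_equal(r$median[["w_low"]] + r$median[["w_high"]], 1)
  expect_equal(nrow(r$replicates), 8)
})
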