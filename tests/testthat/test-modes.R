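test_that("unimodal and point-mass distributions give one mode", {
  m <- detect_modes(dpois(0:120, 50))
  expect_equal(m$n_modes, 1L)
  expect_equal(m$weights, 1)
  pm <- detect_modes(c(0, 0, 1, 0, 0))
  expect_equal(pm$n_modes, 1L)
  expect_equal(pm$locations, 2L)
  expect_equal(pm$weights, 1)
})

test_that("a balanced Poisson mixture splits into two equal modes", {
  mix <- 0.5 * dpois(0:160, 5) + 0.5 * dpois(0:160, 80)
  m <- detect_modes(mix)
  expect_equal(m$n_modes, 2L)
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 0.02)
  expect_lt(abs(m$locations[1] - 5), 3)
  expect_lt(abs(m$locations[2] - 80), 3)
  # weights follow the mixture proportions
  mix37 <- 0.3 * dpois(0:160, 5) + 0.7 * dpois(0:160, 80)
  m37 <- detect_modes(mix37)
  expect_equal(m37$weights, c(0.3, 0.7), tolerance = 0.02)
})

test_that("plateau maxima report the leftmost bin", {
  p <- c(0.1, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1)
  m <- detect_modes(p, smoothing_window = 1)
  expect_equal(m$locations, 1L)
})

test_that("sub-prominence ripples are not counted as modes", {
  base <- dnorm(0:200, 100, 20)
  ripple <- base * (1 + 0.02 * sin((0:200) / 3))
  m <- detect_modes(ripple, smoothing_window = 5)
  expect_equal(m$n_modes, 1L)
})

test_that("degenerate input errors", {
  expect_error(detect_modes(numeric(0)), "empty")
  expect_error(detect_modes(c(0, 0, 0)), "empty")
  expect_error(detect_modes(dpois(0:10, 2), smoothing_window = 4),
               "odd")
})
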