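test_that("birth-death limit is Poisson(g/k1) to solver precision", {
  d <- cme_stationary(birth_death_params(g = 2, k1 = 0.2),
                      n_max = c(tetr = 60, ta = 0, i = 0))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  tv <- 0.5 * sum(abs(as.numeric(d) - dpois(0:60, 10)))
  expect_lt(tv, 1e-8)
})

test_that("operator symmetry: A10 and A01 carry identical stationary mass", {
  d <- cme_stationary(small_system_params(),
                      n_max = c(tetr = 40, ta = 10, i = 10))
  joint <- attr(d, "joint")
  p10 <- sum(joint$p[joint$states$gene == 1])
  p01 <- sum(joint$p[joint$states$gene == 2])
  expect_equal(p10, p01, tolerance = 1e-9)
  expect_true(all(as.numeric(d) >= 0))
  expect_equal(sum(d), 1, tolerance = 1e-9)
})

test_that("too-small truncation raises a boundary-mass error", {
  expect_error(cme_stationary(birth_death_params(g = 2, k1 = 0.2),
                              n_max = c(tetr = 12, ta = 0, i = 0)),
               "truncation too small")
})

test_that("free and total marginals differ by the bound/complexed pools", {
  p <- small_system_params()
  d_free <- cme_stationary(p, n_max = c(tetr = 40, ta = 10, i = 10),
                           coord = "free")
  d_tot <- cme_stationary(p, n_max = c(tetr = 40, ta = 10, i = 10),
                          coord = "total")
  mean_free <- sum(as.numeric(names(d_free)) * d_free)
  mean_tot <- sum(as.numeric(names(d_tot)) * d_tot)
  joint <- attr(d_tot, "joint")
  extra <- sum(joint$p * (joint$states$ta +
                            c(0, 2, 2, 4)[joint$states$gene + 1L]))
  expect_equal(mean_tot, mean_free + extra, tolerance = 1e-9)
  expect_gt(mean_tot, mean_free)
})

test_that("SSA time-average agrees with the master equation", {
  # small fully-coupled system; ~1e6 SSA events
  p <- small_system_params()
  cme <- cme_stationary(p, n_max = c(tetr = 40, ta = 10, i = 10),
                        coord = "free")
  ssa <- ssa_stationary(system_state("A11", n_tetr = 4), p, t_end = 2.5e5,
                        burn_in = 5e3, seed = 17, coord = "free",
                        n_max = 40)
  expect_gt(attr(ssa, "n_events"), 5e5)
  tv <- 0.5 * sum(abs(as.numeric(ssa) - as.numeric(cme)))
  expect_lt(tv, 0.05)
})
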