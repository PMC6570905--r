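test_that("zero-horizon and replay contracts hold", {
  p <- default_rate_params()
  tr0 <- ssa_simulate(system_state("A11", n_tetr = 3), p, t_end = 0,
                      seed = 1)
  expect_equal(nrow(tr0$events), 1L)
  expect_equal(tr0$events$n_tetr, 3)
  a <- ssa_simulate(system_state("A11"), p, t_end = 200, seed = 99)
  b <- ssa_simulate(system_state("A11"), p, t_end = 200, seed = 99)
  expect_identical(a$events, b$events)
  expect_true(all(diff(a$events$t) > 0))
})

test_that("consecutive SSA states differ by one reaction stoichiometry", {
  p <- small_system_params()
  tr <- ssa_simulate(system_state("A11", n_tetr = 4), p, t_end = 500,
                     seed = 3)
  ev <- tr$events
  dn <- diff(ev$n_tetr); dta <- diff(ev$n_ta); di <- diff(ev$n_i)
  gene_change <- ev$gene[-1] != ev$gene[-nrow(ev)]
  legal <-
    (gene_change & dn == -2 & dta == 0 & di == 0) |  # operator binding
    (gene_change & dn == 2 & dta == 0 & di == 0) |   # operator unbinding
    (!gene_change & ((abs(dn) == 1 & dta == 0 & di == 0) |   # syn/deg
                     (dn == -1 & dta == 1 & di == -1) |      # association
                     (dn == 1 & dta == -1 & di == 1) |       # dissociation
                     (dn == 0 & dta == -1 & di == 0) |       # Ta decay
                     (dn == 0 & dta == 0 & abs(di) == 1)))   # aTc in/out
  expect_true(all(legal))
  expect_true(all(ev$n_tetr >= 0 & ev$n_ta >= 0 & ev$n_i >= 0))
})

test_that("birth-death limit reproduces the closed-form mean g/k1", {
  p <- birth_death_params(g = 5, k1 = 0.25)  # mean 20
  d <- ssa_stationary(system_state("A11", n_tetr = 20), p, t_end = 2e4,
                      burn_in = 1e3, seed = 5, coord = "free",
                      n_max = 100)
  mean_hat <- sum(as.numeric(names(d)) * as.numeric(d))
  expect_equal(mean_hat, 20, tolerance = 0.05)
})

test_that("an absorbing state terminates with a flag, not an error", {
  # pure decay: once every molecule is gone nothing can fire
  p <- rate_params(h = 0, f = 0, g11 = 0, g10 = 0, g01 = 0, g00 = 0,
                   k1 = 1, b = 0, a = 0, k2 = 0, c_diff = 0, E_aTc = 0)
  tr <- ssa_simulate(system_state("A11", n_tetr = 5), p, t_end = 1e6,
                     seed = 2)
  expect_equal(tr$status, "absorbing")
  expect_equal(tr$events$n_tetr[nrow(tr$events)], 0)
})

test_that("exactly one gene label is occupied along any trajectory", {
  p <- small_system_params()
  tr <- ssa_simulate(system_state("A00", n_tetr = 2), p, t_end = 300,
                     seed = 11)
  expect_true(all(tr$events$gene %in% gene_state_labels()))
})
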