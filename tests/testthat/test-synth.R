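test_that("trajectory generation is reproducible and well-formed", {
  cfg <- trajectory_gen_config(n_trajectories = 20, seed = 61)
  g1 <- gen_trajectories(cfg)
  g2 <- gen_trajectories(cfg)
  expect_identical(g1, g2)
  lens <- vapply(g1$trajectories, function(tr) length(tr$log10_fluor),
                 integer(1))
  expect_true(all(lens >= 40 & lens <= 60))
  expect_equal(lengths(g1$truth), lens)
  expect_true(all(vapply(g1$trajectories, function(tr) tr$dt == 5,
                         logical(1))))
})

test_that("near-zero emission noise pins emissions to the state means", {
  m <- two_state_hmm(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(2.0, 3.0),
                     c(1e-12, 1e-12))
  g <- gen_trajectories(trajectory_gen_config(n_trajectories = 5,
                                              model = m, seed = 62))
  for (i in seq_along(g$trajectories)) {
    expect_equal(g$trajectories[[i]]$log10_fluor,
                 m$means[g$truth[[i]]], tolerance = 1e-4)
  }
})

test_that("pooled emissions and occupancy match the generating model", {
  g <- gen_trajectories(trajectory_gen_config(seed = 63))
  pooled <- unlist(lapply(g$trajectories, `[[`, "log10_fluor"))
  # pooled moments match the stationary mixture of the two emission laws
  w <- c(0.617, 0.383)
  mix_mean <- sum(w * c(2.690, 2.933))
  mix_var <- sum(w * (c(0.085, 0.080) + c(2.690, 2.933)^2)) - mix_mean^2
  expect_equal(mean(pooled), mix_mean, tolerance = 0.01)
  expect_equal(var(pooled), mix_var, tolerance = 0.05)
  # long-run occupancy approaches the stationary split 0.617/0.383
  m <- default_trajectory_hmm()
  set.seed(64)
  sim <- autorep:::simulate_hmm(m, 2e5)
  expect_equal(mean(sim$states == 2), 0.023 / 0.060, tolerance = 0.05)
})

test_that("snapshot generator follows its weight schedule", {
  cfg <- snapshot_gen_config(cells_per_level = 2000, seed = 65)
  snaps <- gen_snapshots(cfg)
  expect_equal(length(snaps), 7)
  expect_true(all(vapply(snaps, function(s) s$n == 2000, logical(1))))
  # the two highest levels are bimodal
  for (lev in c("1300", "1500")) {
    s <- snapshot_summary(snaps[[lev]])
    expect_equal(s$n_modes, 2L)
  }
  # the lowest levels stay unimodal
  expect_equal(snapshot_summary(snaps[["300"]])$n_modes, 1L)
  # Fano rises into the bimodal region
  tab <- snapshot_stats_table(snaps)
  expect_gt(tab$fano[nrow(tab)], tab$fano[1])
  expect_gt(max(tab$fano), 10 * min(tab$fano))
})

test_that("snapshot config rejects out-of-range and unknown settings", {
  expect_error(snapshot_gen_config(atc_grid = c(300, 2000)),
               "validity range")
  expect_error(snapshot_gen_config(mechanism = "magic"))
})

test_that("SSA fluorescence conversion is exact without noise and
           scale-equivariant", {
  p <- birth_death_params(g = 5, k1 = 0.25)
  tr <- ssa_simulate(system_state("A11", n_tetr = 20), p, t_end = 300,
                     seed = 66)
  f0 <- ssa_to_fluorescence(tr, frame_dt = 5, scale = 1, noise_cv = 0)
  # frame values are log10 of the sampled totals (integers, or the
  # half-count floor at zero)
  back <- 10^f0$log10_fluor
  expect_true(all(abs(back - pmax(round(back), 0.5)) < 1e-9))
  f2 <- ssa_to_fluorescence(tr, frame_dt = 5, scale = 2, noise_cv = 0)
  expect_equal(f2$log10_fluor - f0$log10_fluor,
               rep(log10(2), length(f0$log10_fluor)))
  # higher synthesis gives brighter trajectories
  p_hi <- birth_death_params(g = 25, k1 = 0.25)
  tr_hi <- ssa_simulate(system_state("A11", n_tetr = 100), p_hi,
                        t_end = 300, seed = 66)
  f_hi <- ssa_to_fluorescence(tr_hi, frame_dt = 5, scale = 1,
                              noise_cv = 0)
  expect_gt(mean(f_hi$log10_fluor), mean(f0$log10_fluor))
})
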