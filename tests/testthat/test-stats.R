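test_that("Fano factor matches hand-computed values", {
  expect_equal(fano_factor(c(0, 2)), 1)          # mu 1, pop var 1
  expect_equal(fano_factor(rep(7, 10)), 0)       # constant vector
  x <- c(1, 2, 3, 4, 5)
  expect_equal(fano_factor(x), mean((x - 3)^2) / 3)
  expect_error(fano_factor(c(-2, 0, 2)), "mean <= 0")
  expect_error(fano_factor(3), ">= 2")
})

test_that("Fano scales linearly with units while CV is scale-free", {
  set.seed(42)
  x <- rpois(5000, 40)
  for (a in c(0.5, 3, 110)) {
    expect_equal(fano_factor(a * x) / a, fano_factor(x),
                 tolerance = 1e-12)
  }
  s1 <- snapshot_summary(x + 1)
  s2 <- snapshot_summary(7 * (x + 1))
  expect_equal(s1$cv, s2$cv, tolerance = 1e-12)
})

test_that("inhibition probability is the empirical CDF", {
  expect_equal(inhibition_probability(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(inhibition_probability(c(1, 2), 10), 1)
  expect_equal(inhibition_probability(c(1, 2), 0.5), 0)
  # strictly-below convention
  expect_equal(inhibition_probability(c(1, 2, 3), 2), 1 / 3)
  grid <- seq(0, 10, by = 0.25)
  curve <- inhibition_probability(rexp(500, 0.5), grid)
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve >= 0 & curve <= 1))
  expect_error(inhibition_probability(numeric(0), 1), "empty")
  expect_error(inhibition_probability(1:3, Inf), "finite")
})

test_that("a two-mean mixture is super-Poissonian while one Poisson is not", {
  set.seed(7)
  mix <- c(rpois(5000, 5), rpois(5000, 80))
  s_mix <- suppressWarnings(snapshot_summary(mix + 0.5))
  expect_gt(s_mix$fano, 10)
  single <- rpois(5000, 80)
  expect_equal(fano_factor(single), 1, tolerance = 0.1)
  # mixture Fano exceeds the weighted component Fano factors
  f_comp <- 0.5 * fano_factor(mix[1:5000]) +
    0.5 * fano_factor(mix[5001:10000])
  expect_gt(s_mix$fano, f_comp)
})

test_that("snapshot summary assembles all statistics coherently", {
  set.seed(8)
  x <- 10^c(rnorm(2000, 2.0, 0.1), rnorm(2000, 3.0, 0.1))
  s <- snapshot_summary(population_snapshot(x, 1500), threshold = 10^2.5)
  expect_equal(s$n, 4000)
  expect_equal(s$inhibition_p, 0.5, tolerance = 0.05)
  expect_equal(s$n_modes, 2L)
  expect_equal(s$mode_weights, c(0.5, 0.5), tolerance = 0.05)
  expect_lt(abs(s$mode_locations[1] - 2.0), 0.15)
  expect_lt(abs(s$mode_locations[2] - 3.0), 0.15)
  # degenerate single-value snapshot
  sd1 <- snapshot_summary(population_snapshot(rep(50, 3), min_cells = 1))
  expect_equal(sd1$fano, 0)
  expect_equal(sd1$n_modes, 1L)
})

test_that("valley threshold lands between well-separated modes", {
  set.seed(9)
  x <- 10^c(rnorm(3000, 2.0, 0.1), rnorm(2000, 3.0, 0.1))
  th <- valley_threshold(x)
  expect_gt(log10(th), 2.2)
  expect_lt(log10(th), 2.8)
  # unimodal fallback: the median
  u <- 10^rnorm(3000, 2.5, 0.1)
  expect_equal(valley_threshold(u), 10^median(log10(u)), tolerance = 0.05)
})

test_that("snapshot tables round-trip through TSV", {
  set.seed(10)
  snaps <- list(
    "300" = population_snapshot(10^rnorm(500, 2, 0.2), 300,
                                min_cells = 1),
    "1500" = population_snapshot(10^c(rnorm(250, 2, 0.1),
                                      rnorm(250, 3, 0.1)), 1500,
                                 min_cells = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snapshots(snaps, path)
  back <- read_snapshots(path, min_cells = 1)
  expect_equal(length(back), 2)
  expect_equal(back[["300"]]$values, snaps[["300"]]$values)
  tab <- snapshot_stats_table(back)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$aTc_ng_per_ml, c(300, 1500))
  expect_true(all(tab$fano > 0))
  expect_equal(tab$n_modes[2], 2L)
})
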