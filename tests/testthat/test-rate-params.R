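test_that("rate parameter invariants are enforced", {
  expect_error(rate_params(h = -1, f = 0, g11 = 1, g10 = 1, g01 = 1,
                           g00 = 1, k1 = 1, b = 0, a = 0, k2 = 0,
                           c_diff = 0, E_aTc = 0),
               "finite and >= 0")
  # synthesis ordering g11 >= g10 = g01 >= g00
  expect_error(rate_params(h = 0, f = 0, g11 = 1, g10 = 2, g01 = 2,
                           g00 = 1, k1 = 1, b = 0, a = 0, k2 = 0,
                           c_diff = 0, E_aTc = 0),
               "g11 >= g10")
  expect_error(rate_params(h = 0, f = 0, g11 = 3, g10 = 2, g01 = 1,
                           g00 = 1, k1 = 1, b = 0, a = 0, k2 = 0,
                           c_diff = 0, E_aTc = 0),
               "g10 == g01")
})

test_that("adiabaticity and affinity ratios are derived, not stored", {
  p <- default_rate_params()
  expect_identical(omega(p), p$f / p$k1)
  expect_identical(x_eq(p), p$f / p$h)
  expect_false(any(c("omega", "x_eq") %in% names(p)))
  # the default regime is non-adiabatic at zero inducer
  expect_lt(omega(p), 1)
})

test_that("aTc mass-to-molecule conversion is linear in concentration and volume", {
  m1 <- atc_to_molecules(1)
  expect_equal(atc_to_molecules(1500), 1500 * m1)
  expect_equal(atc_to_molecules(100, volume_fl = 2),
               2 * atc_to_molecules(100))
  # 1 ng/mL in 1 fL is on the order of one molecule
  expect_gt(m1, 1)
  expect_lt(m1, 2)
})

test_that("gene-state bookkeeping matches the operator occupancy", {
  expect_equal(bound_monomers(system_state("A11")), 0L)
  expect_equal(bound_monomers(system_state("A10")), 2L)
  expect_equal(bound_monomers(system_state("A00")), 4L)
  s <- system_state("A01", n_tetr = 3, n_ta = 2)
  expect_equal(total_venus(s), 3 + 2 + 2)
  expect_error(system_state("A11", n_tetr = -1), "non-negative")
  expect_error(system_state("A11", n_tetr = 1.5), "non-negative")
})
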