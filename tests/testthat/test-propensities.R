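p_ref <- default_rate_params()

test_that("operator binding follows the dimer rate law h*n*(n-1)/2", {
  a <- propensities(system_state("A11", n_tetr = 5), p_ref)
  expect_equal(unname(a[["bind_11_10"]]), 0.5 * p_ref$h * 5 * 4)
  expect_equal(a[["bind_11_10"]], a[["bind_11_01"]])  # two equal channels
  # a single monomer cannot form the dimer
  a1 <- propensities(system_state("A11", n_tetr = 1), p_ref)
  expect_equal(unname(a1[["bind_11_10"]] + a1[["bind_11_01"]]), 0)
  # binding channels out of A10/A01 target A00 only
  a10 <- propensities(system_state("A10", n_tetr = 4), p_ref)
  expect_equal(unname(a10[["bind_10_00"]]), 0.5 * p_ref$h * 4 * 3)
  expect_equal(unname(a10[["bind_11_10"]]), 0)
})

test_that("unbinding is linear in free TetR, or constant in the variant", {
  a <- propensities(system_state("A10", n_tetr = 3), p_ref)
  expect_equal(unname(a[["unbind_10_11"]]), 3 * p_ref$f)
  # no competitor monomer, no unbinding
  a0 <- propensities(system_state("A10", n_tetr = 0), p_ref)
  expect_equal(unname(a0[["unbind_10_11"]]), 0)
  # constant-unbinding variant uses the fixed reference scale at any n
  pc <- default_rate_params(unbinding_mode = "constant")
  for (n in c(0, 3, 50)) {
    ac <- propensities(system_state("A00", n_tetr = n), pc)
    expect_equal(unname(ac[["unbind_00_10"]]), pc$f * pc$n_ref)
  }
})

test_that("synthesis follows the gene state and housekeeping channels are mass-action", {
  s <- system_state("A00", n_tetr = 7, n_ta = 4, n_i = 6)
  a <- propensities(s, p_ref)
  expect_equal(unname(a[["synthesis"]]), p_ref$g00)
  expect_equal(unname(a[["degradation"]]), p_ref$k1 * 7)
  expect_equal(unname(a[["association"]]), p_ref$b * 7 * 6)
  expect_equal(unname(a[["dissociation"]]), p_ref$a * 4)
  expect_equal(unname(a[["complex_degradation"]]), p_ref$k2 * 4)
  expect_equal(unname(a[["atc_influx"]]), p_ref$c * p_ref$E_aTc)
  expect_equal(unname(a[["atc_efflux"]]), p_ref$c * 6)
  expect_true(all(a >= 0))
  expect_equal(unname(propensities(system_state("A11"),
                                   p_ref)[["synthesis"]]), p_ref$g11)
})
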