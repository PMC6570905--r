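ref_model <- default_trajectory_hmm()

test_that("model constructor enforces ordering and stochasticity", {
  # swapped input is relabelled so state 1 is the low-mean state
  m <- two_state_hmm(rbind(c(0.963, 0.037), c(0.023, 0.977)),
                     means = c(2.933, 2.690),
                     variances = c(0.080, 0.085))
  expect_equal(m$means, c(2.690, 2.933))
  expect_equal(m$transition, rbind(c(0.977, 0.023), c(0.037, 0.963)))
  expect_error(two_state_hmm(rbind(c(0.9, 0.2), c(0.1, 0.9)),
                             c(0, 1), c(1, 1)), "sum to 1")
  expect_error(two_state_hmm(diag(2), c(0, 1), c(1, 0)), "variances > 0")
})

test_that("stationary mixture weights solve pi T = pi", {
  # hand-solved: p_high = 0.023 / (0.023 + 0.037)
  w <- mixture_weights(ref_model)
  expect_equal(unname(w$stationary["high"]), 0.023 / 0.060,
               tolerance = 1e-12)
  expect_equal(sum(w$stationary), 1)
  # symmetric chain
  ms <- two_state_hmm(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0, 1), c(1, 1))
  expect_equal(unname(mixture_weights(ms)$stationary), c(0.5, 0.5))
  # reducible chain: stationary undefined, empirical still reported
  mi <- two_state_hmm(diag(2), c(0, 1), c(1, 1), initial = c(0.5, 0.5))
  segs <- list(segmentation_from_labels(rep("low", 10)))
  wi <- mixture_weights(mi, segs)
  expect_true(all(is.na(wi$stationary)))
  expect_equal(unname(wi$empirical), c(1, 0))
})

test_that("EM log-likelihood is monotone and the fit recovers the truth", {
  g <- gen_trajectories(trajectory_gen_config(seed = 21))
  fit <- fit_hmm(g$trajectories, restarts = 4, seed = 22)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
  m <- fit$model
  expect_lt(abs(m$transition[2, 2] - 0.963), 0.03)
  expect_lt(abs(m$transition[1, 2] - 0.023), 0.03)
  expect_lt(abs(m$means[1] - 2.690), 0.05)
  expect_lt(abs(m$means[2] - 2.933), 0.05)
  expect_lt(abs(m$variances[1] - 0.085), 0.03)
  expect_equal(length(fit$per_trajectory_loglik), 163)
  expect_equal(sum(fit$per_trajectory_loglik), fit$loglik,
               tolerance = 1e-6)
})

test_that("single-Gaussian data collapses the two states or errors", {
  set.seed(23)
  trajs <- lapply(1:10, function(i)
    fluor_trajectory(rnorm(60, 2.8, 0.05), cell_id = paste0("c", i)))
  res <- tryCatch(fit_hmm(trajs, restarts = 3, seed = 24),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "degenerate")
  } else {
    # no second state exists: fitted means collapse well inside the
    # noise scale (far from any genuine two-state separation)
    expect_lt(diff(res$model$means), 0.1)
  }
})

test_that("decoding separates well-separated noiseless states exactly", {
  states <- c(1, 1, 2, 2, 2, 1, 2, 1, 1, 2)
  m <- two_state_hmm(rbind(c(0.8, 0.2), c(0.2, 0.8)), c(0, 5),
                     c(0.01, 0.01))
  tr <- fluor_trajectory(m$means[states])
  seg <- decode(tr, m)
  expect_equal(seg$states, c("low", "high")[states])
  # segments tile the trajectory and alternate
  expect_equal(sum(seg$segments$length), 10)
  expect_true(all(seg$segments$state[-1] !=
                    seg$segments$state[-nrow(seg$segments)]))
  expect_true(seg$segments$censored[1])
  expect_true(seg$segments$censored[nrow(seg$segments)])
  # constant trajectory: one all-censored segment
  segc <- decode(fluor_trajectory(rep(0, 8)), m)
  expect_equal(nrow(segc$segments), 1)
  expect_true(all(segc$segments$censored))
})

test_that("decode accuracy at the reference parameters matches the
           posterior-oracle level", {
  # independent oracle (brute-force simulation at the fitted parameters)
  # puts mean frame-wise Viterbi accuracy near 0.89 at this overlap
  g <- gen_trajectories(trajectory_gen_config(n_trajectories = 60,
                                              seed = 25))
  segs <- lapply(g$trajectories, decode, model = ref_model)
  acc <- mean(unlist(Map(function(s, st) mean((s$states == "high") ==
                                                (st == 2)),
                         segs, g$truth)))
  expect_gt(acc, 0.85)
})

test_that("residence times follow the stated counting conventions", {
  # H,H,H,L,L,H at dt = 5: one complete L dwell of 2 frames
  seg <- segmentation_from_labels(c("high", "high", "high", "low", "low",
                                    "high"))
  rt <- residence_times(list(seg))
  low <- rt[rt$state == "low", ]
  expect_equal(low$mean_minutes, 10)
  expect_equal(low$n_exits, 1L)
  # high state: both segments censored; first exits, last does not
  high <- rt[rt$state == "high", ]
  expect_false(high$lower_bound_only)   # include-censored bound exists
  expect_equal(high$upper, 20 / 1)      # 4 frames x 5 min / 1 exit
  # single-state trajectory: lower bound only
  rt1 <- residence_times(list(segmentation_from_labels(rep("low", 6))))
  expect_true(rt1[rt1$state == "low", "lower_bound_only"])
  expect_equal(rt1[rt1$state == "low", "lower"], 30)
})

test_that("residence estimate converges to dt/(1-p_self) on long chains", {
  set.seed(26)
  m <- two_state_hmm(rbind(c(0.98, 0.02), c(0.05, 0.95)), c(0, 2),
                     c(0.01, 0.01))
  sim <- autorep:::simulate_hmm(m, 2e5)
  seg <- segmentation_from_labels(c("low", "high")[sim$states])
  rt <- residence_times(list(seg))
  expect_equal(rt[rt$state == "low", "mean_minutes"], 5 / 0.02,
               tolerance = 0.05)
  expect_equal(rt[rt$state == "high", "mean_minutes"], 5 / 0.05,
               tolerance = 0.05)
})

test_that("fit quality is near one for self-consistent data and is
           order-invariant", {
  g <- gen_trajectories(trajectory_gen_config(n_trajectories = 80,
                                              seed = 27))
  q <- hmm_fit_quality(g$trajectories, ref_model, seed = 28)
  expect_gt(q$correlation, 0.99)
  q2 <- hmm_fit_quality(rev(g$trajectories), ref_model, seed = 28)
  expect_equal(q2$correlation, q$correlation, tolerance = 1e-12)
  # a third mode degrades the agreement
  set.seed(29)
  tr3 <- c(g$trajectories[1:40],
           lapply(1:40, function(i)
             fluor_trajectory(rnorm(50, 4.2, 0.1),
                              cell_id = paste0("x", i))))
  q3 <- hmm_fit_quality(tr3, ref_model, seed = 28)
  expect_lt(q3$correlation, q$correlation - 0.01)
})

test_that("fitting is reproducible under a fixed seed", {
  g <- gen_trajectories(trajectory_gen_config(n_trajectories = 40,
                                              seed = 30))
  f1 <- fit_hmm(g$trajectories, restarts = 3, seed = 31)
  f2 <- fit_hmm(g$trajectories, restarts = 3, seed = 31)
  expect_identical(f1$model, f2$model)
})
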