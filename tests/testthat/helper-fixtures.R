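# shared fixtures, built in code at test time

# pure birth-death parameters: h = b = c = 0 reduces the network to
# synthesis/degradation of free TetR, whose stationary law is Poisson(g/k1)
birth_death_params <- function(g = 2, k1 = 0.2) {
  rate_params(h = 0, f = 0, g11 = g, g10 = g, g01 = g, g00 = g, k1 = k1,
              b = 0, a = 0, k2 = 0.1, c_diff = 0, E_aTc = 0)
}

# small fully-coupled system kept solvable by the master equation
small_system_params <- function(unbinding_mode = "concentration_dependent") {
  rate_params(h = 0.02, f = 0.1, g11 = 1.5, g10 = 0.1, g01 = 0.1,
              g00 = 0.1, k1 = 0.1, b = 0.02, a = 0.2, k2 = 0.05,
              c_diff = 0.2, E_aTc = 1.2, unbinding_mode = unbinding_mode,
              n_ref = 5)
}

# deterministic two-state trajectories with hand-chosen states
trajectory_from_states <- function(states, model = default_trajectory_hmm(),
                                   noise_sd = 0, dt = 5, cell_id = "fix") {
  y <- model$means[states]
  if (noise_sd > 0) y <- y + rnorm(length(states), 0, noise_sd)
  fluor_trajectory(y, dt = dt, cell_id = cell_id)
}

tv_dist_num <- function(a, b) autorep:::tv_distance(as.numeric(a),
                                                    as.numeric(b))

# replicate-averaged SSA stationary distribution over free TetR
avg_ssa_dist <- function(params, t_end, seed, reps = 2, n_max = 400) {
  acc <- 0
  for (r in seq_len(reps)) {
    d <- ssa_stationary(system_state("A00", n_tetr = 2), params,
                        t_end = t_end, burn_in = t_end / 10,
                        seed = seed + 31L * r, coord = "free",
                        n_max = n_max)
    acc <- acc + as.numeric(d)
  }
  acc / reps
}

# segmentation object built directly from a label run, bypassing decode
segmentation_from_labels <- function(labels, dt = 5, cell_id = "fix") {
  r <- rle(labels)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  segs <- data.frame(state = r$values, start_frame = starts,
                     length = r$lengths,
                     censored = seq_along(r$values) %in%
                       c(1L, length(r$values)))
  structure(list(states = labels, segments = segs, dt = dt,
                 cell_id = cell_id), class = "segmentation")
}
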