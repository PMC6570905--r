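#' Exact stochastic simulation of the self-repressor circuit
#'
#' Gillespie direct-method simulation of the full reaction network (gene
#' state, free TetR, TetR-aTc complex, internal aTc). The same seed and
#' parameters always reproduce the identical event list. If every
#' propensity vanishes before `t_end` the trajectory stops at the
#' absorbing state and is flagged (`status = "absorbing"`), which is a
#' legitimate outcome, not an error.
#'
#' @param init initial [system_state()].
#' @param params [rate_params()].
#' @param t_end simulation horizon in minutes (>= 0).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param max_events cap on the number of recorded reaction events; the
#'   run is flagged `status = "max_events"` if reached.
#' @return An `ssa_trajectory`: list with `events` (data.frame `t`, `gene`,
#'   `n_tetr`, `n_ta`, `n_i`, `total_venus`), `status`, `seed`, `params`.
#' @examples
#' p <- default_rate_params()
#' tr <- ssa_simulate(system_state("A11"), p, t_end = 100, seed = 1)
#' tail(tr$events)
#' @export
ssa_simulate <- function(init, params, t_end, seed = NULL,
                         max_events = 1e6) {
  stopifnot(inherits(init, "system_state"), inherits(params, "rate_params"))
  if (!is.numeric(t_end) || t_end < 0)
    stop("t_end must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa_events(gene_index(init$gene), init$n_tetr, init$n_ta,
                        init$n_i, params_vector(params), t_end, max_events)
  gene <- gene_state_labels()[res$gene + 1L]
  bound <- c(A11 = 0, A10 = 2, A01 = 2, A00 = 4)[gene]
  events <- data.frame(t = res$t, gene = gene, n_tetr = res$n_tetr,
                       n_ta = res$n_ta, n_i = res$n_i,
                       total_venus = res$n_tetr + res$n_ta + unname(bound),
                       row.names = NULL)
  structure(list(events = events, status = res$status, seed = seed,
                 params = params),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("ssa_trajectory: %d events over %.1f min (status: %s)\n",
              nrow(x$events) - 1L, max(x$events$t), x$status))
  invisible(x)
}

#' Stationary distribution estimated by SSA time-averaging
#'
#' Runs one long Gillespie trajectory and accumulates the time-weighted
#' occupancy of a molecular-count coordinate after a burn-in period,
#' giving a Monte-Carlo estimate of the stationary distribution.
#'
#' @inheritParams ssa_simulate
#' @param burn_in time (minutes) discarded before accumulation starts.
#' @param coord `"free"` (free TetR monomers) or `"total"` (all fluorescent
#'   TetR-Venus: free + complexed + DNA-bound).
#' @param n_max histogram truncation; counts above are pooled into the top
#'   bin.
#' @return A [stationary_distribution()] with attribute `n_events`.
#' @export
ssa_stationary <- function(init, params, t_end, burn_in = 0, seed = NULL,
                           coord = c("free", "total"), n_max = 1500) {
  coord <- match.arg(coord)
  stopifnot(inherits(init, "system_state"), inherits(params, "rate_params"),
            t_end > burn_in)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa_histogram(gene_index(init$gene), init$n_tetr, init$n_ta,
                           init$n_i, params_vector(params), t_end, burn_in,
                           match(coord, c("free", "total")) - 1L, n_max)
  d <- stationary_distribution(res$p, coord = coord)
  attr(d, "n_events") <- res$n_events
  attr(d, "status") <- res$status
  d
}

#' Probability distribution over a molecular count
#'
#' Container for a (stationary) probability mass function over a protein
#' copy-number coordinate, indexed from zero. Normalised on construction;
#' construction fails if the input is not within 1e-9 of unit mass unless
#' `renormalize = TRUE`.
#'
#' @param p numeric vector of masses for counts `0:(length(p)-1)`.
#' @param coord which coordinate the distribution describes.
#' @param renormalize divide by the total mass instead of insisting it be 1.
#' @return Object of class `stationary_distribution`: numeric vector with
#'   names `0:(n-1)` and attribute `coord`.
#' @export
stationary_distribution <- function(p, coord = "free", renormalize = TRUE) {
  p <- as.numeric(p)
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0))
    stop("distribution must be non-empty, finite and non-negative",
         call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("distribution has zero total mass", call. = FALSE)
  if (renormalize) p <- p / s
  else if (abs(s - 1) > 1e-9)
    stop("distribution mass differs from 1 by more than 1e-9", call. = FALSE)
  structure(setNames(p, 0:(length(p) - 1L)), coord = coord,
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  m <- sum(as.numeric(names(x)) * x)
  cat(sprintf(
    "stationary_distribution over %s TetR count: support 0..%d, mean %.2f\n",
    attr(x, "coord"), length(x) - 1L, m))
  invisible(x)
}

# total-variation distance between two count distributions (padded)
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}
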