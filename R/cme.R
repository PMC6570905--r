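#' Stationary solution of the truncated chemical master equation
#'
#' Builds the generator of the full jump process on the truncated state
#' space (gene state x free TetR x Ta complex x internal aTc) and solves
#' for its stationary distribution (the null left eigenvector, computed by
#' one sparse linear solve). Reactions that would leave the truncation box
#' are dropped (reflecting boundary); the probability mass sitting on the
#' truncation boundary is measured afterwards and must stay below
#' `boundary_tol`, otherwise the truncation is declared too small.
#'
#' Intended as a brute-force exact reference for small systems; the state
#' space grows as `4 * prod(n_max + 1)`, so keep the per-species bounds
#' modest (a few hundred thousand states at most).
#'
#' @param params [rate_params()].
#' @param n_max named integer vector `c(tetr=, ta=, i=)` giving the
#'   truncation bound of each molecular species (a single number is
#'   recycled to all three). Use 0 for species that stay empty (e.g. `ta`
#'   and `i` when `b = c = 0`).
#' @param coord marginal to return: `"free"` TetR or `"total"` TetR-Venus.
#' @param boundary_tol maximum tolerated stationary mass on the truncation
#'   boundary of any dynamic species (default 1e-6).
#' @return A [stationary_distribution()] over the requested coordinate,
#'   with attributes `boundary_mass` and `joint` (the full joint
#'   probability vector with its state index data.frame).
#' @examples
#' # pure birth-death limit: h = b = c = 0 gives Poisson(g/k1)
#' p <- rate_params(h = 0, f = 0, g11 = 2, g10 = 2, g01 = 2, g00 = 2,
#'                  k1 = 0.2, b = 0, a = 0, k2 = 0.1, c_diff = 0, E_aTc = 0)
#' d <- cme_stationary(p, n_max = c(tetr = 60, ta = 0, i = 0))
#' sum(d)  # 1
#' @export
cme_stationary <- function(params, n_max, coord = c("free", "total"),
                           boundary_tol = 1e-6) {
  coord <- match.arg(coord)
  stopifnot(inherits(params, "rate_params"))
  if (is.list(n_max)) n_max <- unlist(n_max)
  if (is.null(names(n_max))) {
    n_max <- if (length(n_max) == 1) c(tetr = n_max, ta = n_max, i = n_max)
             else setNames(n_max, c("tetr", "ta", "i"))
  }
  N1 <- as.integer(n_max[["tetr"]]); N2 <- as.integer(n_max[["ta"]])
  N3 <- as.integer(n_max[["i"]])
  stopifnot(N1 >= 0, N2 >= 0, N3 >= 0)

  states <- expand.grid(gene = 0:3, n = 0:N1, ta = 0:N2, i = 0:N3,
                        KEEP.OUT.ATTRS = FALSE)
  idx <- function(gene, n, ta, i)
    1L + gene + 4L * (n + (N1 + 1L) * (ta + (N2 + 1L) * i))
  ns <- nrow(states)
  g_rates <- c(params$g11, params$g10, params$g01, params$g00)
  unb_rate <- if (params$unbinding_mode == "constant")
    rep(params$f * params$n_ref, ns) else params$f * states$n
  bind_rate <- 0.5 * params$h * states$n * (states$n - 1)

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(ok, gene_to, dn, dta, di, r) {
    ok <- ok & r > 0 &
      states$n + dn >= 0 & states$n + dn <= N1 &
      states$ta + dta >= 0 & states$ta + dta <= N2 &
      states$i + di >= 0 & states$i + di <= N3
    if (!any(ok)) return(invisible())
    g2 <- if (is.null(gene_to)) states$gene[ok] else gene_to
    from <<- c(from, which(ok))
    to <<- c(to, idx(g2, states$n[ok] + dn, states$ta[ok] + dta,
                     states$i[ok] + di))
    rate <<- c(rate, r[ok])
  }
  # operator binding (consumes a dimer = 2 free monomers)
  add(states$gene == 0 & states$n >= 2, 1L, -2L, 0L, 0L, bind_rate)
  add(states$gene == 0 & states$n >= 2, 2L, -2L, 0L, 0L, bind_rate)
  add(states$gene == 1 & states$n >= 2, 3L, -2L, 0L, 0L, bind_rate)
  add(states$gene == 2 & states$n >= 2, 3L, -2L, 0L, 0L, bind_rate)
  # unbinding (net +2 free monomers); the competitor requirement n >= 1
  # is implied by f*n under concentration-dependent unbinding
  can_unb <- if (params$unbinding_mode == "constant") rep(TRUE, ns)
             else states$n >= 1
  add(states$gene == 1 & can_unb, 0L, 2L, 0L, 0L, unb_rate)
  add(states$gene == 2 & can_unb, 0L, 2L, 0L, 0L, unb_rate)
  add(states$gene == 3 & can_unb, 1L, 2L, 0L, 0L, unb_rate)
  add(states$gene == 3 & can_unb, 2L, 2L, 0L, 0L, unb_rate)
  # synthesis / degradation
  add(rep(TRUE, ns), NULL, 1L, 0L, 0L, g_rates[states$gene + 1L])
  add(rep(TRUE, ns), NULL, -1L, 0L, 0L, params$k1 * states$n)
  # inducer sequestration
  add(rep(TRUE, ns), NULL, -1L, 1L, -1L, params$b * states$n * states$i)
  add(rep(TRUE, ns), NULL, 1L, -1L, 1L, params$a * states$ta)
  add(rep(TRUE, ns), NULL, 0L, -1L, 0L, params$k2 * states$ta)
  add(rep(TRUE, ns), NULL, 0L, 0L, 1L, rep(params$c * params$E_aTc, ns))
  add(rep(TRUE, ns), NULL, 0L, 0L, -1L, params$c * states$i)

  exit <- vapply(split(rate, from), sum, numeric(1))
  diag_q <- numeric(ns)
  diag_q[as.integer(names(exit))] <- -exit
  if (ns <= 5000) {
    # direct sparse solve: fix pi[1] = 1, solve the reduced balance
    # system, renormalise (keeps the factorisation sparse)
    Q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                              dims = c(ns, ns))
    Matrix::diag(Q) <- diag_q
    A <- Matrix::t(Q)
    x <- Matrix::solve(A[-1L, -1L], -A[-1L, 1L, drop = FALSE])
    pi_hat <- c(1, as.numeric(x))
  } else {
    # uniformized power iteration (compiled); exact enough for the
    # distribution-level comparisons large systems are used for
    lambda <- 1.05 * max(exit)
    pw <- cpp_power_stationary(from - 1L, to - 1L, rate, diag_q,
                               lambda, 300000L, 1e-12, 200L)
    if (pw$delta >= 1e-12)
      warning(sprintf(
        "power iteration stopped at L1 change %.2e after %d iterations",
        pw$delta, pw$iterations), call. = FALSE)
    pi_hat <- pw$p
  }
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0))
    stop("master-equation solve produced negative probabilities",
         call. = FALSE)
  pi_hat <- pi_hat / sum(pi_hat)

  # boundary mass of every species whose box is non-trivial
  bmass <- 0
  if (N1 > 0) bmass <- max(bmass, sum(pi_hat[states$n == N1]))
  if (N2 > 0) bmass <- max(bmass, sum(pi_hat[states$ta == N2]))
  if (N3 > 0) bmass <- max(bmass, sum(pi_hat[states$i == N3]))
  if (bmass >= boundary_tol)
    stop(sprintf(
      "truncation too small: boundary mass %.3g >= %.3g; enlarge n_max",
      bmass, boundary_tol), call. = FALSE)

  val <- if (coord == "free") states$n else {
    bound <- c(0L, 2L, 2L, 4L)[states$gene + 1L]
    states$n + states$ta + bound
  }
  marg <- vapply(0:max(val), function(v) sum(pi_hat[val == v]), numeric(1))
  d <- stationary_distribution(marg, coord = coord)
  attr(d, "boundary_mass") <- bmass
  attr(d, "joint") <- list(p = pi_hat, states = states)
  d
}
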