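#' Reaction propensities of the self-repressor network
#'
#' Evaluates the propensity of every reaction channel at a given state.
#' Channels, in fixed order: four operator-binding channels (two out of
#' `A11`, one each out of `A10`/`A01`, each `h*n*(n-1)/2` where `n` is the
#' free TetR count); four unbinding channels (`f*n` under
#' concentration-dependent unbinding, or the constant `f*n_ref`;
#' unbinding releases the bound dimer for a net gain of two free
#' monomers); synthesis `g_ij` for the current gene state; degradation
#' `k1*n`; TetR-aTc association `b*n*n_i`; complex dissociation `a*n_ta`;
#' complex degradation `k2*n_ta`; aTc influx `c*E_aTc`; aTc efflux
#' `c*n_i`. Channels not enabled in the current gene state have
#' propensity zero.
#'
#' @param state a [system_state()].
#' @param params a [rate_params()].
#' @return Named numeric vector of 15 non-negative propensities (per
#'   minute).
#' @examples
#' p <- default_rate_params()
#' propensities(system_state("A11", n_tetr = 5), p)[["bind_11_10"]]
#' # = 0.5 * h * 5 * 4
#' @export
propensities <- function(state, params) {
  stopifnot(inherits(state, "system_state"), inherits(params, "rate_params"))
  a <- cpp_propensities(gene_index(state$gene), state$n_tetr, state$n_ta,
                        state$n_i, params_vector(params))
  names(a) <- channel_names()
  if (any(a < 0) || any(!is.finite(a)))
    stop("invalid state: negative or non-finite propensity", call. = FALSE)
  a
}

channel_names <- function() {
  c("bind_11_10", "bind_11_01", "bind_10_00", "bind_01_00",
    "unbind_10_11", "unbind_01_11", "unbind_00_10", "unbind_00_01",
    "synthesis", "degradation", "association", "dissociation",
    "complex_degradation", "atc_influx", "atc_efflux")
}
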