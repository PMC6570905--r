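#' Kinetic parameters of the self-repressor reaction network
#'
#' Bundles all rate constants of the inducer-coupled negative
#' auto-regulation circuit. The repressor (TetR, fused to Venus) represses
#' its own promoter: a dimer formed from two free monomers occupies one of
#' two operators with propensity `h*n*(n-1)/2` (quadratic in the free
#' monomer count `n`), and is displaced by a free-monomer competitor with
#' propensity `f*n` (linear in `n`). The inducer aTc enters the cell by
#' passive diffusion and sequesters free TetR into a complex (`Ta`) that
#' cannot bind DNA, which slows both operator binding and unbinding and
#' drives the circuit into the non-adiabatic, bimodal regime.
#'
#' Two derived dimensionless quantities are recomputed on demand (never
#' stored): the adiabaticity parameter `omega = f / k1` comparing operator
#' unbinding to protein degradation, and the operator equilibrium constant
#' `Xeq = f / h` (inverse affinity).
#'
#' @param h operator binding rate constant (per molecule^2 per minute).
#' @param f operator unbinding rate constant (per molecule per minute).
#' @param g11,g10,g01,g00 protein synthesis rate (molecules/min) in each
#'   gene state; `A11` is fully active (both operators free), `A00` fully
#'   repressed. Operator symmetry requires `g11 >= g10 == g01 >= g00`.
#' @param k1 TetR degradation-plus-dilution rate (per minute).
#' @param b TetR-aTc association rate (per molecule per minute).
#' @param a Ta complex dissociation rate (per minute).
#' @param k2 Ta complex degradation rate (per minute).
#' @param c_diff membrane diffusion rate for aTc (per minute), used for both
#'   influx `c*E_aTc` and efflux `c*n_i`.
#' @param E_aTc external inducer abundance (molecules, held constant as an
#'   infinite bath).
#' @param unbinding_mode `"concentration_dependent"` (propensity `f*n`, the
#'   competitor-rebinding mechanism) or `"constant"` (propensity
#'   `f*n_ref`, independent of the free TetR level).
#' @param n_ref fixed reference monomer count used only when
#'   `unbinding_mode = "constant"`, chosen so the two variants are
#'   comparable at the low end of an inducer sweep.
#'
#' @return An object of class `rate_params` (a named list).
#' @seealso [default_rate_params()] for the calibrated defaults,
#'   [propensities()], [ssa_simulate()], [cme_stationary()].
#' @examples
#' p <- rate_params(h = 1e-4, f = 0.015, g11 = 10, g10 = 0.2, g01 = 0.2,
#'                  g00 = 0.2, k1 = 0.02, b = 1e-3, a = 0.1, k2 = 0.02,
#'                  c_diff = 0.1, E_aTc = 0)
#' omega(p)   # f / k1
#' x_eq(p)    # f / h
#' @export
rate_params <- function(h, f, g11, g10, g01, g00, k1, b, a, k2, c_diff,
                        E_aTc,
                        unbinding_mode = c("concentration_dependent",
                                           "constant"),
                        n_ref = 10) {
  unbinding_mode <- match.arg(unbinding_mode)
  vals <- c(h = h, f = f, g11 = g11, g10 = g10, g01 = g01, g00 = g00,
            k1 = k1, b = b, a = a, k2 = k2, c = c_diff, E_aTc = E_aTc,
            n_ref = n_ref)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (g10 != g01)
    stop("operator symmetry requires g10 == g01", call. = FALSE)
  if (!(g11 >= g10 && g10 >= g00))
    stop("synthesis rates must satisfy g11 >= g10 = g01 >= g00",
         call. = FALSE)
  structure(c(as.list(vals),
              list(unbinding_mode = unbinding_mode)),
            class = "rate_params")
}

#' Calibration-default parameters for the self-repressor
#'
#' A reference parameter set calibrated (not measured) so that: operator
#' switching is slow compared with protein turnover in the induced regime
#' (the effective unbinding rate is `f` times the free monomer count, so
#' the effective adiabaticity ratio `f*n/k1` spans from well above one at
#' zero inducer down to far below one once the inducer sequesters the
#' repressor -- the rate-constant ratio `omega = f/k1` alone is 0.02);
#' the fully active state expresses a few hundred molecules
#' (`g11/k1 = 500`); and an inducer sweep over roughly 0-1500 ng/mL
#' passes from an (almost entirely) unimodal population through rising
#' expression to a clearly bimodal population whose low-expression mode
#' gains weight monotonically toward the top of the range. Every value
#' can be overridden via [rate_params()] or a pipeline config file.
#'
#' @param E_aTc external inducer abundance in molecules (convert from
#'   ng/mL with [atc_to_molecules()]).
#' @param unbinding_mode see [rate_params()].
#' @return A `rate_params` object.
#' @export
default_rate_params <- function(E_aTc = 0,
                                unbinding_mode = "concentration_dependent") {
  rate_params(h = 4e-7, f = 4e-4,
              g11 = 10, g10 = 0.2, g01 = 0.2, g00 = 0.2,
              k1 = 0.02, b = 6.15e-5, a = 0.01, k2 = 0.01,
              c_diff = 0.02, E_aTc = E_aTc,
              unbinding_mode = unbinding_mode, n_ref = 20)
}

#' Count-scaled study parameters for fast simulation experiments
#'
#' A version of the calibrated circuit with all molecule pools scaled
#' down about tenfold and time scaled up fivefold (`k1 = 0.1`, active
#' synthesis `g11 = 5`, on-state mean around 50 molecules). Stationary
#' behaviour mirrors [default_rate_params()] -- unimodal at low inducer,
#' a bimodal window with a monotonically growing low-expression mode
#' under concentration-dependent unbinding, and a higher-inducer bimodal
#' window with a growing high-expression mode under constant unbinding
#' -- at a fraction of the simulation cost, because both the event rate
#' and the switching times shrink with the counts. Used by the
#' simulation-based validation suite; the inducer axis is in bare
#' molecule counts (the interesting range is roughly `E_aTc` 0-100).
#'
#' @param E_aTc external inducer abundance (molecules).
#' @param unbinding_mode see [rate_params()].
#' @return A `rate_params` object.
#' @export
scaled_rate_params <- function(E_aTc = 0,
                               unbinding_mode = "concentration_dependent") {
  rate_params(h = 2e-4, f = 0.02,
              g11 = 5, g10 = 0.1, g01 = 0.1, g00 = 0.1,
              k1 = 0.1, b = 0.02, a = 0.05, k2 = 0.05,
              c_diff = 0.1, E_aTc = E_aTc,
              unbinding_mode = unbinding_mode, n_ref = 2)
}

#' @rdname rate_params
#' @param params a `rate_params` object.
#' @export
omega <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  params$f / params$k1
}

#' @rdname rate_params
#' @export
x_eq <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  params$f / params$h
}

#' Convert an aTc mass concentration to a molecule count
#'
#' Converts ng/mL of anhydrotetracycline (molar mass 462.9 g/mol) into the
#' expected number of molecules in a reaction volume, the unit used for the
#' external inducer bath `E_aTc`. The default volume of 1 fL is an E.
#' coli-scale cytoplasmic volume; the conversion is configuration, not part
#' of any rate law.
#'
#' @param ng_per_ml aTc concentration(s) in ng/mL.
#' @param volume_fl reaction volume in femtolitres (default 1).
#' @param molar_mass aTc molar mass in g/mol (default 462.9).
#' @return molecule count(s), same length as `ng_per_ml`.
#' @examples
#' atc_to_molecules(1500)  # about 1950 molecules in 1 fL
#' @export
atc_to_molecules <- function(ng_per_ml, volume_fl = 1, molar_mass = 462.9) {
  stopifnot(all(ng_per_ml >= 0), volume_fl > 0)
  avogadro <- 6.02214076e23
  # ng/mL -> g/L -> mol/L -> molecules per fL
  ng_per_ml * 1e-6 / molar_mass * avogadro * volume_fl * 1e-15
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Self-repressor rate parameters\n")
  cat(sprintf("  binding h = %g, unbinding f = %g (%s)\n", x$h, x$f,
              x$unbinding_mode))
  cat(sprintf("  synthesis g11/g10/g01/g00 = %g/%g/%g/%g, degradation k1 = %g\n",
              x$g11, x$g10, x$g01, x$g00, x$k1))
  cat(sprintf("  inducer: b = %g, a = %g, k2 = %g, c = %g, E_aTc = %g\n",
              x$b, x$a, x$k2, x$c, x$E_aTc))
  cat(sprintf("  derived: omega = f/k1 = %g, Xeq = f/h = %g\n",
              omega(x), x_eq(x)))
  invisible(x)
}

# flat numeric vector handed to the C++ kernels
params_vector <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  c(h = params$h, f = params$f, g11 = params$g11, g10 = params$g10,
    g01 = params$g01, g00 = params$g00, k1 = params$k1, b = params$b,
    a = params$a, k2 = params$k2, c = params$c, E_aTc = params$E_aTc,
    n_ref = params$n_ref,
    const_unbind = as.numeric(params$unbinding_mode == "constant"))
}
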