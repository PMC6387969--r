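## The five current sub-models of the membrane voltage equation, plus the
## zero-current resting-PD solver.  Sign convention: outward positive;
## depolarization is V increasing toward 0.  All currents in A m-2, V at
## the interface in mV.

#' Nernst equilibrium potential
#'
#' @param c_in,c_out internal/external concentrations (any common unit,
#'   both > 0).
#' @param z ion valence (signed).
#' @param temperature K.
#' @return Potential in mV.
#' @export
nernst_potential <- function(c_in, c_out, z, temperature = DEFAULT_TEMPERATURE) {
  if (any(c(c_in, c_out) <= 0))
    stop_arg("nernst_potential: concentrations must be positive")
  if (z == 0) stop_arg("nernst_potential: z must be nonzero")
  v_to_mv(rt_over_f(temperature) / z * log(c_out / c_in))
}

#' Proton-pump current
#'
#' `I_p = z_p F N (k_io kappa_oi - k_oi kappa_io) / (k_io + k_oi +
#' kappa_io + kappa_oi)` with the Eyring-barrier rates
#' `k_io = kio0 exp(z_p F V / 2RT)`, `k_oi = koi0 exp(-z_p F V / 2RT)`.
#'
#' @param V membrane PD, mV.
#' @param pump a [pump_params()] object (use the caller's no-pump contract,
#'   not zero rates, for inactive pumps).
#' @return Outward-positive current, A m-2.
#' @export
pump_current <- function(V, pump) {
  stopifnot(inherits(pump, "pump_params"))
  u <- pump$z_p * mv_to_v(V) / (2 * rt_over_f(pump$temperature))
  kio <- pump$kio0 * exp(u)
  koi <- pump$koi0 * exp(-u)
  pump$z_p * FARADAY * pump$N *
    (kio * pump$kappa_oi - koi * pump$kappa_io) /
    (kio + koi + pump$kappa_io + pump$kappa_oi)
}

#' Background current
#'
#' Empirical ohmic leak `G_bkg (V - E_bkg)`.
#'
#' @param V membrane PD, mV.
#' @param G_bkg conductance, S m-2.
#' @param E_bkg reversal PD, mV.
#' @return Current, A m-2.
#' @export
background_current <- function(V, G_bkg, E_bkg = -100) {
  if (G_bkg < 0) stop_arg("background_current: G_bkg must be >= 0")
  G_bkg * mv_to_v(V - E_bkg)
}

## GHK factor u/(1 - exp(-u)) with its removable singularity at u = 0
ghk_factor <- function(u) {
  ifelse(abs(u) < 1e-8, 1 + u / 2 + u^2 / 12, u / (1 - exp(-u)))
}

#' K+ outward rectifier current
#'
#' GHK constant-field flux scaled by two Boltzmann open probabilities:
#' `P_o+` activates on depolarization (half-activation `V50_plus`), `P_o-`
#' deactivates below `V50_minus`.  Continuous at V = 0 (series limit) and
#' zero at the K+ reversal potential.
#'
#' @param V membrane PD, mV.
#' @param passive a [passive_params()] object.
#' @return Current, A m-2.
#' @export
outward_rectifier_current <- function(V, passive) {
  stopifnot(inherits(passive, "passive_params"))
  p <- passive
  RTF <- rt_over_f(p$temperature)
  v <- mv_to_v(V)
  u <- p$z * v / RTF
  po_plus <- 1 / (1 + exp(-p$z_g * mv_to_v(V - p$V50_plus) / RTF))
  po_minus <- 1 / (1 + exp(-p$z_g * mv_to_v(V - p$V50_minus) / RTF))
  flux <- p$NK_PK * p$z * FARADAY * (p$K_cyt - p$K_out * exp(-u)) *
    ghk_factor(u)
  po_plus * po_minus * flux
}

#' Chloride-gate kinetics
#'
#' First-order Ca2+-driven gate for the chloride channels:
#' `dy/dt = k_a x1_eff (1 - y) - k_i y`, with steady state
#' `y_inf = k_a x1 / (k_a x1 + k_i)`.
#'
#' @param y open fraction in `[0, 1]`.
#' @param x1_eff effective scaled cytoplasmic Ca2+ (pulse included).
#' @param k_a activation rate, per s per unit scaled Ca2+.
#' @param k_i inactivation rate, per s.
#' @return dy/dt in per s.
#' @export
chloride_gate_derivative <- function(y, x1_eff, k_a, k_i) {
  if (y < 0 || y > 1) stop_arg("chloride_gate_derivative: y must be in [0, 1]")
  k_a * x1_eff * (1 - y) - k_i * y
}

#' Ca2+-activated chloride current
#'
#' @param V membrane PD, mV.
#' @param y gate open fraction.
#' @param G_Cl maximal conductance, S m-2.
#' @param E_Cl chloride reversal PD, mV.
#' @return Current, A m-2.
#' @export
chloride_current <- function(V, y, G_Cl, E_Cl) {
  if (G_Cl < 0) stop_arg("chloride_current: G_Cl must be >= 0")
  G_Cl * y * mv_to_v(V - E_Cl)
}

#' TRP-like Ca2+ pulse current
#'
#' `G_Ca (V - E_Ca)` inside the pulse window, zero outside; `E_Ca` from
#' the Nernst potential of the tabulated Ca2+ concentrations.  Defaults to
#' zero everywhere when `G_Ca = 0` (the pulse then acts on the store model
#' only through the `dCa` increment).
#'
#' @param V membrane PD, mV.
#' @param t time, s.
#' @param passive a [passive_params()] object.
#' @param window `c(t_on, t_off)` in s.
#' @return Current, A m-2.
#' @export
trp_current <- function(V, t, passive, window) {
  stopifnot(inherits(passive, "passive_params"))
  if (window[2] < window[1]) stop_arg("trp_current: window must be ordered")
  if (t < window[1] || t >= window[2] || passive$G_Ca == 0) return(0)
  E_Ca <- nernst_potential(um_to_molm3(passive$Ca_cyt), passive$Ca_out, 2,
                           passive$temperature)
  passive$G_Ca * mv_to_v(V - E_Ca)
}

## total steady-state membrane current with the chloride gate closed,
## no TRP pulse and no IP3 -- the balance the resting PD solves
resting_current <- function(V, ps) {
  Ip <- if (is.null(ps$pump)) 0 else pump_current(V, ps$pump)
  Ip + background_current(V, ps$passive$G_bkg, ps$passive$E_bkg) +
    outward_rectifier_current(V, ps$passive)
}

#' Zero-current resting membrane PD
#'
#' Solves `I_p + I_bkg + I_orc = 0` (chloride gate closed, no TRP pulse,
#' no IP3) by bisection on the given bracket to 0.01 mV.  For no-pump
#' parameter sets the pump term is identically absent.
#'
#' @param ps a [parameter_set()].
#' @param bracket search interval in mV.
#' @param tol bisection tolerance, mV.
#' @return Resting PD, mV.
#' @export
resting_pd <- function(ps, bracket = c(-300, -40), tol = 0.01) {
  stopifnot(inherits(ps, "parameter_set"))
  lo <- bracket[1]; hi <- bracket[2]
  flo <- resting_current(lo, ps); fhi <- resting_current(hi, ps)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop_arg(sprintf(
      "resting_pd: no sign change on [%g, %g] mV (I(%g) = %.4g, I(%g) = %.4g A m-2)",
      lo, hi, lo, flo, hi, fhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- resting_current(mid, ps)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

## inverse problem used by the registry: which kappa_oi puts the
## zero-current PD at `target` mV?  NULL when unreachable.
kappa_for_resting_pd <- function(ps, target, bracket = c(0.01, 5000)) {
  if (is.null(ps$pump)) return(NULL)
  root_at <- function(kappa) {
    ps$pump$kappa_oi <- kappa
    tryCatch(resting_pd(ps, tol = 0.001) - target, error = function(e) NA_real_)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- root_at(lo); fhi <- root_at(hi)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) return(NULL)
  for (i in 1:60) {
    mid <- sqrt(lo * hi)  # rates are log-distributed
    fm <- root_at(mid)
    if (is.na(fm)) return(NULL)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  sqrt(lo * hi)
}
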