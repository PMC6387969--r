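## Parameter containers.  Plain named lists with S3 classes and eager
## validation; every simulation input is explicit so a ParameterSet is a
## complete, serializable description of one cell/condition.

stop_arg <- function(...) stop(..., call. = FALSE)

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop_arg(what, " must be a single non-negative number, got ",
             deparse(substitute(x)))
}

#' Store-channel kinetic parameters
#'
#' Kinetics of the IP3-gated Ca2+ channel on internal stores and of the
#' store Ca2+ pump.  Rates written with a `_prime` suffix are the tabulated
#' (unscaled) values; the scalings `k2 = k2_prime * C0`, `k3 = k3_prime *
#' C0`, `p1 = p1_prime / C0`, `p2 = p2_prime / C0` are applied internally
#' so that the scaled Ca2+ variable `x1 = C / C0` and the channel-state
#' fractions all range in `[0, 1]`.
#'
#' @param k1 binding rate of IP3 to the unbound channel, per (uM s).
#' @param k_m1 unbinding rate of IP3, per s.
#' @param k2_prime binding rate of activating Ca2+, per (uM s).
#' @param k_m2 unbinding rate of activating Ca2+, per s.
#' @param k3_prime binding rate of inactivating Ca2+, per (uM s).
#' @param k_m3 return rate from the inactivated state, per s.  Controls the
#'   refractory period: the inactivated state's lifetime is `1 / k_m3`.
#' @param gamma0 store permeability in the absence of IP3, per s.
#' @param gamma1 density of IP3-activated channels, per s.
#' @param nu_r store-to-cytoplasm volume ratio (dimensionless).
#' @param C0 average Ca2+ concentration scale, uM.
#' @param p1_prime maximal store-pump rate, uM/s.
#' @param p2_prime pump half-saturation Ca2+ concentration, uM.
#' @param hill_n Hill exponent of the pump (1, 2 or 4).  1 is
#'   Michaelis-Menten (no cooperativity, gradual repolarization); 2 is
#'   cooperative binding with a steeper repolarization; 4 is the original
#'   formulation of the store model.
#' @param I0 IP3 bolus injected at t = 0, uM.
#' @param ip3_decay first-order decay rate of the bolus, per s (0.2,
#'   determined experimentally by repetitive stimulation).
#' @param dCa additive increment to scaled Ca2+ delivered by the TRP-like
#'   plasma-membrane pulse (dimensionless, already scaled by C0).
#' @param dCa_window `c(t_on, t_off)` in s during which `dCa` applies.
#' @param Ca_rest resting cytoplasmic Ca2+, uM; sets the default initial
#'   `x1 = Ca_rest / C0`.
#' @return An object of class `store_kinetics`.
#' @export
store_kinetics <- function(k1 = 12, k_m1 = 8, k2_prime = 14.2, k_m2 = 1.595,
                           k3_prime = 1.51, k_m3 = 0.312,
                           gamma0 = 0.1, gamma1 = 20.5, nu_r = 0.185,
                           C0 = 1.56, p1_prime = 9.74, p2_prime = 0.0197,
                           hill_n = 1, I0 = 2.1, ip3_decay = 0.2,
                           dCa = 0, dCa_window = c(0, 0), Ca_rest = 0.02) {
  for (nm in c("k1", "k_m1", "k2_prime", "k_m2", "k3_prime", "k_m3",
               "gamma0", "gamma1", "nu_r", "C0", "p1_prime", "p2_prime",
               "I0", "ip3_decay", "dCa", "Ca_rest")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_arg("store_kinetics: '", nm, "' must be a non-negative number")
  }
  if (!(hill_n %in% c(1, 2, 4)))
    stop_arg("store_kinetics: hill_n must be 1, 2 or 4")
  if (length(dCa_window) != 2 || any(is.na(dCa_window)) ||
      dCa_window[2] < dCa_window[1])
    stop_arg("store_kinetics: dCa_window must be an ordered (t_on, t_off)")
  structure(list(k1 = k1, k_m1 = k_m1, k2_prime = k2_prime, k_m2 = k_m2,
                 k3_prime = k3_prime, k_m3 = k_m3, gamma0 = gamma0,
                 gamma1 = gamma1, nu_r = nu_r, C0 = C0,
                 p1_prime = p1_prime, p2_prime = p2_prime,
                 hill_n = as.integer(hill_n), I0 = I0,
                 ip3_decay = ip3_decay, dCa = dCa,
                 dCa_window = as.numeric(dCa_window), Ca_rest = Ca_rest),
            class = "store_kinetics")
}

## scaled coefficients used by the rate equations
scaled_kinetics <- function(kin) {
  list(k2 = kin$k2_prime * kin$C0,
       k3 = kin$k3_prime * kin$C0,
       p1 = kin$p1_prime / kin$C0,
       p2 = kin$p2_prime / kin$C0,
       lambda = 1 + kin$nu_r)
}

#' Proton-pump parameters (Eyring barrier model)
#'
#' Charge transit through the pump is carried by voltage-dependent rate
#' constants `k_io`, `k_oi` across a symmetrical Eyring barrier, combined
#' with the voltage-independent cycle rates `kappa_io`, `kappa_oi`
#' (subsuming ATP/ADP/phosphate/H+ binding and carrier recycling).  An
#' inactive pump is represented by `pump = NULL` in a [parameter_set()],
#' never by zero rates.
#'
#' @param kappa_oi,kappa_io voltage-independent cycle rates, per s.
#' @param kio0,koi0 barrier rates at 0 PD, per s.
#' @param z_p pump stoichiometry (charges per cycle).
#' @param N scaling factor, mol m-2.
#' @param temperature K.
#' @return An object of class `pump_params`.
#' @export
pump_params <- function(kappa_oi = 80, kio0 = 6500, koi0 = 0.1,
                        kappa_io = 0.1, z_p = 1, N = 2e-8,
                        temperature = DEFAULT_TEMPERATURE) {
  for (nm in c("kappa_oi", "kio0", "koi0", "kappa_io", "z_p", "N",
               "temperature")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop_arg("pump_params: '", nm, "' must be a positive number ",
               "(use pump = NULL for a cell without pump)")
  }
  structure(list(kappa_oi = kappa_oi, kio0 = kio0, koi0 = koi0,
                 kappa_io = kappa_io, z_p = z_p, N = N,
                 temperature = temperature),
            class = "pump_params")
}

#' Passive-membrane parameters
#'
#' Everything in the voltage equation apart from the pump: the background
#' leak, the K+ outward rectifier (GHK flux times Boltzmann open
#' probabilities), the Ca2+-activated chloride conductance and its gate
#' rates, the TRP-like Ca2+ conductance, ionic concentrations, and the
#' membrane capacitance.
#'
#' @param G_bkg background conductance, S m-2.
#' @param E_bkg background reversal PD, mV.
#' @param NK_PK rectifier channel-count times permeability, m3 s-1.
#' @param z valence of the rectified ion (+1 for K+).
#' @param z_g gating charges of the rectifier Boltzmann factors.
#' @param V50_plus,V50_minus half-activation PDs (mV) of the depolarized-
#'   and hyperpolarized-limb Boltzmann factors.  `V50_minus` defaults to
#'   -300 mV so its factor is ~1 over the physiological range.
#' @param K_cyt,K_out K+ concentrations, mM (= mol m-3).
#' @param Cl_cyt,Cl_out Cl- concentrations, mM.
#' @param Ca_cyt cytoplasmic Ca2+, uM.
#' @param Ca_out external Ca2+, mM.
#' @param G_Cl_max maximal chloride conductance, S m-2.
#' @param k_a,k_i chloride-gate activation (per s, per unit scaled Ca2+)
#'   and inactivation (per s) rate constants.
#' @param G_Ca TRP-like Ca2+ conductance, S m-2 (0 by default: the pulse
#'   acts on the store model through `dCa` alone).
#' @param Cm membrane capacitance, F m-2 (0.01, typical characean plasma
#'   membrane).
#' @param temperature K.
#' @return An object of class `passive_params`.
#' @export
passive_params <- function(G_bkg = 0.5, E_bkg = -100, NK_PK = 6.5e-7,
                           z = 1, z_g = 1, V50_plus = 100, V50_minus = -300,
                           K_cyt = 80, K_out = 0.1, Cl_cyt = 60,
                           Cl_out = 1.3, Ca_cyt = 0.02, Ca_out = 0.1,
                           G_Cl_max = 4, k_a = 4.6, k_i = 2, G_Ca = 0,
                           Cm = 0.01, temperature = DEFAULT_TEMPERATURE) {
  for (nm in c("K_cyt", "K_out", "Cl_cyt", "Cl_out", "Ca_cyt", "Ca_out")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop_arg("passive_params: concentration '", nm, "' must be positive")
  }
  for (nm in c("G_bkg", "G_Cl_max", "G_Ca", "k_a", "k_i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_arg("passive_params: '", nm, "' must be non-negative")
  }
  if (!is.numeric(Cm) || Cm <= 0) stop_arg("passive_params: Cm must be > 0")
  structure(list(G_bkg = G_bkg, E_bkg = E_bkg, NK_PK = NK_PK, z = z,
                 z_g = z_g, V50_plus = V50_plus, V50_minus = V50_minus,
                 K_cyt = K_cyt, K_out = K_out, Cl_cyt = Cl_cyt,
                 Cl_out = Cl_out, Ca_cyt = Ca_cyt, Ca_out = Ca_out,
                 G_Cl_max = G_Cl_max, k_a = k_a, k_i = k_i, G_Ca = G_Ca,
                 Cm = Cm, temperature = temperature),
            class = "passive_params")
}

#' Time-varying schedules for the pump rate and chloride conductance
#'
#' Two slow parameter drifts observed around the AP are represented as
#' schedules on simulation time (t = 0 at the IP3 bolus): a piecewise
#' linear ramp of the pump cycle rate `kappa_oi` (transient pump inhibition
#' by elevated cytoplasmic Ca2+), and an exponential decay of `G_Cl_max`
#' over the first seconds of excitation.
#'
#' @param kappa_ramp `NULL`, or a list with `t_start`, `t_stop`,
#'   `end_value` and optionally `recovery_value` (reached by a second
#'   linear leg from `t_stop` to `t_recover`, default held).
#' @param gcl_decay `NULL`, or a list with `G_start`, `G_end`, `duration`
#'   (s) and `tau` (s): `G(t) = G_end + (G_start - G_end) exp(-t/tau)` for
#'   `t < duration`, then `G_end`.
#' @return An object of class `ap_schedule`.
#' @export
ap_schedule <- function(kappa_ramp = NULL, gcl_decay = NULL) {
  if (!is.null(kappa_ramp)) {
    need <- c("t_start", "t_stop", "end_value")
    if (!all(need %in% names(kappa_ramp)))
      stop_arg("ap_schedule: kappa_ramp needs ", paste(need, collapse = ", "))
    if (kappa_ramp$t_start >= kappa_ramp$t_stop)
      stop_arg("ap_schedule: kappa_ramp t_start must precede t_stop")
    if (kappa_ramp$end_value < 0)
      stop_arg("ap_schedule: kappa_ramp end_value must be >= 0")
  }
  if (!is.null(gcl_decay)) {
    need <- c("G_start", "G_end", "duration", "tau")
    if (!all(need %in% names(gcl_decay)))
      stop_arg("ap_schedule: gcl_decay needs ", paste(need, collapse = ", "))
    if (gcl_decay$G_start < 0 || gcl_decay$G_end < 0)
      stop_arg("ap_schedule: conductances must be >= 0")
  }
  structure(list(kappa_ramp = kappa_ramp, gcl_decay = gcl_decay),
            class = "ap_schedule")
}

#' Complete simulation parameter set for one cell/condition
#'
#' @param label cell/condition identifier.
#' @param kinetics a [store_kinetics()] object.
#' @param pump a [pump_params()] object, or `NULL` for a cell whose proton
#'   pump is inactive (the pump term is then omitted entirely).
#' @param passive a [passive_params()] object.
#' @param schedule an [ap_schedule()] object.
#' @param V0 pre-excitation resting PD in mV, or `NA` to use the
#'   zero-current PD computed by [resting_pd()].
#' @param V_post printed post-excitation resting PD in mV (informational;
#'   `NA` when not reported).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(label, kinetics = store_kinetics(),
                          pump = pump_params(), passive = passive_params(),
                          schedule = ap_schedule(), V0 = NA_real_,
                          V_post = NA_real_) {
  stopifnot(inherits(kinetics, "store_kinetics"),
            is.null(pump) || inherits(pump, "pump_params"),
            inherits(passive, "passive_params"),
            inherits(schedule, "ap_schedule"))
  structure(list(label = as.character(label), kinetics = kinetics,
                 pump = pump, passive = passive, schedule = schedule,
                 V0 = as.numeric(V0), V_post = as.numeric(V_post)),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", x$label, "\n", sep = "")
  cat("  pump: ", if (is.null(x$pump)) "none" else
    sprintf("kappa_oi = %g s-1, kio0 = %g s-1", x$pump$kappa_oi, x$pump$kio0),
    "\n", sep = "")
  cat(sprintf("  store: p1' = %g uM/s, p2' = %g uM, k-3 = %g s-1, IP3 = %g uM, n = %d\n",
              x$kinetics$p1_prime, x$kinetics$p2_prime, x$kinetics$k_m3,
              x$kinetics$I0, x$kinetics$hill_n))
  cat(sprintf("  membrane: G_Cl,max = %g S/m2, G_bkg = %g S/m2, V0 = %s mV\n",
              x$passive$G_Cl_max, x$passive$G_bkg,
              if (is.na(x$V0)) "(zero-current)" else format(x$V0)))
  if (!is.null(x$schedule$kappa_ramp))
    cat(sprintf("  kappa_oi ramp -> %g s-1 over [%g, %g] s\n",
                x$schedule$kappa_ramp$end_value,
                x$schedule$kappa_ramp$t_start, x$schedule$kappa_ramp$t_stop))
  if (!is.null(x$schedule$gcl_decay))
    cat(sprintf("  G_Cl,max decay %g -> %g S/m2 (tau %g s, first %g s)\n",
                x$schedule$gcl_decay$G_start, x$schedule$gcl_decay$G_end,
                x$schedule$gcl_decay$tau, x$schedule$gcl_decay$duration))
  invisible(x)
}

## Flat parameter addressing used by fitting, overrides and the CLI.
param_location <- function(name) {
  map <- list(
    p1_prime = c("kinetics", "p1_prime"), p2_prime = c("kinetics", "p2_prime"),
    k1 = c("kinetics", "k1"), k_m1 = c("kinetics", "k_m1"),
    k2_prime = c("kinetics", "k2_prime"), k_m2 = c("kinetics", "k_m2"),
    k3_prime = c("kinetics", "k3_prime"), k_m3 = c("kinetics", "k_m3"),
    gamma0 = c("kinetics", "gamma0"), gamma1 = c("kinetics", "gamma1"),
    nu_r = c("kinetics", "nu_r"), C0 = c("kinetics", "C0"),
    hill_n = c("kinetics", "hill_n"), I0 = c("kinetics", "I0"),
    ip3_decay = c("kinetics", "ip3_decay"), dCa = c("kinetics", "dCa"),
    Ca_rest = c("kinetics", "Ca_rest"),
    kappa_oi = c("pump", "kappa_oi"), kappa_io = c("pump", "kappa_io"),
    kio0 = c("pump", "kio0"), koi0 = c("pump", "koi0"),
    G_bkg = c("passive", "G_bkg"), E_bkg = c("passive", "E_bkg"),
    NK_PK = c("passive", "NK_PK"), z_g = c("passive", "z_g"),
    V50_plus = c("passive", "V50_plus"), V50_minus = c("passive", "V50_minus"),
    K_cyt = c("passive", "K_cyt"), K_out = c("passive", "K_out"),
    Cl_cyt = c("passive", "Cl_cyt"), Cl_out = c("passive", "Cl_out"),
    Ca_cyt = c("passive", "Ca_cyt"), Ca_out = c("passive", "Ca_out"),
    G_Cl_max = c("passive", "G_Cl_max"), k_a = c("passive", "k_a"),
    k_i = c("passive", "k_i"), G_Ca = c("passive", "G_Ca"),
    Cm = c("passive", "Cm"), V0 = "V0")
  loc <- map[[name]]
  if (is.null(loc)) stop_arg("unknown parameter name '", name, "'")
  loc
}

#' Read or replace a single parameter in a parameter set by flat name
#'
#' @param ps a [parameter_set()].
#' @param name flat parameter name, e.g. `"p1_prime"`, `"kappa_oi"`,
#'   `"G_Cl_max"`, `"V0"`.
#' @param value replacement value (for `set_parameter`).
#' @return `get_parameter` the numeric value; `set_parameter` the modified
#'   parameter set.
#' @export
get_parameter <- function(ps, name) {
  loc <- param_location(name)
  if (loc[1] == "pump" && is.null(ps$pump))
    stop_arg("parameter set '", ps$label, "' has no pump")
  if (length(loc) == 1) ps[[loc]] else ps[[loc[1]]][[loc[2]]]
}

#' @rdname get_parameter
#' @export
set_parameter <- function(ps, name, value) {
  loc <- param_location(name)
  if (loc[1] == "pump" && is.null(ps$pump))
    stop_arg("parameter set '", ps$label, "' has no pump")
  if (length(loc) == 1) ps[[loc]] <- value else ps[[loc[1]]][[loc[2]]] <- value
  ps
}
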