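## Coupled AP simulation: the excitation core, the chloride gate and the
## membrane voltage equation integrated jointly.  State vector:
## (x1, x2, x3, x4, x5, y, V) with V in volts internally.

## per-term membrane currents at one sample; V in mV
current_terms <- function(V, t, y, x1_eff, ps, kappa_t, gcl_t) {
  E_Cl <- nernst_potential(ps$passive$Cl_cyt, ps$passive$Cl_out, -1,
                           ps$passive$temperature)
  I_Cl <- chloride_current(V, y, gcl_t, E_Cl)
  I_p <- if (is.null(ps$pump)) 0 else {
    pump <- ps$pump
    pump$kappa_oi <- kappa_t
    pump_current(V, pump)
  }
  I_orc <- outward_rectifier_current(V, ps$passive)
  I_bkg <- background_current(V, ps$passive$G_bkg, ps$passive$E_bkg)
  I_trp <- trp_current(V, t, ps$passive, ps$kinetics$dCa_window)
  c(I_Cl = I_Cl, I_p = I_p, I_orc = I_orc, I_bkg = I_bkg, I_trp = I_trp)
}

#' Per-current diagnostic table
#'
#' Evaluates each membrane current term of the voltage equation along a
#' simulated trajectory (columns `t, I_Cl, I_p, I_orc, I_bkg, I_trp,
#' I_total, dVdt`); `I_total` equals `-Cm dV/dt` at every sample.
#'
#' @param sim result of [simulate_ap()].
#' @return data.frame of currents in A m-2 and `dVdt` in mV/s.
#' @export
membrane_currents <- function(sim) {
  stopifnot(inherits(sim, "ap_simulation"))
  sim$currents
}

#' Simulate a single action potential
#'
#' Integrates the voltage equation `dV/dt = -(1/Cm) (I_Cl + I_p + I_orc +
#' I_bkg + I_TRP)` jointly with the store ODEs and the chloride gate from
#' `V(0) = V0`, with the IP3 bolus applied at t = 0.  Schedules (pump-rate
#' ramp, chloride-conductance decay) run on simulation time.  Integration
#' restarts at every schedule/pulse discontinuity.
#'
#' @param ps a [parameter_set()].
#' @param t_end simulation length, s.
#' @param dt_out output sampling interval, s.
#' @param rtol,atol solver tolerances.
#' @return An object of class `ap_simulation`: list with `trace` (an
#'   [ap_trace()] of the membrane PD), `states` (data.frame `t, x1..x5, y,
#'   x1_eff`), `currents` (per-term table) and `ps`.
#' @export
simulate_ap <- function(ps, t_end = 20, dt_out = 0.01,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(ps, "parameter_set"))
  if (t_end <= 0 || dt_out <= 0)
    stop_arg("simulate_ap: t_end and dt_out must be positive")
  kin <- ps$kinetics
  sc <- scaled_kinetics(kin)
  V0 <- if (is.na(ps$V0)) resting_pd(ps) else ps$V0
  kappa_base <- if (is.null(ps$pump)) NA_real_ else ps$pump$kappa_oi
  gcl_base <- ps$passive$G_Cl_max
  sched <- ps$schedule

  rhs <- function(t, s) {
    x1 <- s[1]; y <- s[6]; V_mv <- v_to_mv(s[7])
    xe <- effective_x1(x1, t, kin)
    d_store <- excitation_rhs(t, s[1:5], kin, sc)
    dy <- ps$passive$k_a * xe * (1 - min(max(y, 0), 1)) - ps$passive$k_i * y
    sg <- evaluate_schedule(sched, t, kappa_base, gcl_base)
    terms <- current_terms(V_mv, t, y, xe, ps, sg[["kappa_oi"]],
                           sg[["G_Cl_max"]])
    dV <- -sum(terms) / ps$passive$Cm
    c(d_store, dy, dV)
  }

  t_grid <- seq(0, t_end, by = dt_out)
  breaks <- c(kin$dCa_window,
              if (!is.null(sched$kappa_ramp))
                c(sched$kappa_ramp$t_start, sched$kappa_ramp$t_stop),
              if (!is.null(sched$gcl_decay)) sched$gcl_decay$duration)
  y0 <- c(kin$Ca_rest / kin$C0, 1, 0, 0, 0, 0, mv_to_v(V0))
  out <- integrate_piecewise(y0, t_grid, breaks, rhs, rtol, atol)

  t <- out[, 1]
  states <- data.frame(t = t, x1 = out[, 2], x2 = out[, 3], x3 = out[, 4],
                       x4 = out[, 5], x5 = out[, 6], y = out[, 7])
  states$x1_eff <- vapply(seq_along(t),
                          function(i) effective_x1(states$x1[i], t[i], kin),
                          numeric(1))
  V_mv <- v_to_mv(out[, 8])

  cur <- t(vapply(seq_along(t), function(i) {
    sg <- evaluate_schedule(sched, t[i], kappa_base, gcl_base)
    current_terms(V_mv[i], t[i], states$y[i], states$x1_eff[i], ps,
                  sg[["kappa_oi"]], sg[["G_Cl_max"]])
  }, numeric(5)))
  currents <- data.frame(t = t, cur)
  currents$I_total <- rowSums(cur)
  currents$dVdt <- -v_to_mv(currents$I_total / ps$passive$Cm)

  trace <- ap_trace(t, V_mv,
                    meta = list(label = ps$label, membrane = "plasma",
                                source = "simulation", V0 = V0))
  structure(list(trace = trace, states = states, currents = currents,
                 ps = ps, V0 = V0),
            class = "ap_simulation")
}

#' @export
print.ap_simulation <- function(x, ...) {
  v <- x$trace$v
  cat("<ap_simulation> ", x$ps$label, "\n", sep = "")
  cat(sprintf("  %d samples over %g s; V0 = %.1f mV; peak = %.1f mV at %.2f s\n",
              length(v), max(x$trace$t), x$V0, max(v),
              x$trace$t[which.max(v)]))
  invisible(x)
}
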