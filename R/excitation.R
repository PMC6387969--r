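## Excitation core: cytoplasmic Ca2+ and store-channel state dynamics.
##
## The store channel has four states, R (x2), RI (x3), RIC+ (x4, the
## conducting state) and RIC+C- (x5, inactivated); x1 = C/C0 is the scaled
## cytoplasmic Ca2+.  During the TRP pulse window the effective Ca2+ seen
## by every consumer of x1 is x1 + dCa, floored at zero.

#' IP3 concentration after a bolus
#'
#' The bolus `I0` injected at t = 0 decays as `I0 * exp(-ip3_decay * t)`;
#' the decay constant (0.2 per s) was determined experimentally from
#' repetitive stimulation.
#'
#' @param I0 bolus size, uM.
#' @param t time since the bolus, s (vectorized).
#' @param decay decay rate, per s.
#' @return IP3 concentration in uM.
#' @export
ip3_concentration <- function(I0, t, decay = 0.2) {
  if (any(t < 0)) stop_arg("ip3_concentration: t must be >= 0")
  if (I0 < 0) stop_arg("ip3_concentration: I0 must be >= 0")
  I0 * exp(-decay * t)
}

#' Construct a store state
#'
#' @param x1 scaled cytoplasmic Ca2+ (C/C0), >= 0.
#' @param x2,x3,x4,x5 channel-state fractions; must sum to 1 within 1e-8.
#' @param t time stamp, s.
#' @return An object of class `store_state`.
#' @export
store_state <- function(x1, x2, x3, x4, x5, t = 0) {
  fr <- c(x2, x3, x4, x5)
  if (x1 < 0) stop_arg("store_state: x1 must be >= 0")
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop_arg("store_state: fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-8)
    stop_arg("store_state: x2 + x3 + x4 + x5 must equal 1 (got ",
             format(sum(fr)), ")")
  structure(list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5, t = t),
            class = "store_state")
}

## raw channel-state rates; x1 here is the effective (pulse-including) value
state_rates <- function(x1, x2, x3, x4, x5, I, kin, sc = scaled_kinetics(kin)) {
  dx2 <- -kin$k1 * I * x2 + kin$k_m1 * x3
  dx3 <- -(kin$k_m1 + sc$k2 * x1) * x3 + kin$k1 * I * x2 + kin$k_m2 * x4
  dx4 <- sc$k2 * x1 * x3 + kin$k_m3 * x5 - (kin$k_m2 + sc$k3 * x1) * x4
  dx5 <- sc$k3 * x1 * x4 - kin$k_m3 * x5
  c(dx2 = dx2, dx3 = dx3, dx4 = dx4, dx5 = dx5)
}

#' Channel-state transition rates
#'
#' Time derivatives of the four state fractions given the current state,
#' the IP3 concentration, and the kinetics.  The four rates sum to zero
#' (conservation of channels).
#'
#' @param state a [store_state()].
#' @param I IP3 concentration, uM.
#' @param kin a [store_kinetics()].
#' @return Named vector `(dx2, dx3, dx4, dx5)` in per s.
#' @export
store_state_derivatives <- function(state, I, kin) {
  stopifnot(inherits(state, "store_state"), inherits(kin, "store_kinetics"))
  if (I < 0) stop_arg("store_state_derivatives: I must be >= 0")
  state_rates(state$x1, state$x2, state$x3, state$x4, state$x5, I, kin)
}

## scaled Ca2+ rate; x1 effective, floored at 0 by callers
calcium_rate <- function(x1, x4, kin, sc = scaled_kinetics(kin)) {
  n <- kin$hill_n
  influx <- sc$lambda * (kin$gamma0 + kin$gamma1 * x4) * (1 - x1)
  pump <- if (x1 <= 0) 0 else sc$p1 * x1^n / (sc$p2^n + x1^n)
  influx - pump
}

#' Rate of change of scaled cytoplasmic Ca2+
#'
#' `dx1/dt = lambda (gamma0 + gamma1 x4)(1 - x1) - p1 x1^n / (p2^n + x1^n)`
#' with `lambda = 1 + nu_r`, `p1 = p1_prime / C0`, `p2 = p2_prime / C0`,
#' `n = hill_n`.  The first term is release from (and leak out of) the
#' store, proportional to the conducting fraction `x4` and to the scaled
#' store-cytoplasm gradient `(1 - x1)`; the Hill term is re-sequestration
#' by the store Ca2+ pump.
#'
#' @param x1 scaled cytoplasmic Ca2+, >= 0.
#' @param x4 conducting-state fraction in `[0, 1]`.
#' @param kin a [store_kinetics()].
#' @return dx1/dt in per s.
#' @export
calcium_derivative <- function(x1, x4, kin) {
  stopifnot(inherits(kin, "store_kinetics"))
  if (x1 < 0) stop_arg("calcium_derivative: x1 must be >= 0")
  if (x4 < 0 || x4 > 1) stop_arg("calcium_derivative: x4 must be in [0, 1]")
  calcium_rate(x1, x4, kin)
}

#' Resting fixed point of the scaled Ca2+ equation
#'
#' With no IP3 all channel mass sits in the unbound state (x2 = 1, x4 = 0)
#' and the resting scaled Ca2+ solves `lambda gamma0 (1 - x1) = p1 x1^n /
#' (p2^n + x1^n)`.  Solved by bisection on `[0, 1]`.
#'
#' @param kin a [store_kinetics()].
#' @return A [store_state()] at the no-IP3 fixed point.
#' @export
store_rest_state <- function(kin) {
  f <- function(x1) calcium_rate(x1, 0, kin)
  lo <- 0; hi <- 1
  if (f(lo) <= 0) return(store_state(0, 1, 0, 0, 0))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  store_state((lo + hi) / 2, 1, 0, 0, 0)
}

## effective scaled Ca2+ fed to all consumers of x1
effective_x1 <- function(x1, t, kin) {
  off <- if (t >= kin$dCa_window[1] && t < kin$dCa_window[2]) kin$dCa else 0
  max(x1 + off, 0)
}

## full excitation-core RHS used by both integrate_excitation and the
## coupled simulator (which appends the gate and voltage equations)
excitation_rhs <- function(t, x, kin, sc) {
  xe <- effective_x1(x[1], t, kin)
  I <- kin$I0 * exp(-kin$ip3_decay * t)
  r <- state_rates(xe, x[2], x[3], x[4], x[5], I, kin, sc)
  c(calcium_rate(xe, x[4], kin, sc), r)
}

#' Integrate the excitation core
#'
#' Integrates the scaled Ca2+ and the four channel-state fractions under a
#' decaying IP3 bolus applied at t = 0, with the TRP pulse offset `dCa`
#' added to the Ca2+ value seen by every rate term inside its window.
#' Integration restarts at the window edges so the adaptive solver never
#' steps across the discontinuity.
#'
#' @param kin a [store_kinetics()].
#' @param t_grid strictly increasing output times, s, starting at 0.
#' @param initial a [store_state()], or `NULL` for the default initial
#'   state: all channels unbound, `x1 = Ca_rest / C0`.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `t, x1, x2, x3, x4, x5, x1_eff`.
#' @export
integrate_excitation <- function(kin, t_grid, initial = NULL,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(kin, "store_kinetics"))
  if (any(diff(t_grid) <= 0))
    stop_arg("integrate_excitation: t_grid must be strictly increasing")
  if (is.null(initial)) {
    initial <- store_state(kin$Ca_rest / kin$C0, 1, 0, 0, 0)
  }
  stopifnot(inherits(initial, "store_state"))
  sc <- scaled_kinetics(kin)
  y0 <- c(initial$x1, initial$x2, initial$x3, initial$x4, initial$x5)
  out <- integrate_piecewise(
    y0, t_grid, breaks = kin$dCa_window,
    rhs = function(t, y) excitation_rhs(t, y, kin, sc),
    rtol = rtol, atol = atol)
  colnames(out) <- c("t", "x1", "x2", "x3", "x4", "x5")
  out <- as.data.frame(out)
  out$x1_eff <- vapply(seq_len(nrow(out)),
                       function(i) effective_x1(out$x1[i], out$t[i], kin),
                       numeric(1))
  out
}

## Segment-wise adaptive integration: restart lsoda at every break point
## (pulse window edges, schedule knots) so discontinuous forcing cannot be
## stepped over.  Returns a matrix with time in column 1.
integrate_piecewise <- function(y0, t_grid, breaks, rhs, rtol, atol) {
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  br <- sort(unique(breaks[breaks > t0 & breaks < t1]))
  edges <- c(t0, br, t1)
  rows <- matrix(c(t0, y0), nrow = 1)
  y <- y0
  func <- function(t, y, p) list(rhs(t, y))
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    inner <- t_grid[t_grid > a & t_grid < b]
    times <- unique(c(a, inner, b))
    sol <- try(deSolve::lsoda(y, times, func, parms = NULL,
                              rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol)))
      stop(structure(class = c("charAP_integration_error", "error",
                               "condition"),
                     list(message = paste0(
                       "integration failed on [", format(a), ", ",
                       format(b), "] s; last state: ",
                       paste(format(y, digits = 6), collapse = ", ")),
                       call = NULL)))
    keep <- sol[-1, , drop = FALSE]
    rows <- rbind(rows, keep)
    y <- as.numeric(sol[nrow(sol), -1])
  }
  rows[rows[, 1] %in% t_grid, , drop = FALSE]
}
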