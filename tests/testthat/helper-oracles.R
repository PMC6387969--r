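## Independent oracles used by the tests.  The RK4 integrator below is a
## direct fixed-step transcription of the model equations written against
## the raw parameter values; it shares no code with the package's adaptive
## solver path.

FARADAY_O <- 96485
RTF_O <- 8.314 * 293 / 96485  # volts

## RHS for the full coupled system, transcribed independently.
## state: c(x1, x2, x3, x4, x5, y, V_volts)
oracle_rhs <- function(t, s, ps) {
  kin <- ps$kinetics; pas <- ps$passive
  k2 <- kin$k2_prime * kin$C0; k3 <- kin$k3_prime * kin$C0
  p1 <- kin$p1_prime / kin$C0; p2 <- kin$p2_prime / kin$C0
  lam <- 1 + kin$nu_r; n <- kin$hill_n
  off <- if (t >= kin$dCa_window[1] && t < kin$dCa_window[2]) kin$dCa else 0
  xe <- max(s[1] + off, 0)
  I <- kin$I0 * exp(-kin$ip3_decay * t)
  dx2 <- -kin$k1 * I * s[2] + kin$k_m1 * s[3]
  dx3 <- -(kin$k_m1 + k2 * xe) * s[3] + kin$k1 * I * s[2] + kin$k_m2 * s[4]
  dx4 <- k2 * xe * s[3] + kin$k_m3 * s[5] - (kin$k_m2 + k3 * xe) * s[4]
  dx5 <- k3 * xe * s[4] - kin$k_m3 * s[5]
  pump_term <- if (xe <= 0) 0 else p1 * xe^n / (p2^n + xe^n)
  dx1 <- lam * (kin$gamma0 + kin$gamma1 * s[4]) * (1 - xe) - pump_term
  dy <- pas$k_a * xe * (1 - s[6]) - pas$k_i * s[6]
  V <- s[7]
  ## schedules
  kap <- if (is.null(ps$pump)) NA else ps$pump$kappa_oi
  if (!is.null(ps$schedule$kappa_ramp)) {
    r <- ps$schedule$kappa_ramp
    if (t >= r$t_stop) kap <- r$end_value
    else if (t > r$t_start)
      kap <- kap + (r$end_value - kap) * (t - r$t_start) / (r$t_stop - r$t_start)
  }
  gcl <- pas$G_Cl_max
  if (!is.null(ps$schedule$gcl_decay)) {
    d <- ps$schedule$gcl_decay
    gcl <- if (t >= d$duration) d$G_end else
      d$G_end + (d$G_start - d$G_end) * exp(-t / d$tau)
  }
  E_Cl <- -RTF_O * log(pas$Cl_out / pas$Cl_cyt)
  I_Cl <- gcl * s[6] * (V - E_Cl)
  I_p <- if (is.null(ps$pump)) 0 else {
    u <- ps$pump$z_p * V / (2 * RTF_O)
    kio <- ps$pump$kio0 * exp(u); koi <- ps$pump$koi0 * exp(-u)
    ps$pump$z_p * FARADAY_O * ps$pump$N *
      (kio * kap - koi * ps$pump$kappa_io) /
      (kio + koi + ps$pump$kappa_io + kap)
  }
  u <- pas$z * V / RTF_O
  pop <- 1 / (1 + exp(-pas$z_g * (V - pas$V50_plus / 1000) / RTF_O))
  pom <- 1 / (1 + exp(-pas$z_g * (V - pas$V50_minus / 1000) / RTF_O))
  gf <- if (abs(u) < 1e-8) 1 + u / 2 else u / (1 - exp(-u))
  I_orc <- pop * pom * pas$NK_PK * pas$z * FARADAY_O *
    (pas$K_cyt - pas$K_out * exp(-u)) * gf
  I_bkg <- pas$G_bkg * (V - pas$E_bkg / 1000)
  I_trp <- if (pas$G_Ca > 0 && t >= kin$dCa_window[1] &&
               t < kin$dCa_window[2]) {
    E_Ca <- RTF_O / 2 * log(pas$Ca_out / (pas$Ca_cyt * 1e-3))
    pas$G_Ca * (V - E_Ca)
  } else 0
  dV <- -(I_Cl + I_p + I_orc + I_bkg + I_trp) / pas$Cm
  c(dx1, dx2, dx3, dx4, dx5, dy, dV)
}

## Classic RK4 at fixed dt; returns states at every `keep`-th step.
rk4_integrate <- function(rhs, s0, t_end, dt, keep = 100L, ...) {
  n_steps <- round(t_end / dt)
  out_t <- numeric(n_steps %/% keep + 1)
  out_s <- matrix(0, nrow = n_steps %/% keep + 1, ncol = length(s0))
  out_t[1] <- 0; out_s[1, ] <- s0
  s <- s0; t <- 0; row <- 1L
  for (i in seq_len(n_steps)) {
    k1 <- rhs(t, s, ...)
    k2 <- rhs(t + dt / 2, s + dt / 2 * k1, ...)
    k3 <- rhs(t + dt / 2, s + dt / 2 * k2, ...)
    k4 <- rhs(t + dt, s + dt * k3, ...)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
    if (i %% keep == 0L) {
      row <- row + 1L
      out_t[row] <- t; out_s[row, ] <- s
    }
  }
  list(t = out_t[1:row], s = out_s[1:row, , drop = FALSE])
}

## oracle run of a full parameter set
oracle_simulate <- function(ps, t_end = 20, dt = 1e-4, keep = 100L,
                            V0 = NULL) {
  kin <- ps$kinetics
  if (is.null(V0)) V0 <- if (is.na(ps$V0)) resting_pd(ps) else ps$V0
  s0 <- c(kin$Ca_rest / kin$C0, 1, 0, 0, 0, 0, V0 / 1000)
  rk4_integrate(oracle_rhs, s0, t_end, dt, keep, ps = ps)
}

## a small library of valid random store states for property tests
random_store_state <- function() {
  fr <- abs(rnorm(4)); fr <- fr / sum(fr)
  store_state(abs(rnorm(1, 0.1, 0.2)), fr[1], fr[2], fr[3], fr[4])
}
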