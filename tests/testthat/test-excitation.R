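kin_apav <- function(...) {
  args <- list(...)
  do.call(store_kinetics, modifyList(list(
    p1_prime = 9.74, p2_prime = 0.0197, k_m3 = 0.312, I0 = 2.1,
    hill_n = 1, dCa = 0.009, dCa_window = c(0.07, 0.16)), args))
}

test_that("IP3 bolus decays exponentially from its initial value", {
  expect_identical(ip3_concentration(2.1, 0), 2.1)
  expect_identical(ip3_concentration(0, 10), 0)
  expect_equal(ip3_concentration(2.1, 5), 2.1 * exp(-1), tolerance = 1e-12)
  tt <- seq(0, 30, 0.5)
  expect_true(all(diff(ip3_concentration(2.1, tt)) <= 0))
  expect_error(ip3_concentration(2.1, -1), "t must be")
  expect_error(ip3_concentration(-0.1, 1), "I0 must be")
})

test_that("channel-state rates match hand evaluation and conserve mass", {
  kin <- kin_apav()
  ## resting channel, no ligand: nothing moves
  r0 <- store_state_derivatives(store_state(0.01, 1, 0, 0, 0), 0, kin)
  expect_equal(unname(r0), rep(0, 4))
  ## pure IP3 binding out of x2: dx2 = -k1 I, dx3 = +k1 I (x1 = 0 kills
  ## the Ca-dependent terms)
  r1 <- store_state_derivatives(store_state(0, 1, 0, 0, 0), 2.1,
                                store_kinetics(k1 = 12))
  expect_equal(r1[["dx2"]], -25.2, tolerance = 1e-12)
  expect_equal(r1[["dx3"]], 25.2, tolerance = 1e-12)
  ## conservation: rates sum to zero for arbitrary valid states
  set.seed(42)
  for (i in 1:50) {
    st <- random_store_state()
    r <- store_state_derivatives(st, runif(1, 0, 3), kin)
    expect_lt(abs(sum(r)), 1e-12)
  }
})

test_that("scaled Ca2+ rate reproduces hand-computed values", {
  kin <- kin_apav()
  ## x1 = 1: influx vanishes, pump at saturation end
  expect_equal(calcium_derivative(1, 0, kin),
               -(9.74 / 1.56) / (1 + 0.0197 / 1.56), tolerance = 1e-12)
  expect_equal(calcium_derivative(1, 0, kin), -6.166, tolerance = 1e-3)
  ## x1 = 0: pump is exactly zero, influx = lambda gamma0
  expect_identical(calcium_derivative(0, 0.3, kin) > 0, TRUE)
  expect_equal(calcium_derivative(0, 0, kin), 1.185 * 0.1, tolerance = 1e-12)
  expect_error(calcium_derivative(-0.1, 0, kin), "x1 must be")
})

test_that("no-IP3 fixed point is stationary under integration", {
  kin <- kin_apav(I0 = 0, dCa = 0)
  rest <- store_rest_state(kin)
  expect_lt(abs(calcium_derivative(rest$x1, 0, kin)), 1e-10)
  out <- integrate_excitation(kin, seq(0, 20, 0.1), initial = rest)
  expect_lt(max(abs(out$x1 - rest$x1)), 1e-6)
  expect_equal(out$x2[nrow(out)], 1, tolerance = 1e-8)
})

test_that("trajectories conserve channel mass and stay in range", {
  for (col in c("AP_av Nitellopsis APW", "AP_av Chara APW",
                "Cell 3 50 mM NaCl overnight")) {
    kin <- load_parameter_set(2, col)$kinetics
    out <- integrate_excitation(kin, seq(0, 15, 0.05))
    expect_lt(max(abs(out$x2 + out$x3 + out$x4 + out$x5 - 1)), 1e-8)
    expect_gt(min(out$x2, out$x3, out$x4, out$x5), -1e-9)
    expect_gt(min(out$x1_eff), -1e-12)
  }
})

test_that("excitable kinetics produce a regenerative Ca2+ transient", {
  ## the Chara reference column and the spontaneously firing saline cell
  ## both regenerate: scaled Ca2+ rises far above its starting level
  for (col in c("AP_av Chara APW", "Cell 3 50 mM NaCl overnight")) {
    kin <- load_parameter_set(2, col)$kinetics
    out <- integrate_excitation(kin, seq(0, 15, 0.01))
    expect_gt(max(out$x1), 10 * out$x1[1])
    expect_gt(max(out$x4), 0.2)
  }
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  ## excitable kinetics over the AP time scale
  ps <- load_parameter_set(2, "AP_av Chara APW")
  kin <- ps$kinetics
  oracle <- rk4_integrate(function(t, s, kin) {
    r <- oracle_rhs(t, c(s, 0, -0.2), ps)  # reuse full RHS, ignore y/V
    r[1:5]
  }, c(kin$Ca_rest / kin$C0, 1, 0, 0, 0), t_end = 8, dt = 1e-4,
  keep = 1000L, kin = kin)
  out <- integrate_excitation(kin, oracle$t)
  expect_lt(max(abs(out$x1 - oracle$s[, 1])), 1e-3)
  expect_lt(max(abs(out$x4 - oracle$s[, 4])), 1e-3)
})

test_that("faster return from inactivation shortens x5 residence", {
  ## k_m3 rises an order of magnitude between the Chara and Nitellopsis
  ## fits; relaxing from an excited store state, the inactivated state
  ## should empty faster the larger k_m3 is.
  half_life <- function(k_m3) {
    kin <- load_parameter_set(2, "AP_av Nitellopsis APW")$kinetics
    kin$k_m3 <- k_m3; kin$I0 <- 0; kin$dCa <- 0
    init <- store_state(0.5, 0.05, 0.25, 0.6, 0.1)
    out <- integrate_excitation(kin, seq(0, 60, 0.02), initial = init)
    pk <- which.max(out$x5)
    half <- out$x5[pk] / 2
    after <- which(out$x5[pk:nrow(out)] <= half)
    expect_true(length(after) > 0)
    out$t[pk + after[1] - 1] - out$t[pk]
  }
  hl <- vapply(c(0.04, 0.15, 0.312), half_life, numeric(1))
  expect_true(all(diff(hl) < 0))
})

test_that("steeper pump Hill exponent repolarizes Ca2+ faster", {
  ## relaxation from an excited store state (channel mass conducting,
  ## Ca2+ high, IP3 spent): time from peak to 10% of peak
  decay_time <- function(n) {
    kin <- kin_apav(hill_n = n, I0 = 0, dCa = 0)
    init <- store_state(0.5, 0.05, 0.25, 0.6, 0.1)
    out <- integrate_excitation(kin, seq(0, 30, 0.01), initial = init)
    below <- which(out$x1 <= 0.1 * 0.5)
    expect_true(length(below) > 0)
    out$t[below[1]]
  }
  expect_lt(decay_time(2), decay_time(1))
})

test_that("invalid states and grids are rejected", {
  expect_error(store_state(0.1, 0.5, 0.5, 0.5, 0.5), "must equal 1")
  expect_error(store_state(-0.1, 1, 0, 0, 0), "x1 must be")
  expect_error(integrate_excitation(kin_apav(), c(0, 0.1, 0.1)),
               "strictly increasing")
})
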