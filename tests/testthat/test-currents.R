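ps_apav <- load_parameter_set(2, "AP_av Nitellopsis APW")

test_that("Nernst potentials match direct evaluation", {
  expect_equal(nernst_potential(60, 60, -1), 0)
  expect_equal(nernst_potential(80, 0.1, 1),
               8.314 * 293 / 96485 * 1000 * log(0.1 / 80), tolerance = 1e-12)
  expect_equal(nernst_potential(80, 0.1, 1), -168.77, tolerance = 1e-4)
  expect_equal(nernst_potential(60, 1.3, -1), 96.75, tolerance = 1e-4)
  ## divalent Ca2+ from the tabulated concentrations (0.02 uM in,
  ## 0.1 mM out)
  expect_equal(nernst_potential(2e-5, 0.1, 2), 107.5, tolerance = 1e-3)
  expect_error(nernst_potential(0, 1, 1), "positive")
})

test_that("pump current obeys detailed balance, matches evaluation, and is monotone in kappa_oi", {
  sym <- pump_params(kappa_oi = 0.1, kio0 = 0.1, koi0 = 0.1, kappa_io = 0.1)
  expect_equal(pump_current(0, sym), 0)
  p1 <- pump_params(kappa_oi = 80, kio0 = 6500)
  expect_equal(pump_current(-232, p1), 0.06513, tolerance = 1e-3)
  ips <- vapply(c(5, 80, 950),
                function(k) pump_current(-232, pump_params(kappa_oi = k,
                                                           kio0 = 6500)),
                numeric(1))
  expect_true(all(diff(ips) > 0))
})

test_that("background current is ohmic around its reversal", {
  expect_equal(background_current(-100, 1, -100), 0)
  expect_equal(background_current(-232, 0.5, -100), -0.066)
  expect_equal(background_current(-68, 1.0, -100), 0.032)
})

test_that("outward rectifier vanishes at the K+ reversal and is continuous at 0 mV", {
  pas <- ps_apav$passive
  EK <- nernst_potential(pas$K_cyt, pas$K_out, 1)
  expect_lt(abs(outward_rectifier_current(EK, pas)), 1e-12)
  ## removable singularity: compare against the analytic limit
  RTF <- 8.314 * 293 / 96485
  po_plus <- 1 / (1 + exp(-(0 - 0.1) / RTF))
  po_minus <- 1 / (1 + exp(-(0 + 0.3) / RTF))
  limit <- po_plus * po_minus * 6.5e-7 * 96485 * (pas$K_cyt - pas$K_out)
  expect_equal(outward_rectifier_current(0, pas), limit, tolerance = 1e-9)
  expect_equal(outward_rectifier_current(1e-9, pas), limit, tolerance = 1e-6)
  expect_equal(outward_rectifier_current(-1e-9, pas), limit, tolerance = 1e-6)
  ## frozen oracle value: depolarized saline cell (K_cyt = 50 mM)
  pas50 <- passive_params(K_cyt = 50)
  expect_equal(outward_rectifier_current(-68, pas50), 7.654e-4,
               tolerance = 1e-3)
  ## continuity over the physiological range: increments shrink in
  ## proportion to the grid step
  vv <- seq(-300, 100, 0.01)
  ii <- vapply(vv, outward_rectifier_current, numeric(1), passive = pas)
  expect_true(all(abs(diff(ii)) < 0.005))
})

test_that("chloride gate kinetics and current match closed forms", {
  expect_equal(chloride_gate_derivative(0, 0, 4.6, 2), 0)
  y_inf <- 4.6 / (4.6 + 2)
  expect_lt(abs(chloride_gate_derivative(y_inf, 1, 4.6, 2)), 1e-12)
  expect_equal(y_inf, 0.697, tolerance = 1e-3)
  expect_equal(chloride_gate_derivative(1, 0, 4.6, 2), -2)
  expect_equal(chloride_current(-150, 0, 5, 96.75), 0)
  expect_equal(chloride_current(96.75, 0.8, 5, 96.75), 0)
  expect_equal(chloride_current(-150, 0.5, 5, 96.75),
               5 * 0.5 * (-0.24675), tolerance = 1e-10)
})

test_that("TRP pulse current is windowed and Nernst-anchored", {
  pas <- passive_params(G_Ca = 0.1)
  expect_equal(trp_current(-100, 5, pas, c(0.07, 0.16)), 0)
  expect_equal(trp_current(-100, 0.1, passive_params(G_Ca = 0),
                           c(0.07, 0.16)), 0)
  E_Ca <- nernst_potential(2e-5, 0.1, 2)
  expect_equal(trp_current(-100, 0.1, pas, c(0.07, 0.16)),
               0.1 * (-100 - E_Ca) / 1000, tolerance = 1e-10)
  expect_equal(trp_current(E_Ca, 0.1, pas, c(0.07, 0.16)), 0)
})

test_that("resting PD solver reproduces the frozen bisection oracle", {
  expect_equal(resting_pd(ps_apav), -231.34, tolerance = 1e-4)
  cell6 <- load_parameter_set(4, "Cell 6 APW")
  expect_equal(resting_pd(cell6), -119.15, tolerance = 1e-3)
  ## pump-off cell rests essentially at the background reversal
  nopump <- load_parameter_set(2, "Cell 3 50 mM NaCl overnight")
  expect_equal(resting_pd(nopump), -100.1, tolerance = 1e-2)
  ## stronger pump cycling -> more negative rest
  roots <- vapply(c(5, 80, 175, 950), function(k) {
    ps <- set_parameter(ps_apav, "kappa_oi", k)
    resting_pd(ps)
  }, numeric(1))
  expect_true(all(diff(roots) < 0))
  ## bracket without sign change is a diagnostic error
  expect_error(resting_pd(ps_apav, bracket = c(-150, -140)), "sign change")
})
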