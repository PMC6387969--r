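triangle_trace <- function(dt = 0.01) {
  t <- seq(0, 6, dt)
  v <- pmax(0, 100 * (1 - abs(t - 2) / 2))  # 0 -> 100 over 0..2, back by 4
  ap_trace(t, v)
}

test_that("trace construction validates the grid", {
  expect_error(ap_trace(c(0, 1, 1.5), c(0, 0, 0)), "non-uniform")
  expect_error(ap_trace(c(0, 1, 0.5), c(0, 0, 0)), "strictly increasing")
  expect_error(ap_trace(1:3, 1:2), "lengths differ")
})

test_that("features of degenerate and geometric traces", {
  flat <- ap_trace(seq(0, 10, 0.01), rep(-100, 1001))
  f <- ap_features(flat, c(0, 1), c(9, 10))
  expect_equal(f$peak, -100)
  expect_equal(f$rest_pre, -100)
  expect_equal(f$rest_post, -100)
  expect_true(is.na(f$duration))

  f2 <- ap_features(triangle_trace(), c(0, 0.0101), c(5.5, 6))
  expect_equal(f2$peak, 100, tolerance = 1e-6)
  expect_equal(f2$half_width, 2, tolerance = 0.02)
  expect_equal(f2$t_peak, 2, tolerance = 0.011)
})

test_that("features are invariant to time shift and sampling density", {
  tr <- triangle_trace()
  shifted <- ap_trace(tr$t + 7, tr$v)
  f1 <- ap_features(tr, c(0, 0.0101), c(5.5, 6))
  f2 <- ap_features(shifted, c(7, 7.0101), c(12.5, 13))
  expect_equal(f1$half_width, f2$half_width, tolerance = 1e-9)
  expect_equal(f1$peak, f2$peak)
  fine <- triangle_trace(dt = 0.005)
  f3 <- ap_features(fine, c(0, 0.0101), c(5.5, 6))
  expect_lt(abs(f3$half_width - f1$half_width), 0.011)
})

test_that("ensemble averaging: mean, population SD, bounds", {
  tr <- triangle_trace()
  same <- average_traces(list(tr, tr, tr))
  expect_equal(same$mean, tr$v, tolerance = 1e-12)
  expect_equal(same$sd, rep(0, length(tr$v)))
  expect_equal(same$n, 3L)

  up <- offset_trace(tr, 10); down <- offset_trace(tr, -10)
  pair <- average_traces(list(up, down))
  expect_equal(pair$mean, tr$v, tolerance = 1e-12)
  expect_equal(pair$sd, rep(10, length(tr$v)), tolerance = 1e-12)

  set.seed(1)
  peaks <- runif(6, -29, -4)
  traces <- lapply(peaks, function(p) offset_trace(tr, p - 100))
  ens <- average_traces(traces)
  expect_gte(max(ens$mean), -29)
  expect_lte(max(ens$mean), -4)
  expect_error(average_traces(list()), "empty")
})

test_that("peak alignment brings dispersed peaks to a common origin", {
  tr <- triangle_trace()
  shifted <- ap_trace(tr$t, c(tr$v[51:601], rep(0, 50)))  # peak 0.5 s early
  ens <- average_traces(list(tr, shifted), align = "peak")
  expect_equal(ens$mean[which.min(abs(ens$t))], 100, tolerance = 1e-6)
})

test_that("tonoplast subtraction propagates SD in quadrature", {
  t <- seq(0, 5, 0.01); n <- length(t)
  pm <- ensemble_trace(t, rep(-150, n), rep(4, n), 6)
  both <- ensemble_trace(t, rep(-136, n), rep(3, n), 7)
  tono <- subtract_tonoplast(both, pm)
  expect_equal(tono$mean, rep(14, n))          # +14 mV tonoplast rest
  expect_equal(tono$sd, rep(5, n))             # 3-4-5 in quadrature
  self <- subtract_tonoplast(pm, pm)
  expect_equal(self$mean, rep(0, n))
  expect_equal(self$sd, rep(4 * sqrt(2), n))
})

test_that("the shorter ensemble is extended at rest with undefined SD", {
  t_long <- seq(0, 6, 0.01); t_short <- seq(0, 4, 0.01)
  both <- ensemble_trace(t_long, seq(-136, -130, length.out = length(t_long)),
                         rep(2, length(t_long)), 7)
  pm <- ensemble_trace(t_short, rep(-150, length(t_short)),
                       rep(2, length(t_short)), 6)
  tono <- subtract_tonoplast(both, pm)
  expect_equal(length(tono$t), length(t_long))
  expect_true(all(is.na(tono$sd[t_long > 4 + 1e-9])))
  expect_false(anyNA(tono$sd[t_long <= 4 + 1e-9]))
  ## extension holds the final resting value
  expect_equal(tono$mean[length(tono$mean)], -130 - (-150))
  expect_error(subtract_tonoplast(both,
                                  ensemble_trace(t_short + 0.005,
                                                 rep(0, length(t_short)),
                                                 rep(1, length(t_short)), 2)),
               "incompatible")
})

test_that("offsets are exact and additive", {
  tr <- triangle_trace()
  expect_equal(offset_trace(tr, 0)$v, tr$v)
  expect_equal(offset_trace(offset_trace(tr, 55), 55)$v, tr$v + 110)
  expect_equal(offset_trace(ap_trace(c(0, 1), c(-41, -41)), 55)$v, c(14, 14))
})

test_that("averaging commutes with subtraction on matched ensembles", {
  set.seed(3)
  t <- seq(0, 5, 0.01); n <- length(t)
  mk <- function() ap_trace(t, -150 + cumsum(rnorm(n, 0, 0.3)))
  pm_traces <- replicate(4, mk(), simplify = FALSE)
  both_traces <- lapply(pm_traces, function(tr) offset_trace(tr, 14))
  route1 <- subtract_tonoplast(average_traces(both_traces),
                               average_traces(pm_traces))
  diffs <- mapply(function(b, p) b$v - p$v, both_traces, pm_traces)
  route2 <- rowMeans(diffs)
  expect_lt(max(abs(route1$mean - route2)), 1e-9)
})
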