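## Synthetic current-clamp recordings with the statistical structure of
## the study's data: single APs of seconds duration, additive Gaussian
## measurement noise, and lognormal cell-to-cell parameter variability
## (parameters are positive rates, so multiplicative noise is the natural
## choice; the perturbation is median-preserving).

#' Generate one synthetic recording
#'
#' Simulates the parameter set, samples at `sample_dt` and adds i.i.d.
#' Gaussian measurement noise.  `noise_sd = 0` reproduces the simulator
#' output exactly; a fixed seed reproduces the trace byte for byte.
#'
#' @param ps a [parameter_set()].
#' @param noise_sd measurement noise SD, mV.
#' @param sample_dt sampling interval, s.
#' @param seed integer seed.
#' @param t_end record length, s.
#' @return An [ap_trace()]; `meta` records the generating truth (label,
#'   seed, noise).
#' @export
generate_recording <- function(ps, noise_sd = 1, sample_dt = 0.01, seed = 1,
                               t_end = 20) {
  stopifnot(inherits(ps, "parameter_set"))
  if (noise_sd < 0) stop_arg("generate_recording: noise_sd must be >= 0")
  sim <- simulate_ap(ps, t_end = t_end, dt_out = sample_dt)
  v <- sim$trace$v
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  ap_trace(sim$trace$t, v,
           meta = c(sim$trace$meta,
                    list(noise_sd = noise_sd, seed = seed,
                         source = "synthetic")))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cell population
#'
#' Draws `n_cells` parameter sets by independent lognormal perturbation of
#' the parameters named in `cv` (median-preserving: `sdlog =
#' sqrt(log(1 + cv^2))`), simulates each, and adds measurement noise.
#' Perturbed sets whose simulation fails are resampled (the count is
#' reported).  With `train`, each record concatenates `n_aps` identical
#' APs at the given interval, emulating repetitive excitation.
#'
#' @param base a [parameter_set()].
#' @param n_cells number of cells.
#' @param cv named vector of coefficients of variation, e.g.
#'   `c(p1_prime = 0.1, p2_prime = 0.1)`.
#' @param noise_sd measurement noise SD, mV.
#' @param sample_dt sampling interval, s.
#' @param seed integer seed (drives both the parameter draws and the
#'   noise).
#' @param t_end single-AP record length, s.
#' @param train `NULL`, or `list(n_aps =, interval =)` for repetitive-AP
#'   records.
#' @return List with `traces` (list of [ap_trace()]), `truth` (data.frame
#'   of the per-cell generating parameters) and `resampled` (count).
#' @export
generate_population <- function(base, n_cells = 6,
                                cv = c(p1_prime = 0.1, p2_prime = 0.1,
                                       k_m3 = 0.1, I0 = 0.1,
                                       G_Cl_max = 0.1),
                                noise_sd = 1, sample_dt = 0.01, seed = 7,
                                t_end = 20, train = NULL) {
  stopifnot(inherits(base, "parameter_set"))
  if (any(cv < 0)) stop_arg("generate_population: cv must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  resampled <- 0L
  for (i in seq_len(n_cells)) {
    for (attempt in 1:10) {
      ps <- base
      vals <- numeric(0)
      for (nm in names(cv)) {
        v0 <- get_parameter(base, nm)
        sdlog <- sqrt(log(1 + cv[[nm]]^2))
        vi <- if (sdlog > 0) rlnorm(1, meanlog = log(v0), sdlog = sdlog)
              else v0
        ps <- set_parameter(ps, nm, vi)
        vals[nm] <- vi
      }
      sim <- tryCatch(simulate_ap(ps, t_end = t_end, dt_out = sample_dt),
                      error = function(e) NULL)
      if (!is.null(sim)) break
      resampled <- resampled + 1L
    }
    if (is.null(sim))
      stop_arg("generate_population: simulation kept failing for cell ", i)
    v <- sim$trace$v; t <- sim$trace$t
    if (!is.null(train)) {
      n_aps <- train$n_aps; interval <- train$interval
      per <- round(interval / sample_dt)
      one <- if (length(v) >= per + 1) v[1:per] else
        c(v, rep(v[length(v)], per - length(v)))
      v <- c(rep(one, n_aps), v[length(v)])
      t <- seq(0, by = sample_dt, length.out = length(v))
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
    traces[[i]] <- ap_trace(t, v, meta = list(
      cell = i, label = base$label, seed = seed, noise_sd = noise_sd,
      source = "synthetic_population"))
    truth[[i]] <- data.frame(cell = i, t(vals))
  }
  list(traces = traces, truth = do.call(rbind, truth),
       resampled = resampled)
}
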