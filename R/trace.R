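## Membrane-PD traces and the trace arithmetic used on them: feature
## extraction, ensemble averaging with SD bands, tonoplast subtraction
## with error propagation, and constant offsets.

#' Uniformly sampled membrane-PD trace
#'
#' @param t time, s; strictly increasing, uniform step (within 1e-9 s).
#' @param v membrane PD, mV.
#' @param meta named list of provenance (cell id, condition, membrane:
#'   plasma / both / tonoplast, ...).
#' @return An object of class `ap_trace`.
#' @export
ap_trace <- function(t, v, meta = list()) {
  if (length(t) != length(v)) stop_arg("ap_trace: t and v lengths differ")
  if (length(t) < 2) stop_arg("ap_trace: need at least two samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop_arg("ap_trace: t must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop_arg("ap_trace: non-uniform sampling (steps range ",
             format(min(dt)), " to ", format(max(dt)), " s)")
  structure(list(t = as.numeric(t), v = as.numeric(v), meta = meta),
            class = "ap_trace")
}

trace_dt <- function(tr) (tr$t[length(tr$t)] - tr$t[1]) / (length(tr$t) - 1)

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples, %.3g s at dt = %.3g s, PD %.1f..%.1f mV\n",
              length(x$t), max(x$t) - min(x$t), trace_dt(x),
              min(x$v), max(x$v)))
  invisible(x)
}

#' Ensemble trace: pointwise mean with SD band
#'
#' @param t time, s.
#' @param mean pointwise mean PD, mV.
#' @param sd pointwise standard deviation, mV (NA where undefined).
#' @param n number of traces averaged.
#' @return An object of class `ensemble_trace`.
#' @export
ensemble_trace <- function(t, mean, sd, n) {
  if (length(t) != length(mean) || length(t) != length(sd))
    stop_arg("ensemble_trace: component lengths differ")
  if (any(sd < 0, na.rm = TRUE)) stop_arg("ensemble_trace: sd must be >= 0")
  if (n < 1) stop_arg("ensemble_trace: n must be >= 1")
  structure(list(t = as.numeric(t), mean = as.numeric(mean),
                 sd = as.numeric(sd), n = as.integer(n)),
            class = "ensemble_trace")
}

first_crossing_up <- function(t, v, level) {
  idx <- which(v[-1] > level & v[-length(v)] <= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

last_crossing_down <- function(t, v, level) {
  idx <- which(v[-1] <= level & v[-length(v)] > level)
  if (!length(idx)) return(NA_real_)
  i <- idx[length(idx)]
  t[i] + (v[i] - level) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
}

#' Extract AP features from a trace
#'
#' Operational definitions: `peak` is the trace maximum; `rest_pre` /
#' `rest_post` are mean PDs over the given windows; `half_width` is the
#' width of the interval where the PD exceeds the midpoint between
#' `rest_pre` and `peak` (linear interpolation at the crossings);
#' `duration` runs from the first upward crossing of `rest_pre + guard` to
#' the last downward crossing of `rest_post + guard`.  Features whose
#' crossings do not exist are returned as `NA`, not as errors.
#'
#' @param tr an [ap_trace()].
#' @param rest_window,post_window `c(from, to)` in s, inside the trace.
#' @param guard guard band above rest defining the AP duration, mV.
#' @return Named list: `peak, t_peak, duration, half_width, rest_pre,
#'   rest_post`.
#' @export
ap_features <- function(tr, rest_window = c(0, 1),
                        post_window = c(max(tr$t) - 2, max(tr$t)),
                        guard = 5) {
  stopifnot(inherits(tr, "ap_trace"))
  span <- range(tr$t)
  for (w in list(rest_window, post_window))
    if (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9 || w[2] <= w[1])
      stop_arg("ap_features: windows must be ordered and inside the trace")
  in_win <- function(w) tr$v[tr$t >= w[1] & tr$t <= w[2]]
  rest_pre <- mean(in_win(rest_window))
  rest_post <- mean(in_win(post_window))
  peak <- max(tr$v)
  t_peak <- tr$t[which.max(tr$v)]
  half_level <- (rest_pre + peak) / 2
  hw_up <- first_crossing_up(tr$t, tr$v, half_level)
  hw_down <- last_crossing_down(tr$t, tr$v, half_level)
  half_width <- if (is.na(hw_up) || is.na(hw_down)) NA_real_ else hw_down - hw_up
  d_up <- first_crossing_up(tr$t, tr$v, rest_pre + guard)
  d_down <- last_crossing_down(tr$t, tr$v, rest_post + guard)
  duration <- if (is.na(d_up) || is.na(d_down)) NA_real_ else d_down - d_up
  list(peak = peak, t_peak = t_peak, duration = duration,
       half_width = half_width, rest_pre = rest_pre, rest_post = rest_post)
}

#' Average an ensemble of traces
#'
#' Pointwise mean and population standard deviation (denominator n) after
#' alignment; the result covers the overlap region of the aligned traces.
#'
#' @param traces list of [ap_trace()] objects sharing one sampling step.
#' @param align `"stimulus"` (use the traces' own clocks, t = 0 at
#'   stimulus) or `"peak"` (shift each trace so its peak sits at t = 0).
#' @return An [ensemble_trace()].
#' @export
average_traces <- function(traces, align = c("stimulus", "peak")) {
  align <- match.arg(align)
  if (!length(traces)) stop_arg("average_traces: empty trace list")
  stopifnot(all(vapply(traces, inherits, logical(1), "ap_trace")))
  dts <- vapply(traces, trace_dt, numeric(1))
  if (max(dts) - min(dts) > 1e-9)
    stop_arg("average_traces: traces must share a sampling step")
  dt <- dts[1]
  shifted <- lapply(traces, function(tr) {
    shift <- if (align == "peak") tr$t[which.max(tr$v)] else 0
    list(t = tr$t - shift, v = tr$v)
  })
  lo <- max(vapply(shifted, function(s) s$t[1], numeric(1)))
  hi <- min(vapply(shifted, function(s) s$t[length(s$t)], numeric(1)))
  if (hi - lo < dt) stop_arg("average_traces: no overlap after alignment")
  grid <- seq(0, floor((hi - lo) / dt + 1e-9)) * dt + lo
  vals <- vapply(shifted, function(s) {
    approx(s$t, s$v, xout = grid)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  m <- rowMeans(vals)
  s <- sqrt(rowMeans((vals - m)^2))  # population SD
  ensemble_trace(grid, m, s, n = length(traces))
}

#' Tonoplast AP by subtraction
#'
#' The PD recorded in the vacuole is the series sum of the plasma-membrane
#' and tonoplast PDs, so the tonoplast component is `both - pm`, with the
#' SDs combined in quadrature: `sd = sqrt(sd_both^2 + sd_pm^2)`.  The
#' shorter ensemble is extended at its final resting value; the SD is
#' undefined (NA) over the extension.
#'
#' @param both ensemble recorded across both membranes.
#' @param pm ensemble recorded across the plasma membrane.
#' @return An [ensemble_trace()] for the tonoplast.
#' @export
subtract_tonoplast <- function(both, pm) {
  stopifnot(inherits(both, "ensemble_trace"), inherits(pm, "ensemble_trace"))
  dtb <- (both$t[length(both$t)] - both$t[1]) / (length(both$t) - 1)
  dtp <- (pm$t[length(pm$t)] - pm$t[1]) / (length(pm$t) - 1)
  if (abs(dtb - dtp) > 1e-9 || abs(both$t[1] - pm$t[1]) > 1e-9)
    stop_arg("subtract_tonoplast: incompatible time grids")
  n <- max(length(both$t), length(pm$t))
  extend <- function(e) {
    k <- n - length(e$t)
    if (k == 0) return(e)
    ensemble_trace(c(e$t, e$t[length(e$t)] + dtb * seq_len(k)),
                   c(e$mean, rep(e$mean[length(e$mean)], k)),
                   c(e$sd, rep(NA_real_, k)), e$n)
  }
  b <- extend(both); p <- extend(pm)
  ensemble_trace(b$t, b$mean - p$mean, sqrt(b$sd^2 + p$sd^2),
                 n = min(both$n, pm$n))
}

#' Shift a trace by a constant PD offset
#'
#' Used e.g. to reconstruct the tonoplast PD from a vacuolar recording by
#' adding back the approximate PD across the plasma membrane.
#'
#' @param tr an [ap_trace()].
#' @param dv offset, mV.
#' @return The shifted [ap_trace()].
#' @export
offset_trace <- function(tr, dv) {
  stopifnot(inherits(tr, "ap_trace"))
  ap_trace(tr$t, tr$v + dv, tr$meta)
}

#' Convert an ensemble mean to a plain trace
#'
#' @param e an [ensemble_trace()].
#' @return An [ap_trace()] carrying the ensemble mean.
#' @export
ensemble_mean_trace <- function(e) {
  stopifnot(inherits(e, "ensemble_trace"))
  ap_trace(e$t, e$mean, meta = list(source = "ensemble_mean", n = e$n))
}
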