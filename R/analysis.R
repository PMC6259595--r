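#' Detect spike times by threshold crossing
#'
#' Upward crossings of `threshold` by the membrane potential, with linear
#' interpolation between samples. Returns a strictly increasing vector of
#' crossing times (possibly empty).
#'
#' @param trajectory A `membrane_trajectory` or any data.frame with `time`
#'   and `v` columns.
#' @param threshold Crossing threshold, mV.
#' @return Numeric vector of times, ms.
#' @export
detect_spikes <- function(trajectory, threshold = -30) {
  t <- trajectory$time
  v <- trajectory$v
  if (length(v) < 2L) return(numeric(0))
  below <- v[-length(v)] < threshold
  above <- v[-1] >= threshold
  k <- which(below & above)
  if (!length(k)) return(numeric(0))
  frac <- (threshold - v[k]) / (v[k + 1] - v[k])
  t[k] + frac * (t[k + 1] - t[k])
}

#' Spike-train metrics of a trajectory
#'
#' Period (mean inter-spike interval over the last `n_cycles` cycles after
#' discarding `transient` ms), peak-to-trough amplitude over those cycles,
#' maximal depolarisation rate, firing rate and spike count. The maximal
#' rate uses the recorded instantaneous derivative (`dvdt` column, exact
#' values of the vector field along the solution) when present, otherwise
#' finite differences. mV/ms equals V/s numerically.
#'
#' @param trajectory A `membrane_trajectory` (or data.frame with `time`,
#'   `v` and optionally `dvdt`).
#' @param threshold Spike threshold, mV.
#' @param n_cycles Number of final cycles entering the metrics.
#' @param transient Initial time discarded, ms.
#' @return Object of class `spike_metrics`: list with `period` (ms),
#'   `amplitude` (mV), `max_dvdt` (V/s), `firing_rate` (Hz), `n_spikes`.
#' @export
spike_metrics <- function(trajectory, threshold = -30, n_cycles = 5,
                          transient = 2000) {
  keep <- trajectory$time >= transient
  tr <- trajectory[keep, , drop = FALSE]
  crossings <- detect_spikes(tr, threshold)
  if (length(crossings) < n_cycles + 1L) {
    stop(sprintf(
      "not periodic: %d crossings of %g mV after %g ms (need %d)",
      length(crossings), threshold, transient, n_cycles + 1L))
  }
  last <- utils::tail(crossings, n_cycles + 1L)
  period <- mean(diff(last))
  win <- tr$time >= last[1] & tr$time <= last[length(last)]
  amplitude <- max(tr$v[win]) - min(tr$v[win])
  max_dvdt <- if ("dvdt" %in% names(tr)) {
    max(tr$dvdt[win])
  } else {
    max(diff(tr$v[win]) / diff(tr$time[win]))
  }
  structure(
    list(period = period, amplitude = amplitude, max_dvdt = max_dvdt,
         firing_rate = 1000 / period, n_spikes = length(crossings)),
    class = "spike_metrics"
  )
}

#' @export
print.spike_metrics <- function(x, ...) {
  cat(sprintf(
    "Spike metrics: period %.2f ms (%.2f Hz), amplitude %.2f mV, max dv/dt %.3f V/s, %d spikes\n",
    x$period, x$firing_rate, x$amplitude, x$max_dvdt, x$n_spikes))
  invisible(x)
}

#' Rheobase by bisection
#'
#' The minimal rectangular current-step amplitude that elicits sustained
#' repetitive spiking, located by bisection to within `resolution` pA.
#' Sustained spiking means at least `min_spikes` spikes in the final
#' `window` ms of a `step_duration` ms step. The model must be silent at
#' `stim_lo` and spiking at `stim_hi`; otherwise an error names the
#' failing endpoint.
#'
#' @param model A `membrane_model` (typically [fs_model()]).
#' @param stim_lo,stim_hi Bracketing step amplitudes, pA.
#' @param resolution Bisection resolution, pA.
#' @param step_duration Step duration, ms.
#' @param onset Step onset, ms.
#' @param threshold Spike threshold, mV.
#' @param min_spikes,window Sustained-spiking criterion.
#' @param sample_dt Sampling interval for the test simulations, ms.
#' @param ... Further arguments for [simulate.membrane_model()].
#' @return Rheobase estimate in pA (upper end of the final bracket), with
#'   attribute `bracket`.
#' @export
find_rheobase <- function(model, stim_lo = 0, stim_hi = 100, resolution = 1,
                          step_duration = 2000, onset = 500, threshold = 0,
                          min_spikes = 3, window = 500, sample_dt = 0.05,
                          ...) {
  stopifnot(stim_lo < stim_hi, resolution > 0)
  tmax <- onset + step_duration
  spiking <- function(amp) {
    traj <- simulate(model, tmax = tmax, sample_dt = sample_dt, stim = amp,
                     stim_onset = onset, stim_duration = step_duration, ...)
    tail_win <- traj[traj$time >= tmax - window, , drop = FALSE]
    length(detect_spikes(tail_win, threshold)) >= min_spikes
  }
  if (spiking(stim_lo)) {
    stop(sprintf("no bracket: model already spiking at stim_lo = %g pA",
                 stim_lo))
  }
  if (!spiking(stim_hi)) {
    stop(sprintf("no bracket: model still silent at stim_hi = %g pA",
                 stim_hi))
  }
  lo <- stim_lo; hi <- stim_hi
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (spiking(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bracket = c(lo, hi))
}

#' Per-cycle extrema of the L-type Ca current
#'
#' Splits a SAN trajectory into cycles at upward threshold crossings and
#' locates the interior local minima and maxima of the `J_CaL` trace in
#' each complete cycle. With default parameters the pacemaker's Ca current
#' shows exactly two local minima (two peaks of inward current) per cycle,
#' separated by a local maximum near the action-potential peak — a
#' consequence of the voltage trajectory passing twice through the region
#' of maximal driving force, not of gating.
#'
#' @param trajectory A SAN `membrane_trajectory` containing a `J_CaL`
#'   column.
#' @param threshold Cycle-splitting threshold, mV.
#' @param transient Initial time discarded, ms.
#' @return A data.frame with columns `cycle`, `type` (`"min"`/`"max"`),
#'   `time` and `value` (pA/pF).
#' @export
ca_current_extrema <- function(trajectory, threshold = -30,
                               transient = 2000) {
  if (!"J_CaL" %in% names(trajectory)) {
    stop("trajectory has no J_CaL trace (not a SAN simulation?)")
  }
  tr <- trajectory[trajectory$time >= transient, , drop = FALSE]
  crossings <- detect_spikes(tr, threshold)
  if (length(crossings) < 2L) stop("need at least one full cycle")
  out <- list()
  for (k in seq_len(length(crossings) - 1L)) {
    win <- tr$time >= crossings[k] & tr$time < crossings[k + 1L]
    j <- tr$J_CaL[win]
    tt <- tr$time[win]
    s <- sign(diff(j))
    nz <- which(s != 0)
    if (length(nz) < 2L) next
    rows <- list()
    for (m in seq_len(length(nz) - 1L)) {
      if (s[nz[m]] != s[nz[m + 1L]]) {
        # the extremum lies in the (possibly flat) run between the two
        # opposite-signed differences
        rng <- (nz[m] + 1L):nz[m + 1L]
        if (s[nz[m + 1L]] > 0) {
          i <- rng[which.min(j[rng])]
          ty <- "min"
        } else {
          i <- rng[which.max(j[rng])]
          ty <- "max"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cycle = k, type = ty, time = tt[i], value = j[i])
      }
    }
    if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(out)) {
    return(data.frame(cycle = integer(0), type = character(0),
                      time = numeric(0), value = numeric(0)))
  }
  do.call(rbind, out)
}
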