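#' Current-voltage dataset
#'
#' A labelled set of paired (voltage, current) observations with strictly
#' increasing voltages, the input to [fit_iv()].
#'
#' @param voltages Command potentials, mV (strictly increasing, length >= 3).
#' @param currents Measured currents, pA (same length).
#' @param label Dataset label.
#' @return Object of class `iv_dataset` (also a data.frame with columns
#'   `voltage_mV`, `current_pA`).
#' @export
iv_dataset <- function(voltages, currents, label = "IV data") {
  if (length(voltages) != length(currents) || length(voltages) < 3L) {
    stop("need >= 3 paired (voltage, current) observations")
  }
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly increasing")
  if (!all(is.finite(voltages)) || !all(is.finite(currents))) {
    stop("voltages and currents must be finite")
  }
  structure(
    data.frame(voltage_mV = voltages, current_pA = currents),
    label = label,
    class = c("iv_dataset", "data.frame")
  )
}

#' @export
print.iv_dataset <- function(x, ...) {
  cat(sprintf("IV dataset '%s': %d points, %g to %g mV\n",
              attr(x, "label"), nrow(x), min(x$voltage_mV), max(x$voltage_mV)))
  print.data.frame(x, ...)
  invisible(x)
}

# Whole-cell currents of AMPA-Kainate receptors expressed in oocytes from
# GluR3 cRNA alone or GluR1+GluR3, recorded in Ca ringer (the charge carrier
# is Ca2+), digitized from the published figure. 14 voltage points each.
.ampa_kainate <- list(
  voltage_mV = c(-99.6354, -89.7348, -80.4530, -70.8619, -60.3425,
                 -50.5967, -40.6961, -30.7956, -21.2044, -11.1492,
                 -1.40331, 8.80663, 19.0166, 28.7624),
  GluR3 = c(-347.253, -223.077, -148.352, -104.396, -69.2308,
            -38.4615, -14.2857, 9.89011, 27.4725, 50.5495,
            64.8352, 89.011, 128.571, 205.495),
  `GluR1+GluR3` = c(-597.802, -423.077, -272.527, -151.648, -87.9121,
                    -45.0549, -21.978, 2.1978, 12.0879, 25.2747,
                    39.5604, 63.7363, 83.5165, 119.78)
)

#' AMPA-Kainate receptor IV data
#'
#' Embedded current-voltage measurements from oocytes expressing
#' AMPA-Kainate receptors built from GluR3 subunits alone or from a
#' GluR1+GluR3 mixture, recorded in a Ca ringer (the current is carried by
#' Ca\eqn{^{2+}}). Subunit composition changes both the reversal potential
#' and the degree of rectification, making these the canonical test data
#' for the rectification-bias fit.
#'
#' @param which `"GluR3"` or `"GluR1+GluR3"`.
#' @return An [iv_dataset()] with 14 points.
#' @examples
#' ampa_kainate_iv("GluR3")
#' @export
ampa_kainate_iv <- function(which = c("GluR3", "GluR1+GluR3")) {
  which <- match.arg(which)
  iv_dataset(.ampa_kainate$voltage_mV, .ampa_kainate[[which]], label = which)
}

#' Simulate an IV dataset from known parameters
#'
#' Evaluates [model_current()] on a voltage grid and adds i.i.d. Gaussian
#' noise, for parameter-recovery studies.
#'
#' @param v_o Reversal potential, mV.
#' @param b Bias in \eqn{[0, 1]}.
#' @param rq Amplitude, pA.
#' @param v_grid Voltage grid, mV (strictly increasing).
#' @param noise_sd Noise standard deviation, pA (>= 0).
#' @param seed Integer seed (required for reproducibility).
#' @param charge,v_T Passed to [model_current()].
#' @return An [iv_dataset()].
#' @export
generate_synthetic_iv <- function(v_o, b, rq, v_grid = seq(-100, 30, length.out = 25),
                                  noise_sd = 5, seed, charge = 1, v_T = 25.7) {
  stopifnot(noise_sd >= 0)
  if (missing(seed)) stop("`seed` must be supplied")
  set.seed(seed)
  i <- model_current(v_grid, v_o, b, rq, charge = charge, v_T = v_T) +
    stats::rnorm(length(v_grid), 0, noise_sd)
  iv_dataset(v_grid, i,
             label = sprintf("synthetic (v_o=%g, b=%g, rq=%g)", v_o, b, rq))
}

#' Read or write IV data as CSV
#'
#' Two-column CSV with mandatory header `voltage_mV,current_pA`.
#'
#' @param path File path.
#' @param dataset An [iv_dataset()].
#' @param label Label for the dataset read from file.
#' @return `read_iv_csv()` returns an `iv_dataset`; `write_iv_csv()`
#'   returns `path` invisibly.
#' @export
read_iv_csv <- function(path, label = basename(path)) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)))
  )
  if (!all(c("voltage_mV", "current_pA") %in% names(df))) {
    stop(sprintf("'%s': header must contain voltage_mV and current_pA", path))
  }
  bad <- which(!is.finite(df$voltage_mV) | !is.finite(df$current_pA))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric value at data line %d", path, bad[1]))
  }
  iv_dataset(df$voltage_mV, df$current_pA, label = label)
}

#' @rdname read_iv_csv
#' @export
write_iv_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "iv_dataset"))
  df <- data.frame(voltage_mV = format_sig(dataset$voltage_mV),
                   current_pA = format_sig(dataset$current_pA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed 10-significant-digit formatting so identical data give identical
# files and round trips are lossless to better than 1e-9 relative
format_sig <- function(x) formatC(x, digits = 10, format = "g")
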