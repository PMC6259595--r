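#' Taylor approximation of the general current
#'
#' Series expansion of the general current of an electrogenic mechanism
#' about its reversal potential \eqn{v_o/\eta}, in powers of
#' \eqn{x = (\eta v - v_o)/v_T}:
#' \deqn{i \approx q \eta r [x + (b - 1/2) x^2 + \tfrac{3b^2 - 3b + 1}{6} x^3].}
#' Order 1 is the conductance-based (linear) current; rectification enters
#' only from order 2 upward, which is why conductance-based models cannot
#' rectify.
#'
#' @inheritParams flux
#' @param order Truncation order, 1, 2 or 3.
#' @return Current density in pA/\eqn{\mu m^2}.
#' @seealso [conductance_approx()]
#' @export
taylor_current <- function(mechanism, v, order = 3,
                           constants = transport_constants()) {
  constants <- as_constants(constants)
  if (!order %in% 1:3) stop("`order` must be 1, 2 or 3")
  et <- eta(mechanism)
  if (et == 0L) stop("Taylor current requires an electrogenic mechanism")
  b <- mechanism$bias
  vo <- as.numeric(reversal_vo(mechanism, constants))
  x <- (et * v - vo) / constants$v_T
  coefs <- c(1, b - 0.5, (3 * b^2 - 3 * b + 1) / 6)[seq_len(order)]
  acc <- 0
  for (k in seq_len(order)) acc <- acc + coefs[k] * x^k
  Q_PA_MS * et * mechanism$rate * acc
}

#' Conductance-based (linear) approximation
#'
#' The tangent of the general current at its reversal potential:
#' \eqn{i \approx g (v - v_o/\eta)} with conductance density
#' \eqn{g = \eta^2 q r / v_T} (nS/\eqn{\mu m^2}). This is exactly the
#' order-1 Taylor approximation, so `g` equals the slope of the full
#' current at the reversal potential for every bias.
#'
#' @inheritParams flux
#' @return Object of class `conductance_approx`: list with `g`
#'   (nS/\eqn{\mu m^2}), `reversal` (mV) and a `predict`-style function
#'   element `current(v)`.
#' @examples
#' ca <- conductance_approx(mechanism_catalog("Na channel"))
#' ca$g; ca$reversal
#' @export
conductance_approx <- function(mechanism, constants = transport_constants()) {
  constants <- as_constants(constants)
  et <- eta(mechanism)
  if (et == 0L) stop("conductance approximation requires eta != 0")
  g <- et^2 * Q_PA_MS * mechanism$rate / constants$v_T
  vrev <- as.numeric(reversal_vo(mechanism, constants)) / et
  structure(
    list(g = g, reversal = vrev,
         current = function(v) g * (v - vrev)),
    class = "conductance_approx"
  )
}

#' @export
print.conductance_approx <- function(x, ...) {
  cat(sprintf("Linear current: i = g (v - v_rev), g = %g nS/um^2, v_rev = %g mV\n",
              x$g, x$reversal))
  invisible(x)
}

#' Goldman-Hodgkin-Katz (constant-field) current
#'
#' \deqn{I_x = g_x v \frac{x_0 - x_1 e^{z_x v / v_T}}{1 - e^{z_x v / v_T}},}
#' the classical electrodiffusion current for an ion of valence `z` with
#' outer/inner concentrations `conc_out`/`conc_in`. The apparent singularity
#' at \eqn{v = 0} is removable; for \eqn{|z v / v_T| < 10^{-4}} the quotient
#' is evaluated by its second-order series, giving the analytic limit
#' \eqn{-g v_T (x_0 - x_1)/z} at 0.
#'
#' @param g Conductance-like amplitude \eqn{g_x}.
#' @param z Valence.
#' @param conc_out,conc_in Concentrations (> 0).
#' @param v Transmembrane potential, mV (vectorised).
#' @inheritParams nernst_potential
#' @return Current (units of `g` times mV times concentration).
#' @seealso [ghk_amplitude()] for the bridge to the general bi-exponential
#'   current.
#' @export
ghk_current <- function(g, z, conc_out, conc_in, v,
                        constants = transport_constants()) {
  constants <- as_constants(constants)
  if (conc_out <= 0 || conc_in <= 0) stop("concentrations must be positive")
  if (z == 0) stop("GHK current requires a charged species")
  u <- z * v / constants$v_T
  small <- abs(u) < 1e-4
  out <- numeric(length(v))
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- g * v[!small] *
      (conc_out - conc_in * exp(us)) / (1 - exp(us))
  }
  if (any(small)) {
    # v * N/D = (v_T/z) * u N / D; series of u N / D to second order in u
    us <- u[small]
    out[small] <- g * (constants$v_T / z) *
      (conc_in * us - (conc_out - conc_in) / (1 + us / 2))
  }
  out
}

#' Amplitude bridging GHK to the general bi-exponential current
#'
#' The GHK current can be rewritten exactly, for any bias `b`, as
#' \eqn{I_x = A_x [e^{b y} - e^{(b-1) y}]} with
#' \eqn{y = z_x (v - v_x)/v_T} and
#' \deqn{A_x = \frac{g v\, x_1^{1-b} x_0^{b}}{e^{b z_x v/v_T} - e^{(b-1) z_x v/v_T}}.}
#' `A_x` depends only weakly on `v` and is often frozen at a reference
#' voltage; set `freeze_at` to obtain that constant (default reference: the
#' Nernst potential of the ion, where the general current crosses zero).
#'
#' @inheritParams ghk_current
#' @param b Bias used in the bi-exponential representation.
#' @param freeze_at `NULL` for the exact v-dependent amplitude, `"nernst"`
#'   for the constant frozen at \eqn{v_x}, or a number (mV).
#' @return Amplitude values (same length as `v` unless frozen).
#' @export
ghk_amplitude <- function(g, z, conc_out, conc_in, v, b = 0.5,
                          freeze_at = NULL,
                          constants = transport_constants()) {
  constants <- as_constants(constants)
  if (!is.null(freeze_at)) {
    v <- if (identical(freeze_at, "nernst")) {
      nernst_potential(z, conc_out, conc_in, constants)
    } else freeze_at
  }
  u <- z * v / constants$v_T
  num <- g * v * conc_in^(1 - b) * conc_out^b
  den <- exp(b * u) - exp((b - 1) * u)
  small <- abs(u) < 1e-4
  out <- num / den
  if (any(small)) {
    # both v and den -> 0 linearly: v/den -> v_T/z at u = 0
    out[small] <- g * (constants$v_T / z) * conc_in^(1 - b) * conc_out^b /
      (1 + (b - 0.5) * u[small])
  }
  out
}

#' Hyperbolic-sine current (symmetric transport)
#'
#' For a symmetric bias \eqn{b = 1/2} the general current collapses to
#' \eqn{i = 2 q \eta r \sinh[(\eta v - v_o)/(2 v_T)]}. For a Ca channel
#' (\eqn{\eta = -2}, \eqn{v_o = -2 v_{Ca}}) this is identically
#' \eqn{4 q r \sinh[(v - v_{Ca})/v_T]}.
#'
#' @inheritParams flux
#' @return Current density, pA/\eqn{\mu m^2}.
#' @export
sinh_current <- function(mechanism, v, constants = transport_constants()) {
  constants <- as_constants(constants)
  if (abs(mechanism$bias - 0.5) > 1e-12) {
    stop("sinh form requires bias b = 1/2")
  }
  et <- eta(mechanism)
  if (et == 0L) stop("sinh current requires an electrogenic mechanism")
  vo <- as.numeric(reversal_vo(mechanism, constants))
  2 * Q_PA_MS * et * mechanism$rate *
    sinh((et * v - vo) / (2 * constants$v_T))
}

#' Fully rectified (one-sided saturating) currents
#'
#' At the extreme biases the general current saturates in one direction:
#' \eqn{b = 0} gives \eqn{i = q \eta r [1 - e^{(v_o - \eta v)/v_T}]}
#' (flux limited in the forward direction; for a K channel this is the
#' classical inward rectifier, saturating at \eqn{q r} for large
#' depolarisations), and \eqn{b = 1} gives
#' \eqn{i = q \eta r [e^{(\eta v - v_o)/v_T} - 1]} (outward rectifier).
#'
#' @inheritParams flux
#' @return Current density, pA/\eqn{\mu m^2}.
#' @export
rectifier_limit_current <- function(mechanism, v,
                                    constants = transport_constants()) {
  constants <- as_constants(constants)
  b <- mechanism$bias
  if (!b %in% c(0, 1)) stop("rectifier limit requires bias 0 or 1")
  et <- eta(mechanism)
  if (et == 0L) stop("rectifier limit requires an electrogenic mechanism")
  vo <- as.numeric(reversal_vo(mechanism, constants))
  x <- (et * v - vo) / constants$v_T
  if (b == 0) {
    Q_PA_MS * et * mechanism$rate * (1 - exp(-x))
  } else {
    Q_PA_MS * et * mechanism$rate * (exp(x) - 1)
  }
}

#' Na-K pump current in concentration-explicit form
#'
#' The inwardly rectifying (\eqn{b = 0}) Na-K ATPase current written
#' directly in terms of the transported concentrations:
#' \deqn{i_{NaK} = q r [1 - ([Na]_0/[Na]_1)^3 ([K]_1/[K]_0)^2
#'   e^{(v_{ATP} - v)/v_T}].}
#' Composing the reversal potential from the same concentrations
#' (\eqn{v_{NaK} = v_{ATP} + 3 v_{Na} - 2 v_K}) makes this identical to the
#' reversal-potential form \eqn{q r [1 - e^{(v_{NaK} - v)/v_T}]}. The
#' asymmetry of the exponential explains why raising intracellular Na (or
#' extracellular K) changes the pump current much more steeply below the
#' reversal potential than above it.
#'
#' @param na_out,na_in,k_out,k_in Na and K concentrations (mM).
#' @param r Pump rate, molecules/ms/\eqn{\mu m^2}.
#' @param v Transmembrane potential, mV (vectorised).
#' @param v_atp ATP hydrolysis potential, mV.
#' @inheritParams nernst_potential
#' @return Current density, pA/\eqn{\mu m^2}.
#' @export
nak_concentration_form <- function(na_out, na_in, k_out, k_in, r, v,
                                   v_atp = -450,
                                   constants = transport_constants()) {
  constants <- as_constants(constants)
  if (any(c(na_out, na_in, k_out, k_in) <= 0)) {
    stop("concentrations must be strictly positive")
  }
  Q_PA_MS * r * (1 - (na_out / na_in)^3 * (k_in / k_out)^2 *
                   exp((v_atp - v) / constants$v_T))
}
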