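#' Physical constants and the thermal voltage
#'
#' Bundles Boltzmann's constant, the elementary charge and an absolute
#' temperature, and derives the thermal voltage \eqn{v_T = kT/q} (in mV),
#' the natural voltage scale of all Boltzmann factors used throughout the
#' package. Energies are carried internally in units of \eqn{kT}
#' (dimensionless), so the temperature enters every formula only through
#' \eqn{v_T}.
#'
#' @param temperature Absolute temperature in kelvin. Default 310 K
#'   (mammalian physiological temperature), giving \eqn{v_T \approx 26.7} mV.
#'
#' @return An object of class `transport_constants`: a list with elements
#'   `boltzmann_k` (J/K), `elementary_q` (C), `temperature` (K) and
#'   `v_T` (mV). `v_T` is always derived from the temperature, never set
#'   independently.
#'
#' @examples
#' transport_constants()          # 310 K, v_T ~ 26.7 mV
#' transport_constants(295)$v_T   # room temperature
#' @export
transport_constants <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)")
  }
  k <- 1.380649e-23
  q <- 1.602176634e-19
  structure(
    list(
      boltzmann_k = k,
      elementary_q = q,
      temperature = temperature,
      v_T = 1000 * k * temperature / q
    ),
    class = "transport_constants"
  )
}

#' @export
print.transport_constants <- function(x, ...) {
  cat(sprintf("Transport constants: T = %.2f K, v_T = kT/q = %.4f mV\n",
              x$temperature, x$v_T))
  invisible(x)
}

# elementary charge expressed so that (charge) * (molecules/ms/um^2) is a
# current density in pA/um^2: 1 molecule/ms * q C = q * 1e15 pA
Q_PA_MS <- 1.602176634e-4

# and so that q*r/v_T is a conductance density in nS/um^2 (pA/mV = nS)
as_constants <- function(constants) {
  if (inherits(constants, "transport_constants")) return(constants)
  stop("`constants` must be created with transport_constants()")
}
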