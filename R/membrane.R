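#' Bi-exponential driving-force factor
#'
#' \eqn{\varphi(x, b) = e^{b x} - e^{(b - 1) x}}: the dimensionless
#' driving-force factor of the general current, evaluated at the normalised
#' distance \eqn{x} from the reversal point. At \eqn{b = 1/2} it equals
#' \eqn{2 \sinh(x/2)}; it vanishes at \eqn{x = 0} and is increasing in
#' \eqn{x} for every \eqn{b \in [0, 1]}.
#'
#' @param x Normalised driving force (vectorised).
#' @param b Bias in \eqn{[0, 1]}.
#' @return Dimensionless factor.
#' @export
phi_bias <- function(x, b) {
  if (b < 0 || b > 1) stop("`b` must lie in [0, 1]")
  exp(b * x) - exp((b - 1) * x)
}

#' Voltage-dependent gating steady state
#'
#' Logistic steady-state activation
#' \eqn{F_u(v) = e^{x}/(1 + e^{x})} with
#' \eqn{x = g_u (v - v_u)/v_T}: 1/2 at the half-activation potential
#' `v_u`, increasing in `v` with steepness `g_u`.
#'
#' @param v Potential, mV (vectorised).
#' @param g_u Dimensionless slope factor.
#' @param v_u Half-activation potential, mV.
#' @inheritParams nernst_potential
#' @return Value in (0, 1).
#' @export
gating_steady_state <- function(v, g_u, v_u,
                                constants = transport_constants()) {
  constants <- as_constants(constants)
  x <- g_u * (v - v_u) / constants$v_T
  stats::plogis(x)
}

#' Voltage-dependent gating rate
#'
#' \deqn{R_w(v) = r_w [e^{b_w g_w (v - v_w)/v_T} +
#'   e^{(b_w - 1) g_w (v - v_w)/v_T}],}
#' the rate of the activation variable's approach to steady state. It has
#' its minimum \eqn{2 r_w} at the half-activation potential and, for
#' \eqn{b_w = 1/2}, the shape of a hyperbolic cosine.
#'
#' @param v Potential, mV (vectorised).
#' @param r_w Base rate, ms\eqn{^{-1}}.
#' @param b_w Bias of the conformational change, in \eqn{[0, 1]}.
#' @param g_w Slope factor.
#' @param v_w Half-activation potential, mV.
#' @inheritParams nernst_potential
#' @return Rate in ms\eqn{^{-1}}.
#' @export
gating_rate <- function(v, r_w, b_w, g_w, v_w,
                        constants = transport_constants()) {
  constants <- as_constants(constants)
  if (r_w <= 0) stop("`r_w` must be > 0")
  x <- g_w * (v - v_w) / constants$v_T
  r_w * (exp(b_w * x) + exp((b_w - 1) * x))
}

#' Parameters of the sinoatrial-node pacemaker model
#'
#' Default parameter set of the three-variable (v, w, c) cardiac
#' sinoatrial-node model: normalised current amplitudes (pA/pF) for the
#' L-type Ca channel, delayed-rectifier K channel, Na-K ATPase and Na-Ca
#' exchanger; fixed Nernst/ATP potentials; gating parameters for the Ca
#' activation (`g_m`, `v_m`) and the K activation variable w (`g_w`, `v_w`,
#' `r_w`, `b_w`, `k_w`); per-current rectification biases; and the
#' intracellular Ca balance (resting concentration `c_inf` in uM, removal
#' rate `r_c` in 1/ms, current-to-concentration factor `k_c`, extracellular
#' Ca `ca_out` in uM). Rates are on the millisecond scale throughout
#' (v is in mV, currents in pA/pF = mV/ms).
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @seealso [san_model()]
#' @export
san_params <- function(...) {
  p <- list(
    C_M = 30,                         # pF
    a_Ca = 1 / 30, a_K = 100 / 30,    # pA/pF
    a_NaK = 1 / 30, a_NaCa = 3 / 30,
    v_ATP = -420, v_Na = 60, v_K = -89,   # mV
    v_m = -25, g_m = 5,               # L-type Ca activation
    v_w = -25, g_w = 3.6,             # K activation variable
    r_w = 0.005,                      # 1/ms
    k_w = 0.3,                        # exponent on w in its own flow
    b_w = 0.35,                       # bias of the gating rate
    b_NaK = 0.35, b_K = 0.1, b_NaCa = 0.5, b_Ca = 0.5,
    c_inf = 0.1,                      # uM
    r_c = 0.02,                       # 1/ms
    k_c = 0.00554,                    # uM per (pA/pF * ms)
    ca_out = 2000,                    # uM (2 mM)
    ca_inact = TRUE                   # (1 - w) inactivation on the Ca current
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown SAN parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$c_inf > 0, p$r_w > 0, p$ca_out > 0)
  p
}

#' Parameters of the fast-spiking interneuron model
#'
#' Default parameter set of the two-variable (v, w) striatal fast-spiking
#' interneuron model: whole-cell current amplitudes (pA) for the transient
#' Na current, delayed-rectifier K current and Na-K ATPase; membrane
#' capacitance; fixed potentials; gating parameters for Na activation
#' (`g_mT`, `v_mT`) and the shared activation/inactivation variable w;
#' and per-current biases. The stimulus current is supplied at simulation
#' time, not here.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @seealso [fs_model()]
#' @export
fs_params <- function(...) {
  p <- list(
    C_m = 30,                          # pF
    abar_NaK = 67, abar_K = 4400, abar_Na = 1400,  # pA
    v_ATP = -430, v_K = -89, v_Na = 60,
    v_mT = -17, g_mT = 5,
    v_w = -5, g_w = 4,
    r_w = 2,                           # 1/ms
    k_w = 1,
    b_w = 0.3,
    b_NaK = 0.5, b_K = 0.5, b_Na = 0.5
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown FS parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$C_m > 0, p$r_w > 0)
  p
}

#' Sinoatrial-node pacemaker derivatives
#'
#' Right-hand side of the SAN model. The state is `c(v, w, c)`: membrane
#' potential (mV), K-channel activation (which doubles as Ca-channel
#' inactivation) in \eqn{[0,1]}, and intracellular Ca (uM). The four
#' normalised currents (pA/pF) are
#' \itemize{
#'   \item `J_NaK = a_NaK phi((v - v_NaK)/v_T, b_NaK)` with
#'     \eqn{v_{NaK} = 3 v_{Na} - 2 v_K + v_{ATP}},
#'   \item `J_KD = a_K w phi((v - v_K)/v_T, b_K)`,
#'   \item `J_CaL = a_Ca (1 - w) F_m(v) phi(2 (v - v_Ca(c))/v_T, b_Ca)`
#'     with \eqn{v_{Ca}(c) = (v_T/2) \ln(ca_{out}/c)} (negative below
#'     \eqn{v_{Ca}}: inward),
#'   \item `J_NaCa = a_NaCa phi((-v - v_NaCa(c))/v_T, b_NaCa)` with
#'     \eqn{v_{NaCa} = 2 v_{Ca} - 3 v_{Na}} (the net-charge convention
#'     \eqn{\eta = -1} applied inside the argument).
#' }
#' and the flow is \eqn{\partial_t v = -(J_{NaK} + J_{NaCa} + J_{CaL} +
#' J_{KD})}, \eqn{\partial_t w = w^{k_w} [F_w(v) - w] R_w(v)},
#' \eqn{\partial_t c = r_c (c_\infty - c) - k_c (J_{CaL} - J_{NaCa})}.
#'
#' @param state Named numeric `c(v=, w=, c=)`.
#' @param params From [san_params()].
#' @inheritParams nernst_potential
#' @return List with `derivatives` (named like the state), `currents`
#'   (J_NaK, J_NaCa, J_CaL, J_KD in pA/pF) and `v_Ca`.
#' @export
san_derivatives <- function(state, params = san_params(),
                            constants = transport_constants()) {
  constants <- as_constants(constants)
  v <- state[["v"]]; w <- state[["w"]]; c <- state[["c"]]
  if (!is.finite(c) || c <= 0) stop("intracellular Ca must be positive")
  vT <- constants$v_T
  p <- params
  v_Ca <- (vT / 2) * log(p$ca_out / c)
  v_NaK <- 3 * p$v_Na - 2 * p$v_K + p$v_ATP
  v_NaCa <- 2 * v_Ca - 3 * p$v_Na
  F_m <- gating_steady_state(v, p$g_m, p$v_m, constants)
  F_w <- gating_steady_state(v, p$g_w, p$v_w, constants)
  R_w <- gating_rate(v, p$r_w, p$b_w, p$g_w, p$v_w, constants)
  J_NaK <- p$a_NaK * phi_bias((v - v_NaK) / vT, p$b_NaK)
  J_KD <- p$a_K * w * phi_bias((v - p$v_K) / vT, p$b_K)
  inact <- if (isTRUE(p$ca_inact)) (1 - w) else 1
  J_CaL <- p$a_Ca * inact * F_m * phi_bias(2 * (v - v_Ca) / vT, p$b_Ca)
  J_NaCa <- p$a_NaCa * phi_bias((-v - v_NaCa) / vT, p$b_NaCa)
  dv <- -(J_NaK + J_NaCa + J_CaL + J_KD)
  dw <- max(w, 0)^p$k_w * (F_w - w) * R_w
  dc <- p$r_c * (p$c_inf - c) - p$k_c * (J_CaL - J_NaCa)
  list(
    derivatives = c(v = dv, w = dw, c = dc),
    currents = c(J_NaK = J_NaK, J_NaCa = J_NaCa, J_CaL = J_CaL, J_KD = J_KD),
    v_Ca = v_Ca
  )
}

#' Fast-spiking interneuron derivatives
#'
#' Right-hand side of the FS model over state `c(v, w)` with an injected
#' current `i_stim` (pA). Normalised amplitudes are
#' \eqn{a_x = \bar a_x / C_m}; the currents (pA/pF) are the transient Na
#' current \eqn{J_{NaT} = -a_{NaT} (1 - w) F_m(v)\,\varphi((v_{Na} - v)/v_T,
#' b_{Na})} (inward below \eqn{v_{Na}}), the delayed-rectifier
#' \eqn{J_K = a_K w\, \varphi((v - v_K)/v_T, b_K)} and the pump current
#' \eqn{J_{NaK} = a_{NaK} \varphi((v - v_{NaK})/v_T, b_{NaK})} with
#' \eqn{v_{NaK} = 3 v_{Na} - 2 v_K + v_{ATP}}. The flow is
#' \eqn{\partial_t v = -(J_{NaT} + J_K + J_{NaK}) + i_{stim}/C_m},
#' \eqn{\partial_t w = w^{k_w} [F_w(v) - w] R_w(v)}.
#'
#' @param state Named numeric `c(v=, w=)`.
#' @param params From [fs_params()].
#' @param i_stim Injected current, pA.
#' @inheritParams nernst_potential
#' @return List with `derivatives` and `currents` (J_NaT, J_K, J_NaK).
#' @export
fs_derivatives <- function(state, params = fs_params(), i_stim = 0,
                           constants = transport_constants()) {
  constants <- as_constants(constants)
  v <- state[["v"]]; w <- state[["w"]]
  vT <- constants$v_T
  p <- params
  a_NaT <- p$abar_Na / p$C_m
  a_K <- p$abar_K / p$C_m
  a_NaK <- p$abar_NaK / p$C_m
  v_NaK <- 3 * p$v_Na - 2 * p$v_K + p$v_ATP
  F_m <- gating_steady_state(v, p$g_mT, p$v_mT, constants)
  F_w <- gating_steady_state(v, p$g_w, p$v_w, constants)
  R_w <- gating_rate(v, p$r_w, p$b_w, p$g_w, p$v_w, constants)
  J_NaT <- -a_NaT * (1 - w) * F_m * phi_bias((p$v_Na - v) / vT, p$b_Na)
  J_K <- a_K * w * phi_bias((v - p$v_K) / vT, p$b_K)
  J_NaK <- a_NaK * phi_bias((v - v_NaK) / vT, p$b_NaK)
  dv <- -(J_NaT + J_K + J_NaK) + i_stim / p$C_m
  dw <- max(w, 0)^p$k_w * (F_w - w) * R_w
  list(
    derivatives = c(v = dv, w = dw),
    currents = c(J_NaT = J_NaT, J_K = J_K, J_NaK = J_NaK)
  )
}

#' Membrane-potential models
#'
#' Constructors for the two bundled excitable-membrane models: the
#' three-variable sinoatrial-node pacemaker (`san_model()`) and the
#' two-variable fast-spiking interneuron (`fs_model()`). Both return a
#' `membrane_model` object that can be integrated with [simulate()].
#' Default initial conditions place the SAN at (v, w, c) =
#' (-60 mV, F_w(-60), c_inf) and the FS cell at (-72 mV, F_w(-72)).
#'
#' @param params Parameter list from [san_params()] or [fs_params()].
#' @param constants A [transport_constants()].
#' @return Object of class `membrane_model` (subclasses `san_model` /
#'   `fs_model`).
#' @examples
#' m <- san_model()
#' \donttest{
#' traj <- simulate(m, tmax = 3000)
#' }
#' @export
san_model <- function(params = san_params(),
                      constants = transport_constants()) {
  init <- c(v = -60,
            w = gating_steady_state(-60, params$g_w, params$v_w, constants),
            c = params$c_inf)
  structure(
    list(kind = "san", params = params, constants = constants, init = init,
         state_names = c("v", "w", "c"),
         current_names = c("J_NaK", "J_NaCa", "J_CaL", "J_KD")),
    class = c("san_model", "membrane_model")
  )
}

#' @rdname san_model
#' @export
fs_model <- function(params = fs_params(),
                     constants = transport_constants()) {
  init <- c(v = -72,
            w = gating_steady_state(-72, params$g_w, params$v_w, constants))
  structure(
    list(kind = "fs", params = params, constants = constants, init = init,
         state_names = c("v", "w"),
         current_names = c("J_NaT", "J_K", "J_NaK")),
    class = c("fs_model", "membrane_model")
  )
}

#' @export
print.membrane_model <- function(x, ...) {
  lab <- switch(x$kind,
                san = "sinoatrial-node pacemaker (v, w, c)",
                fs = "fast-spiking interneuron (v, w)")
  cat(sprintf("Membrane model: %s\n", lab))
  cat(sprintf("  v_T = %.3f mV (T = %g K)\n", x$constants$v_T,
              x$constants$temperature))
  cat("  initial state:", paste(sprintf("%s = %.4g", names(x$init), x$init),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Integrate a derivative function with dense, regular output
#'
#' Thin deterministic contract over [deSolve::lsoda()]: an adaptive,
#' stiffness-switching integration sampled on a regular grid. The
#' derivative function receives `(t, state)` with a named state vector and
#' must return `list(derivatives, extras)` where `extras` is an optional
#' named numeric vector recorded alongside the state (used for per-current
#' traces). Solver failures raise an error naming the last successfully
#' reached time.
#'
#' @param derivatives Function `(t, state) -> list(dstate, extras?)`.
#' @param init Named initial state.
#' @param t_span Length-2 numeric, ms.
#' @param sample_dt Output sampling interval, ms.
#' @param rtol,atol Relative/absolute tolerances.
#' @param max_step Maximum internal step, ms (the bi-exponential currents
#'   are stiff near spikes).
#' @return A data.frame with `time`, the state columns and any extras.
#' @export
simulate_ode <- function(derivatives, init, t_span, sample_dt = 0.05,
                         rtol = 1e-8, atol = 1e-10, max_step = 0.1) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1], sample_dt > 0)
  times <- seq(t_span[1], t_span[2], by = sample_dt)
  func <- function(t, y, parms) {
    out <- derivatives(t, y)
    extras <- if (length(out) > 1L && !is.null(out[[2]])) out[[2]] else NULL
    list(out[[1]], extras)
  }
  sol <- deSolve::lsoda(y = init, times = times, func = func, parms = NULL,
                        rtol = rtol, atol = atol, hmax = max_step)
  df <- as.data.frame(sol)
  if (nrow(df) < length(times)) {
    stop(sprintf(
      "integration failed at t = %.6g ms (reached %d of %d requested samples)",
      df$time[nrow(df)], nrow(df), length(times)))
  }
  df
}

#' Simulate a membrane model
#'
#' Integrates a [san_model()] or [fs_model()] and returns a
#' `membrane_trajectory`: the state sampled every `sample_dt` ms together
#' with all normalised currents (pA/pF) and the instantaneous `dvdt`
#' (mV/ms, numerically equal to V/s) evaluated from the vector field along
#' the solution. For the FS model a rectangular current step of amplitude
#' `stim` pA is injected on `[stim_onset, stim_onset + stim_duration)`.
#'
#' @param object A `membrane_model`.
#' @param nsim,seed Unused (the models are deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param tmax Total simulated time, ms.
#' @param sample_dt Output sampling interval, ms.
#' @param init Optional initial state override (named vector).
#' @param stim Step amplitude, pA (FS model only).
#' @param stim_onset Step onset, ms.
#' @param stim_duration Step duration, ms (default: to the end).
#' @param rtol,atol,max_step Solver controls, see [simulate_ode()].
#' @param ... Ignored.
#' @return A `membrane_trajectory` (data.frame with attributes `kind`,
#'   `params`, `stim`).
#' @export
simulate.membrane_model <- function(object, nsim = 1, seed = NULL,
                                    tmax = 7000, sample_dt = 0.05,
                                    init = NULL, stim = 0, stim_onset = 500,
                                    stim_duration = Inf,
                                    rtol = 1e-8, atol = 1e-10,
                                    max_step = 0.1, ...) {
  p <- object$params
  cst <- object$constants
  y0 <- if (is.null(init)) object$init else init[object$state_names]
  if (object$kind == "san") {
    derivs <- function(t, y) {
      out <- san_derivatives(y, p, cst)
      list(out$derivatives,
           c(out$currents, dvdt = unname(out$derivatives["v"])))
    }
  } else {
    stim_end <- stim_onset + stim_duration
    derivs <- function(t, y) {
      i_s <- if (t >= stim_onset && t < stim_end) stim else 0
      out <- fs_derivatives(y, p, i_stim = i_s, constants = cst)
      list(out$derivatives,
           c(out$currents, dvdt = unname(out$derivatives["v"])))
    }
  }
  df <- simulate_ode(derivs, y0, c(0, tmax), sample_dt = sample_dt,
                     rtol = rtol, atol = atol, max_step = max_step)
  structure(df,
            kind = object$kind, params = p,
            stim = c(amplitude = stim, onset = stim_onset,
                     duration = stim_duration),
            class = c("membrane_trajectory", "data.frame"))
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat(sprintf("Membrane trajectory (%s model): %d samples, 0 to %g ms\n",
              attr(x, "kind"), nrow(x), x$time[nrow(x)]))
  cat(sprintf("  v range [%.2f, %.2f] mV\n", min(x$v), max(x$v)))
  st <- attr(x, "stim")
  if (!is.null(st) && st[["amplitude"]] != 0) {
    cat(sprintf("  stimulus: %g pA from %g ms\n",
                st[["amplitude"]], st[["onset"]]))
  }
  invisible(x)
}

#' Plot a membrane trajectory
#'
#' Membrane potential against time; set `what` to plot another recorded
#' column (e.g. a current trace).
#'
#' @param x A `membrane_trajectory`.
#' @param what Column to plot against time.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.membrane_trajectory <- function(x, what = "v", ...) {
  graphics::plot(x$time, x[[what]], type = "l",
                 xlab = "time (ms)",
                 ylab = if (what == "v") "v (mV)" else what, ...)
  invisible(x)
}

#' Read or write a trajectory as CSV
#'
#' Columns `t_ms`, `v_mV`, `w`, and for the SAN model `c_uM`, followed by
#' one column per recorded current and `dvdt`. Floats are written with a
#' fixed 10-significant-digit format, so identical simulations produce
#' byte-identical files and round trips are lossless to 1e-9 relative.
#'
#' @param trajectory A `membrane_trajectory`.
#' @param path File path.
#' @return `read_traj_csv()` returns a data.frame with standard column
#'   names (`time`, `v`, `w`, ...); `write_traj_csv()` returns `path`
#'   invisibly.
#' @export
write_traj_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  out <- data.frame(t_ms = format_sig(df$time), v_mV = format_sig(df$v),
                    w = format_sig(df$w), check.names = FALSE)
  if ("c" %in% names(df)) out$c_uM <- format_sig(df$c)
  for (nm in setdiff(names(df), c("time", "v", "w", "c"))) {
    out[[nm]] <- format_sig(df[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traj_csv
#' @export
read_traj_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("t_ms", "v_mV") %in% names(df))) {
    stop(sprintf("'%s': header must contain t_ms and v_mV", path))
  }
  names(df)[names(df) == "t_ms"] <- "time"
  names(df)[names(df) == "v_mV"] <- "v"
  names(df)[names(df) == "c_uM"] <- "c"
  df
}
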