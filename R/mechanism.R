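#' Single-species transport step
#'
#' Describes the movement of `count` molecules of one species between the
#' extracellular compartment (labelled 0) and the intracellular compartment
#' (labelled 1) during one transport event. A collection of these steps
#' defines a [transport_mechanism()].
#'
#' @param species Species label, e.g. `"Na"`.
#' @param valence Integer valence \eqn{z_s} (0 for uncharged solutes).
#' @param count Stoichiometry \eqn{n_s \ge 1}: molecules moved per event.
#' @param source,dest Source and destination compartments, each 0 (out) or
#'   1 (in); they must differ. `(0, 1)` is inward transport, `(1, 0)` outward.
#' @param conc_out,conc_in Strictly positive concentrations outside and
#'   inside. Any unit may be used as long as the two sides of one species
#'   share it (only ratios enter the energies).
#'
#' @return An object of class `species_move`.
#' @seealso [transport_mechanism()], [nernst_potential()]
#' @examples
#' species_move("K", valence = 1, count = 1, source = 1, dest = 0,
#'              conc_out = 4, conc_in = 140)
#' @export
species_move <- function(species, valence, count = 1, source, dest,
                         conc_out, conc_in) {
  stopifnot(is.character(species), length(species) == 1L)
  if (!is.numeric(valence) || valence != round(valence)) {
    stop("`valence` must be an integer")
  }
  if (!is.numeric(count) || count < 1 || count != round(count)) {
    stop("`count` must be a positive integer")
  }
  if (!source %in% c(0, 1) || !dest %in% c(0, 1)) {
    stop("`source` and `dest` must each be 0 (out) or 1 (in)")
  }
  if (source == dest) stop("`source` and `dest` must differ")
  if (!is.numeric(conc_out) || !is.numeric(conc_in) ||
      conc_out <= 0 || conc_in <= 0) {
    stop("concentrations must be strictly positive")
  }
  structure(
    list(species = species, valence = as.integer(valence),
         count = as.integer(count), source = source, dest = dest,
         conc_out = conc_out, conc_in = conc_in),
    class = "species_move"
  )
}

#' @export
print.species_move <- function(x, ...) {
  dir <- if (x$source == 0) "inward" else "outward"
  cat(sprintf("%d %s (z = %+d) %s  [%g out / %g in]\n",
              x$count, x$species, x$valence, dir, x$conc_out, x$conc_in))
  invisible(x)
}

#' Transport mechanism
#'
#' A transport mechanism is an ordered collection of [species_move()] steps
#' realised jointly in a single transport event (e.g. 3 Na out and 2 K in
#' for the Na-K ATPase), together with a transport rate `rate`
#' (molecules per ms per \eqn{\mu m^2}), a rectification bias
#' `bias` \eqn{\in [0, 1]} weighting the forward against the backward
#' Boltzmann factor, and an optional external energy source (ATP hydrolysis
#' or similar) of electrical size `v_ext` (mV).
#'
#' The external term enters the total energy as
#' \eqn{\delta_{Ext}\, q\, v_{Ext}}. By default `delta_ext = "auto"`:
#' the indicator is resolved at evaluation time as 1 exactly when the
#' summed electrochemical energy of the moves is positive (uphill
#' transport) and 0 otherwise. ATPase templates from [mechanism_catalog()]
#' pin `delta_ext = 1` because their defining use is uphill transport; a
#' warning is emitted if such a mechanism is evaluated where its
#' electrochemical energy is already downhill.
#'
#' @param name Mechanism label.
#' @param moves List of [species_move()] objects.
#' @param rate Transport rate \eqn{r > 0}, molecules ms\eqn{^{-1}}
#'   \eqn{\mu m^{-2}}.
#' @param bias Rectification bias \eqn{b \in [0, 1]}; 1/2 is symmetric
#'   (non-rectifying), values toward 1 bias the forward direction.
#' @param delta_ext `"auto"`, 0 or 1.
#' @param v_ext External energy in mV (e.g. \eqn{v_{ATP} \approx -450} mV);
#'   only used when the external indicator resolves to 1.
#'
#' @return An object of class `transport_mechanism`.
#' @seealso [flux()], [current()], [eta()], [reversal_vo()],
#'   [mechanism_catalog()]
#' @examples
#' k_out <- species_move("K", 1, 1, source = 1, dest = 0,
#'                       conc_out = 4, conc_in = 140)
#' kchan <- transport_mechanism("K channel", list(k_out), rate = 1e5, bias = 0.5)
#' eta(kchan)
#' @export
transport_mechanism <- function(name, moves, rate, bias = 0.5,
                                delta_ext = "auto", v_ext = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(moves) || length(moves) == 0L ||
      !all(vapply(moves, inherits, logical(1), "species_move"))) {
    stop("`moves` must be a non-empty list of species_move objects")
  }
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  if (!is.numeric(bias) || bias < 0 || bias > 1) {
    stop("`bias` must lie in [0, 1]")
  }
  if (!identical(delta_ext, "auto") && !delta_ext %in% c(0, 1)) {
    stop("`delta_ext` must be \"auto\", 0 or 1")
  }
  structure(
    list(name = name, moves = moves, rate = rate, bias = bias,
         delta_ext = delta_ext, v_ext = v_ext),
    class = "transport_mechanism"
  )
}

#' @export
print.transport_mechanism <- function(x, ...) {
  cat(sprintf("Transport mechanism: %s\n", x$name))
  for (m in x$moves) print(m)
  cat(sprintf("  rate r = %g /ms/um^2, bias b = %g", x$rate, x$bias))
  if (!identical(x$delta_ext, 0)) {
    cat(sprintf(", external term %s (v_ext = %g mV)",
                if (identical(x$delta_ext, "auto")) "auto" else "pinned on",
                x$v_ext))
  }
  cat("\n")
  et <- eta(x)
  cat(sprintf("  eta = %d (%s)\n", et,
              if (et == 0) "non-electrogenic" else "electrogenic"))
  invisible(x)
}

#' Nernst potential
#'
#' The equilibrium (Nernst) potential of an ion,
#' \eqn{v_s = (v_T / z_s) \ln([s]_0 / [s]_1)}, the transmembrane potential
#' at which its electrodiffusive flux vanishes.
#'
#' @param valence Non-zero integer valence.
#' @param conc_out,conc_in Strictly positive concentrations (same unit).
#' @param constants A [transport_constants()] object.
#' @return Potential in mV.
#' @examples
#' nernst_potential(1, 140, 14)   # ~ +61.5 mV at 310 K
#' nernst_potential(2, 140, 14)   # halved for divalents
#' @export
nernst_potential <- function(valence, conc_out, conc_in,
                             constants = transport_constants()) {
  constants <- as_constants(constants)
  if (!is.numeric(valence) || any(valence == 0)) {
    stop("`valence` must be non-zero (uncharged species have no Nernst potential)")
  }
  if (any(conc_out <= 0) || any(conc_in <= 0)) {
    stop("concentrations must be strictly positive")
  }
  (constants$v_T / valence) * log(conc_out / conc_in)
}

#' Energy to transport one species
#'
#' The work (in units of \eqn{kT}) required to move \eqn{n_s} molecules of
#' one species from its source to its destination compartment at
#' transmembrane potential `v`:
#' \deqn{\Delta G_s / kT = n_s (c_s - d_s) [\ln([s]_0/[s]_1) - z_s v / v_T].}
#' For an ion this equals \eqn{q z_s n_s (c_s - d_s)(v_s - v)/kT} with
#' \eqn{v_s} the Nernst potential; for an uncharged solute it is independent
#' of `v`.
#'
#' @param move A [species_move()].
#' @param v Transmembrane potential, mV.
#' @inheritParams nernst_potential
#' @return Energy in kT units (dimensionless).
#' @export
delta_G_species <- function(move, v, constants = transport_constants()) {
  constants <- as_constants(constants)
  stopifnot(inherits(move, "species_move"), is.finite(v))
  move$count * (move$source - move$dest) *
    (log(move$conc_out / move$conc_in) - move$valence * v / constants$v_T)
}

#' Total energy budget of a transport event
#'
#' Sums the per-species energies of a mechanism and adds the external
#' contribution \eqn{\delta_{Ext} q v_{Ext}} when present, all in kT units.
#'
#' @param mechanism A [transport_mechanism()].
#' @param v Transmembrane potential, mV.
#' @inheritParams nernst_potential
#' @return An object of class `energy_breakdown`: list with `per_species`
#'   (named numeric), `total_species`, `delta_ext` (resolved 0/1),
#'   `external`, and `total`, all energies in kT.
#' @examples
#' nak <- mechanism_catalog("Na-K ATPase")
#' delta_G_total(nak, v = -62)
#' @export
delta_G_total <- function(mechanism, v, constants = transport_constants()) {
  constants <- as_constants(constants)
  stopifnot(inherits(mechanism, "transport_mechanism"))
  per <- vapply(mechanism$moves, delta_G_species, numeric(1),
                v = v, constants = constants)
  names(per) <- vapply(mechanism$moves, `[[`, character(1), "species")
  total_species <- sum(per)
  dext <- mechanism$delta_ext
  if (identical(dext, "auto")) {
    dext <- as.numeric(total_species > 0)
  } else if (dext == 1 && total_species <= 0) {
    warning(sprintf(
      "'%s': external energy pinned on but electrochemical energy is already <= 0 at v = %g mV",
      mechanism$name, v))
  }
  external <- dext * mechanism$v_ext / constants$v_T
  structure(
    list(per_species = per, total_species = total_species,
         delta_ext = dext, external = external,
         total = external + total_species),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kT units):\n")
  for (nm in names(x$per_species)) {
    cat(sprintf("  %-8s %+.4f\n", nm, x$per_species[[nm]]))
  }
  cat(sprintf("  species total %+.4f\n", x$total_species))
  if (x$delta_ext == 1) cat(sprintf("  external      %+.4f\n", x$external))
  cat(sprintf("  grand total   %+.4f\n", x$total))
  invisible(x)
}

#' Electrical potential of ATP hydrolysis
#'
#' The extra energy supplied by hydrolysis of one ATP molecule, expressed
#' as a potential:
#' \deqn{v_{ATP} = [\Delta G_{ATP0} + kT \ln([ADP]_1 [P_i]_1 / [ATP]_1)] / q.}
#'
#' The standard-energy term is supplied as a potential `dG0_mV`
#' (\eqn{\Delta G_{ATP0}/q}). Its default, together with typical cytosolic
#' nucleotide concentrations (ATP 3 mM, ADP 0.1 mM, Pi 1 mM), reproduces the
#' commonly used value \eqn{v_{ATP} \approx -450} mV; the hydrolysis
#' potential becomes less negative as ADP and phosphate accumulate.
#'
#' @param conc_atp,conc_adp,conc_pi Intracellular concentrations in mM
#'   (strictly positive).
#' @param dG0_mV Standard hydrolysis energy as a potential, mV.
#' @inheritParams nernst_potential
#' @return \eqn{v_{ATP}} in mV.
#' @examples
#' atp_potential()                        # ~ -450 mV
#' atp_potential(3, 1, 1)                 # less negative with high ADP
#' @export
atp_potential <- function(conc_atp = 3, conc_adp = 0.1, conc_pi = 1,
                          dG0_mV = -174.6, constants = transport_constants()) {
  constants <- as_constants(constants)
  if (conc_atp <= 0 || conc_adp <= 0 || conc_pi <= 0) {
    stop("concentrations must be strictly positive")
  }
  # concentrations in the mass-action ratio are referred to the 1 M standard
  # state: [ADP][Pi]/[ATP] with [Pi], [ADP] in M leaves a residual 1e-3 factor
  ratio <- (conc_adp * 1e-3) * (conc_pi * 1e-3) / (conc_atp * 1e-3)
  dG0_mV + constants$v_T * log(ratio)
}

#' Net charge moved per transport event
#'
#' \eqn{\eta = \sum_s n_s (c_s - d_s) z_s}: the net number of elementary
#' charges moved to the extracellular side in one forward transport event.
#' \eqn{\eta = 0} means the mechanism is non-electrogenic and its flux does
#' not depend on the transmembrane potential.
#'
#' @param mechanism A [transport_mechanism()].
#' @return Integer.
#' @examples
#' eta(mechanism_catalog("Na-K ATPase"))    #  1
#' eta(mechanism_catalog("Na-H exchanger")) #  0
#' eta(mechanism_catalog("Ca channel"))     # -2
#' @export
eta <- function(mechanism) {
  stopifnot(inherits(mechanism, "transport_mechanism"))
  as.integer(sum(vapply(
    mechanism$moves,
    function(m) m$count * (m$source - m$dest) * m$valence,
    numeric(1)
  )))
}

#' Reversal-potential numerator of a mechanism
#'
#' Computes \eqn{v_o = \delta_{Ext} v_{Ext} + \sum_s n_s z_s (c_s - d_s) v_s}.
#' For electrogenic mechanisms the physical reversal potential (where the
#' current crosses zero) is \eqn{v_o / \eta}. Uncharged species contribute
#' their chemical term \eqn{n_s (c_s - d_s) v_T \ln([s]_0/[s]_1)}, so the
#' identity \eqn{\Delta G / kT = (v_o - \eta v)/v_T} holds for every
#' mechanism, not only purely ionic ones.
#'
#' @inheritParams delta_G_total
#' @return `v_o` in mV, with attributes `eta` and `non_electrogenic`
#'   (`TRUE` when \eqn{\eta = 0}, in which case `v_o` is still returned but
#'   no reversal potential exists).
#' @examples
#' vo <- reversal_vo(mechanism_catalog("Na-K ATPase"))
#' vo / attr(vo, "eta")  # reversal potential of the pump current
#' @export
reversal_vo <- function(mechanism, constants = transport_constants()) {
  constants <- as_constants(constants)
  stopifnot(inherits(mechanism, "transport_mechanism"))
  # n z (c-d) v_s == n (c-d) v_T ln(out/in); valid for z = 0 as well
  chem <- sum(vapply(
    mechanism$moves,
    function(m) m$count * (m$source - m$dest) *
      constants$v_T * log(m$conc_out / m$conc_in),
    numeric(1)
  ))
  dext <- mechanism$delta_ext
  if (identical(dext, "auto")) {
    # resolve against the v-independent part: use the chemical energy at v = 0
    dext <- as.numeric(delta_G_total(
      transport_mechanism(mechanism$name, mechanism$moves, mechanism$rate,
                          mechanism$bias, delta_ext = 0),
      v = 0, constants = constants)$total > 0)
  }
  vo <- dext * mechanism$v_ext + chem
  et <- eta(mechanism)
  structure(vo, eta = et, non_electrogenic = et == 0L)
}

#' Boltzmann ratio of forward to backward rates
#'
#' For any transport energy \eqn{\Delta G} (kT units) the steady-state
#' ratio of forward to backward rates is \eqn{\alpha/\beta =
#' \exp(-\Delta G)}, independently of the rate `r` and bias `b`.
#'
#' @param delta_G Energy in kT units.
#' @return Dimensionless ratio.
#' @export
rate_ratio <- function(delta_G) {
  stopifnot(is.numeric(delta_G), all(is.finite(delta_G)))
  exp(-delta_G)
}

#' Forward and backward transport rates
#'
#' Splits the Boltzmann factor between the two directions with bias `b`:
#' \eqn{\alpha = r e^{-b \Delta G}}, \eqn{\beta = r e^{(1-b)\Delta G}}.
#' Their ratio recovers [rate_ratio()] exactly for every `r` and `b`.
#'
#' @param delta_G Energy in kT units.
#' @param r Transport rate, molecules/ms/\eqn{\mu m^2}.
#' @param b Bias in \eqn{[0, 1]}.
#' @return Named list with `alpha` and `beta`.
#' @export
forward_backward_rates <- function(delta_G, r, b) {
  stopifnot(r > 0, b >= 0, b <= 1)
  list(alpha = r * exp(-b * delta_G), beta = r * exp((1 - b) * delta_G))
}

#' Net transport flux
#'
#' The net flux \eqn{\Phi = \alpha - \beta} of transport events per ms per
#' \eqn{\mu m^2}. Two algebraically equivalent forms are available:
#' `"concentration"` evaluates the concentration-explicit product form
#' (useful when concentrations are dynamic), `"reversal"` the compact form
#' \eqn{r [e^{b x} - e^{(b-1) x}]} with \eqn{x = (\eta v - v_o)/v_T}.
#' For non-electrogenic mechanisms (\eqn{\eta = 0}) the result does not
#' depend on `v`.
#'
#' @inheritParams delta_G_total
#' @param form Which algebraic form to evaluate.
#' @return Flux in molecules/ms/\eqn{\mu m^2} (vectorised over `v`).
#' @examples
#' kcl <- mechanism_catalog("K-Cl symporter")
#' flux(kcl, -80) == flux(kcl, 40)  # eta == 0: no voltage dependence
#' @export
flux <- function(mechanism, v, constants = transport_constants(),
                 form = c("concentration", "reversal")) {
  constants <- as_constants(constants)
  stopifnot(inherits(mechanism, "transport_mechanism"))
  form <- match.arg(form)
  b <- mechanism$bias
  r <- mechanism$rate
  et <- eta(mechanism)
  if (form == "reversal") {
    vo <- as.numeric(reversal_vo(mechanism, constants))
    x <- (et * v - vo) / constants$v_T
    return(r * (exp(b * x) - exp((b - 1) * x)))
  }
  # concentration-explicit form: products of ([s]_0/[s]_1)^{k n_s (d_s - c_s)}
  # with exponent k = b (forward) and k = b - 1 (backward)
  dext <- mechanism$delta_ext
  if (identical(dext, "auto")) {
    dext <- as.numeric(delta_G_total(
      transport_mechanism(mechanism$name, mechanism$moves, r, b, delta_ext = 0),
      v = 0, constants = constants)$total > 0)
  }
  lr <- vapply(mechanism$moves,
               function(m) m$count * (m$dest - m$source) *
                 log(m$conc_out / m$conc_in),
               numeric(1))
  lsum <- sum(lr)
  core <- (et * v - dext * mechanism$v_ext) / constants$v_T
  r * (exp(b * lsum + b * core) - exp((b - 1) * lsum + (b - 1) * core))
}

#' Electrogenic current density of a mechanism
#'
#' Converts the net flux to a current density \eqn{i = q \eta \Phi}
#' (pA/\eqn{\mu m^2}). The current vanishes at the reversal potential
#' \eqn{v_o/\eta} and, for any interior bias, has the sign of
#' \eqn{\eta v - v_o}.
#'
#' @inheritParams flux
#' @return Current density in pA/\eqn{\mu m^2} (vectorised over `v`).
#' @examples
#' kchan <- mechanism_catalog("K channel")
#' vk <- as.numeric(reversal_vo(kchan))
#' current(kchan, vk)  # zero at the Nernst potential
#' @export
current <- function(mechanism, v, constants = transport_constants(),
                    form = c("concentration", "reversal")) {
  constants <- as_constants(constants)
  et <- eta(mechanism)
  if (et == 0L) {
    stop(sprintf("'%s' is non-electrogenic (eta = 0): no current",
                 mechanism$name))
  }
  Q_PA_MS * et * flux(mechanism, v, constants, form = match.arg(form))
}
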