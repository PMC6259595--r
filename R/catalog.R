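# Default mammalian transmembrane concentrations used by the catalogue
# templates. Na/K/Cl in mM; Ca in mM outside and uM inside (expressed in a
# common unit, mM, inside each move); H from pH 7.4 (out) / 7.1 (in) in mM;
# iodide reflects ~60-fold accumulation by the Na-I symporter. These only set
# the default Nernst potentials of the templates; all are overridable.
.default_concs <- list(
  Na = c(out = 145,      `in` = 12),
  K  = c(out = 4,        `in` = 140),
  Cl = c(out = 110,      `in` = 10),
  Ca = c(out = 2,        `in` = 1e-4),   # 2 mM out, 0.1 uM in
  H  = c(out = 10^-4.4,  `in` = 10^-4.1),
  I  = c(out = 0.0005,   `in` = 0.03)
)

.catalog_specs <- function() {
  cc <- .default_concs
  mv <- function(sp, z, n, src, dst) {
    species_move(sp, z, n, src, dst, cc[[sp]][["out"]], cc[[sp]][["in"]])
  }
  # rates: electrodiffusion through channels is orders of magnitude faster
  # than carrier-mediated transport
  rch <- 1e5   # molecules/ms/um^2, channels
  rpu <- 1e2   # pumps and carriers
  list(
    "Cl channel" = list(
      moves = list(mv("Cl", -1, 1, 0, 1)), rate = rch, delta_ext = 0,
      vo_expr = "v_Cl", ab_expr = "([Cl]0/[Cl]1) exp(v/v_T)"),
    "K channel" = list(
      moves = list(mv("K", 1, 1, 1, 0)), rate = rch, delta_ext = 0,
      vo_expr = "v_K", ab_expr = "([K]1/[K]0) exp(v/v_T)"),
    "Na channel" = list(
      moves = list(mv("Na", 1, 1, 0, 1)), rate = rch, delta_ext = 0,
      vo_expr = "-v_Na", ab_expr = "([Na]0/[Na]1) exp(-v/v_T)"),
    "Ca channel" = list(
      moves = list(mv("Ca", 2, 1, 0, 1)), rate = rch, delta_ext = 0,
      vo_expr = "-2 v_Ca", ab_expr = "([Ca]0/[Ca]1) exp(-2v/v_T)"),
    "Na-K ATPase" = list(
      moves = list(mv("Na", 1, 3, 1, 0), mv("K", 1, 2, 0, 1)),
      rate = rpu, delta_ext = 1,
      vo_expr = "v_ATP + 3 v_Na - 2 v_K",
      ab_expr = "([Na]1/[Na]0)^3 ([K]0/[K]1)^2 exp((v - v_ATP)/v_T)"),
    "Ca ATPase" = list(
      moves = list(mv("Ca", 2, 1, 1, 0)), rate = rpu, delta_ext = 1,
      vo_expr = "v_ATP + 2 v_Ca",
      ab_expr = "([Ca]1/[Ca]0) exp((2v - v_ATP)/v_T)"),
    "H ATPase" = list(
      moves = list(mv("H", 1, 1, 1, 0)), rate = rpu, delta_ext = 1,
      vo_expr = "v_ATP + v_H",
      ab_expr = "([H]1/[H]0) exp((v - v_ATP)/v_T)"),
    "Na-Ca exchanger" = list(
      moves = list(mv("Na", 1, 3, 0, 1), mv("Ca", 2, 1, 1, 0)),
      rate = rpu, delta_ext = 0,
      vo_expr = "2 v_Ca - 3 v_Na",
      ab_expr = "([Na]0/[Na]1)^3 ([Ca]1/[Ca]0) exp(-v/v_T)"),
    "Na-I symporter" = list(
      moves = list(mv("Na", 1, 2, 0, 1), mv("I", -1, 1, 0, 1)),
      rate = rpu, delta_ext = 0,
      vo_expr = "-v_I - 2 v_Na",
      ab_expr = "([Na]0/[Na]1)^2 ([I]0/[I]1) exp(-v/v_T)"),
    "Na-H exchanger" = list(
      moves = list(mv("Na", 1, 1, 0, 1), mv("H", 1, 1, 1, 0)),
      rate = rpu, delta_ext = 0,
      vo_expr = "v_H - v_Na",
      ab_expr = "([H]1/[H]0) ([Na]0/[Na]1)"),
    "K-Cl symporter" = list(
      moves = list(mv("K", 1, 1, 1, 0), mv("Cl", -1, 1, 1, 0)),
      rate = rpu, delta_ext = 0,
      vo_expr = "v_K - v_Cl",
      ab_expr = "([K]1/[K]0) ([Cl]1/[Cl]0)"),
    "Na-K-Cl symporter" = list(
      moves = list(mv("Na", 1, 1, 0, 1), mv("K", 1, 1, 0, 1),
                   mv("Cl", -1, 2, 0, 1)),
      rate = rpu, delta_ext = 0,
      vo_expr = "2 v_Cl - v_Na - v_K",
      ab_expr = "([Na]0/[Na]1) ([K]0/[K]1) ([Cl]0/[Cl]1)^2")
  )
}

#' Catalogue of standard transport mechanisms
#'
#' Ready-made [transport_mechanism()] templates for twelve common passive
#' and active mechanisms: the Cl, K, Na and Ca channels, the Na-K, Ca and H
#' ATPases, the Na-Ca and Na-H exchangers, and the Na-I, K-Cl and Na-K-Cl
#' symporters. Each template carries textbook mammalian concentrations
#' (overridable via `conc`), a default transport rate (channels much faster
#' than carriers) and a symmetric bias of 1/2.
#'
#' ATPase templates have their external-energy indicator pinned to 1 with
#' `v_ext` as given (their defining use is uphill transport); all other
#' templates resolve the indicator automatically.
#'
#' @param name Mechanism name; `mechanism_catalog()` with no arguments
#'   returns the vector of available names.
#' @param bias Rectification bias for the returned template.
#' @param rate Optional transport rate override.
#' @param v_atp ATP hydrolysis potential (mV) used by ATPase templates.
#' @param conc Optional named list overriding default concentrations, e.g.
#'   `list(Ca = c(out = 2, "in" = 5e-4))`.
#'
#' @return A `transport_mechanism`, or a character vector of names when
#'   `name` is missing.
#' @examples
#' mechanism_catalog()
#' mechanism_catalog("Na-Ca exchanger")
#' @export
mechanism_catalog <- function(name, bias = 0.5, rate = NULL, v_atp = -450,
                              conc = NULL) {
  specs <- .catalog_specs()
  if (missing(name)) return(names(specs))
  if (!name %in% names(specs)) {
    stop(sprintf("unknown mechanism '%s'; see mechanism_catalog() for names",
                 name))
  }
  sp <- specs[[name]]
  moves <- sp$moves
  if (!is.null(conc)) {
    moves <- lapply(moves, function(m) {
      if (m$species %in% names(conc)) {
        cc <- conc[[m$species]]
        species_move(m$species, m$valence, m$count, m$source, m$dest,
                     cc[["out"]], cc[["in"]])
      } else m
    })
  }
  transport_mechanism(
    name, moves,
    rate = if (is.null(rate)) sp$rate else rate,
    bias = bias,
    delta_ext = sp$delta_ext,
    v_ext = if (sp$delta_ext == 1) v_atp else 0
  )
}

#' Tabulate the mechanism catalogue
#'
#' One row per catalogue mechanism with its stoichiometry summary, net
#' charge \eqn{\eta}, reversal composition and rate-ratio expression,
#' together with the numerically computed `eta` and `v_o` under the default
#' concentrations. Suitable for writing as CSV.
#'
#' @inheritParams nernst_potential
#' @param v_atp ATP potential used for ATPase rows, mV.
#' @return A data.frame.
#' @export
catalog_table <- function(constants = transport_constants(), v_atp = -450) {
  specs <- .catalog_specs()
  rows <- lapply(names(specs), function(nm) {
    mech <- mechanism_catalog(nm, v_atp = v_atp)
    stoich <- paste(vapply(mech$moves, function(m) {
      sprintf("%d %s %s", m$count, m$species,
              if (m$source == 0) "in" else "out")
    }, character(1)), collapse = " + ")
    vo <- reversal_vo(mech, constants)
    data.frame(
      name = nm, stoichiometry = stoich, eta = eta(mech),
      v_o_expression = specs[[nm]]$vo_expr,
      v_o_mV = round(as.numeric(vo), 4),
      alpha_beta_expression = specs[[nm]]$ab_expr,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read or write a mechanism as JSON
#'
#' The JSON document has fields `name`, `moves` (array of objects with
#' `species`, `z`, `n`, `source`, `dest`, `conc_out`, `conc_in`), `r`, `b`,
#' `delta_ext` and `v_ext`.
#'
#' @param path File path.
#' @param mechanism A [transport_mechanism()].
#' @return `read_mechanism_json()` returns a `transport_mechanism`;
#'   `write_mechanism_json()` returns `path` invisibly.
#' @export
read_mechanism_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  req <- c("name", "moves", "r", "b")
  if (!all(req %in% names(doc))) {
    stop("mechanism JSON must contain fields: ", paste(req, collapse = ", "))
  }
  moves <- lapply(doc$moves, function(m) {
    species_move(m$species, m$z, m$n, m$source, m$dest, m$conc_out, m$conc_in)
  })
  dext <- if (is.null(doc$delta_ext)) "auto" else doc$delta_ext
  transport_mechanism(doc$name, moves, rate = doc$r, bias = doc$b,
                      delta_ext = dext,
                      v_ext = if (is.null(doc$v_ext)) 0 else doc$v_ext)
}

#' @rdname read_mechanism_json
#' @export
write_mechanism_json <- function(mechanism, path) {
  stopifnot(inherits(mechanism, "transport_mechanism"))
  doc <- list(
    name = mechanism$name,
    moves = lapply(mechanism$moves, function(m) {
      list(species = m$species, z = m$valence, n = m$count,
           source = m$source, dest = m$dest,
           conc_out = m$conc_out, conc_in = m$conc_in)
    }),
    r = mechanism$rate, b = mechanism$bias,
    delta_ext = mechanism$delta_ext, v_ext = mechanism$v_ext
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
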