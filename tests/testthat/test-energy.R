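test_that("thermal voltage follows from the constants", {
  cst <- transport_constants(310)
  expect_equal(cst$v_T, 1000 * 1.380649e-23 * 310 / 1.602176634e-19)
  expect_error(transport_constants(-1), "positive")
})

test_that("Nernst potential: zeros, closed form and valence scaling", {
  cst <- transport_constants(310)
  expect_equal(nernst_potential(1, 5, 5, cst), 0)
  # closed form evaluated independently: v_T * ln 10 at a 10:1 gradient
  expect_equal(nernst_potential(1, 100, 10, cst), cst$v_T * log(10))
  expect_equal(nernst_potential(1, 100, 10, cst), 61.5106436, tolerance = 1e-8)
  expect_equal(nernst_potential(2, 100, 10, cst),
               nernst_potential(1, 100, 10, cst) / 2)
  expect_error(nernst_potential(0, 10, 1), "non-zero")
  expect_error(nernst_potential(1, -1, 1), "positive")
})

test_that("per-species transport energy matches its two printed reductions", {
  cst <- transport_constants()
  # ion at its Nernst potential: no work
  k_out <- species_move("K", 1, 1, source = 1, dest = 0,
                        conc_out = 4, conc_in = 140)
  vK <- nernst_potential(1, 4, 140, cst)
  expect_equal(delta_G_species(k_out, vK, cst), 0)
  # uncharged solute with balanced concentrations: no work at any voltage
  glc <- species_move("glucose", 0, 1, source = 0, dest = 1,
                      conc_out = 5, conc_in = 5)
  expect_equal(delta_G_species(glc, -60, cst), 0)
  expect_equal(delta_G_species(glc, 40, cst), 0)
  # inward Na at v = 0 with a 10:1 gradient: -ln 10 (direct substitution)
  na_in <- species_move("Na", 1, 1, source = 0, dest = 1,
                        conc_out = 120, conc_in = 12)
  expect_equal(delta_G_species(na_in, 0, cst), -log(10))
  # ionic reduction: z n (c - d) (v_s - v) / v_T for random moves
  set.seed(11)
  for (k in 1:20) {
    z <- sample(c(-2, -1, 1, 2), 1)
    n <- sample(1:3, 1)
    src <- sample(0:1, 1)
    co <- runif(1, 0.1, 200); ci <- runif(1, 0.1, 200)
    v <- runif(1, -120, 60)
    mv <- species_move("x", z, n, src, 1 - src, co, ci)
    vs <- nernst_potential(z, co, ci, cst)
    expect_equal(delta_G_species(mv, v, cst),
                 z * n * (src - (1 - src)) * (vs - v) / cst$v_T)
  }
})

test_that("total energy is the sum of the parts plus the external term", {
  cst <- transport_constants()
  for (nm in mechanism_catalog()) {
    mech <- mechanism_catalog(nm)
    bd <- delta_G_total(mech, -40, cst)
    brute <- sum(vapply(mech$moves, delta_G_species, numeric(1),
                        v = -40, constants = cst))
    expect_equal(bd$total_species, brute, info = nm)
    expect_equal(bd$total, bd$external + bd$total_species, info = nm)
  }
})

test_that("Na-K pump energy vanishes at its composed reversal potential", {
  cst <- transport_constants()
  nak <- nak_exact(v_atp = -420, constants = cst)
  v_nak <- 3 * 60 - 2 * (-89) + (-420)
  expect_equal(v_nak, -62)
  bd <- delta_G_total(nak, v_nak, cst)
  expect_equal(bd$delta_ext, 1)
  expect_equal(bd$total, 0, tolerance = 1e-12)
})

test_that("K-Cl symporter energy and flux are voltage independent", {
  cst <- transport_constants()
  kcl <- mechanism_catalog("K-Cl symporter")
  expect_identical(eta(kcl), 0L)
  e1 <- delta_G_total(kcl, -100, cst)$total
  e2 <- delta_G_total(kcl, 50, cst)$total
  expect_equal(e1, e2)
  expect_equal(flux(kcl, -100, cst), flux(kcl, 50, cst))
})

test_that("ATP hydrolysis potential: default, ln-term zero, 10x ATP shift", {
  cst <- transport_constants()
  expect_equal(atp_potential(constants = cst), -450, tolerance = 0.01)
  # [ADP][Pi] = [ATP] on the molar scale: pure standard term
  expect_equal(atp_potential(1, 1, 1000, dG0_mV = -400, constants = cst), -400)
  d <- atp_potential(30, 0.1, 1, constants = cst) -
    atp_potential(3, 0.1, 1, constants = cst)
  expect_equal(d, -cst$v_T * log(10))
  expect_error(atp_potential(-1, 1, 1), "positive")
})

test_that("net charge moved per event matches the catalogue", {
  expected <- c("Cl channel" = 1L, "K channel" = 1L, "Na channel" = -1L,
                "Ca channel" = -2L, "Na-K ATPase" = 1L, "Ca ATPase" = 2L,
                "H ATPase" = 1L, "Na-Ca exchanger" = -1L,
                "Na-I symporter" = -1L, "Na-H exchanger" = 0L,
                "K-Cl symporter" = 0L, "Na-K-Cl symporter" = 0L)
  for (nm in names(expected)) {
    expect_identical(eta(mechanism_catalog(nm)), expected[[nm]], info = nm)
  }
})

test_that("reversal composition v_o matches per-species Nernst potentials", {
  cst <- transport_constants()
  # single K channel: v_o = v_K
  kch <- mechanism_catalog("K channel")
  m <- kch$moves[[1]]
  expect_equal(as.numeric(reversal_vo(kch, cst)),
               nernst_potential(1, m$conc_out, m$conc_in, cst))
  # Na-Ca exchanger: v_o = 2 v_Ca - 3 v_Na
  ncx <- mechanism_catalog("Na-Ca exchanger")
  vna <- nernst_potential(1, ncx$moves[[1]]$conc_out, ncx$moves[[1]]$conc_in, cst)
  vca <- nernst_potential(2, ncx$moves[[2]]$conc_out, ncx$moves[[2]]$conc_in, cst)
  expect_equal(as.numeric(reversal_vo(ncx, cst)), 2 * vca - 3 * vna)
  # Na-K ATPase with exact Table-style potentials: -62 mV
  expect_equal(as.numeric(reversal_vo(nak_exact(constants = cst), cst)), -62,
               tolerance = 1e-10)
  # non-electrogenic mechanisms are flagged but still return v_o
  vo0 <- reversal_vo(mechanism_catalog("Na-H exchanger"), cst)
  expect_true(attr(vo0, "non_electrogenic"))
  expect_true(is.finite(as.numeric(vo0)))
})

test_that("detailed balance: alpha/beta recovers exp(-dG) for any r and b", {
  for (dG in c(-3, -0.5, 0, 0.5, 4)) {
    for (r in c(0.01, 1, 1e5)) {
      for (b in c(0, 0.25, 0.5, 0.9, 1)) {
        fb <- forward_backward_rates(dG, r, b)
        expect_equal(fb$alpha / fb$beta, rate_ratio(dG))
      }
    }
  }
  fb0 <- forward_backward_rates(0, 7, 0.3)
  expect_equal(fb0$alpha, 7)
  expect_equal(fb0$beta, 7)
  expect_equal(rate_ratio(1), exp(-1))
})

test_that("flux: concentration form and reversal form agree for all catalogue entries", {
  cst <- transport_constants()
  v <- seq(-150, 100, by = 5)
  for (nm in mechanism_catalog()) {
    for (b in c(0, 0.35, 0.5, 1)) {
      mech <- mechanism_catalog(nm, bias = b)
      f1 <- flux(mech, v, cst, form = "concentration")
      f2 <- flux(mech, v, cst, form = "reversal")
      expect_lt(max(abs(f1 - f2) / pmax(abs(f1), 1e-100)), 1e-10,
                label = sprintf("%s b=%g duality error", nm, b))
    }
  }
})

test_that("flux runs down the total gradient for every bias", {
  cst <- transport_constants()
  for (nm in c("K channel", "Na channel", "Na-K ATPase", "Na-Ca exchanger")) {
    for (b in c(0, 0.2, 0.5, 0.8, 1)) {
      mech <- mechanism_catalog(nm, bias = b)
      for (v in seq(-120, 60, by = 20)) {
        dG <- delta_G_total(mech, v, cst)$total
        expect_lte(flux(mech, v, cst) * dG, 1e-12,
                   label = sprintf("%s b=%g v=%g sign law", nm, b, v))
      }
    }
  }
})

test_that("current vanishes at the reversal potential and is odd there for b = 1/2", {
  cst <- transport_constants()
  kch <- k_channel_exact(bias = 0.5, constants = cst)
  expect_equal(current(kch, -89, cst), 0, tolerance = 1e-15)
  for (d in c(1, 10, 40)) {
    expect_equal(current(kch, -89 + d, cst), -current(kch, -89 - d, cst))
  }
  # outward-positive convention: i has the sign of (v - v_o/eta) for any
  # interior bias (inward current below the reversal potential)
  nch <- mechanism_catalog("Na channel", bias = 0.3)
  vrev <- as.numeric(reversal_vo(nch, cst)) / eta(nch)
  for (v in seq(-120, 60, by = 17)) {
    if (abs(v - vrev) > 1e-6) {
      expect_equal(sign(current(nch, v, cst)), sign(v - vrev))
    }
  }
  expect_error(current(mechanism_catalog("Na-H exchanger"), 0, cst),
               "non-electrogenic")
})

test_that("fully backward-biased K current matches the printed closed form", {
  cst <- transport_constants()
  kch <- k_channel_exact(bias = 0, constants = cst)
  q <- 1.602176634e-4  # pA per molecule/ms
  v <- seq(-140, 60, by = 10)
  expect_equal(current(kch, v, cst),
               q * kch$rate * (1 - exp((-89 - v) / cst$v_T)))
})

test_that("catalogue rate ratios match the tabulated expressions", {
  cst <- transport_constants()
  vT <- cst$v_T
  v <- c(-90, -30, 10)
  conc <- function(mech, sp) {
    m <- Filter(function(x) x$species == sp, mech$moves)[[1]]
    c(out = m$conc_out, `in` = m$conc_in)
  }
  # K channel: ([K]1/[K]0) exp(v/vT)
  kch <- mechanism_catalog("K channel")
  ck <- conc(kch, "K")
  expect_equal(rate_ratio(delta_G_total(kch, v[1], cst)$total),
               (ck[["in"]] / ck[["out"]]) * exp(v[1] / vT))
  # Na-K ATPase: ([Na]1/[Na]0)^3 ([K]0/[K]1)^2 exp((v - v_ATP)/vT)
  nak <- mechanism_catalog("Na-K ATPase", v_atp = -450)
  cna <- conc(nak, "Na"); ck <- conc(nak, "K")
  for (vv in v) {
    expect_equal(rate_ratio(delta_G_total(nak, vv, cst)$total),
                 (cna[["in"]] / cna[["out"]])^3 *
                   (ck[["out"]] / ck[["in"]])^2 * exp((vv + 450) / vT))
  }
  # Na-Ca exchanger: ([Na]0/[Na]1)^3 ([Ca]1/[Ca]0) exp(-v/vT)
  ncx <- mechanism_catalog("Na-Ca exchanger")
  cna <- conc(ncx, "Na"); cca <- conc(ncx, "Ca")
  expect_equal(rate_ratio(delta_G_total(ncx, v[3], cst)$total),
               (cna[["out"]] / cna[["in"]])^3 *
                 (cca[["in"]] / cca[["out"]]) * exp(-v[3] / vT))
})

test_that("catalogue lookups validate names and tabulate 12 mechanisms", {
  expect_length(mechanism_catalog(), 12L)
  expect_error(mechanism_catalog("flux capacitor"), "unknown mechanism")
  tab <- catalog_table()
  expect_equal(nrow(tab), 12L)
  expect_identical(tab$eta[tab$name == "Na-K-Cl symporter"], 0L)
  expect_identical(tab$eta[tab$name == "Ca ATPase"], 2L)
})

test_that("mechanism JSON round trip preserves energies and currents", {
  cst <- transport_constants()
  mech <- mechanism_catalog("Na-Ca exchanger", bias = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_mechanism_json(mech, path)
  back <- read_mechanism_json(path)
  v <- seq(-80, 40, by = 20)
  expect_equal(flux(back, v, cst), flux(mech, v, cst))
  expect_identical(eta(back), eta(mech))
  expect_error(
    read_mechanism_json(withr::local_tempfile(lines = "{\"name\": \"x\"}",
                                              fileext = ".json")),
    "must contain")
})
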