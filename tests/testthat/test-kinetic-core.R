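test_that("substrate saturation follows simple binding", {
  expect_equal(substrate_saturation(100, 100), 0.5)
  expect_equal(substrate_saturation(0, 50), 0)
  expect_equal(substrate_saturation(300, 100), 0.75)
  # strictly increasing in concentration
  conc <- seq(0, 5000, by = 50)
  expect_true(all(diff(substrate_saturation(conc, 120)) > 0))
  expect_error(substrate_saturation(10, 0), "km")
  expect_error(substrate_saturation(-1, 10), "conc")
})

test_that("apparent Km inflates with competing substrates", {
  t2 <- transporter("t2", "uniporter",
                    list(A = substrate_kinetics(100),
                         B = substrate_kinetics(100)), vmax = 1)
  # no competitor present: Km unchanged
  expect_equal(apparent_km("A", "ext", t2,
                           amino_acid_pool(c(A = 50, B = 0))), 100)
  # one competitor at its own Km doubles the apparent Km
  expect_equal(apparent_km("A", "ext", t2,
                           amino_acid_pool(c(A = 50, B = 100))), 200)
  t3 <- transporter("t3", "uniporter",
                    list(A = substrate_kinetics(50),
                         B = substrate_kinetics(100),
                         C = substrate_kinetics(300)), vmax = 1)
  expect_equal(apparent_km("A", "ext", t3,
                           amino_acid_pool(c(A = 10, B = 200, C = 300))),
               50 * (1 + 200 / 100 + 300 / 300))
  expect_error(apparent_km("D", "ext", t3,
                           amino_acid_pool(c(A = 1, B = 1, C = 1))),
               "does not accept")
})

test_that("fractional saturation profile matches the apparent-Km route", {
  t2 <- transporter("t2", "uniporter",
                    list(A = substrate_kinetics(100),
                         B = substrate_kinetics(100)), vmax = 1)
  pool <- amino_acid_pool(c(A = 100, B = 100))
  prof <- fractional_saturation_profile(t2, "ext", pool)
  # two identical substrates at their Km: each occupies 1/3
  expect_equal(unname(prof), c(1 / 3, 1 / 3))
  expect_lt(sum(prof), 1)
  # brute-force recomputation per substrate through apparent_km
  for (s in c("A", "B")) {
    kapp <- apparent_km(s, "ext", t2, pool)
    expect_equal(prof[[s]], 100 / (kapp + 100))
  }
  zero <- fractional_saturation_profile(t2, "ext",
                                        amino_acid_pool(c(A = 0, B = 0)))
  expect_equal(unname(zero), c(0, 0))
})

test_that("ion saturation multiplies Hill terms on the correct faces", {
  ions <- ion_conditions(na_ext = 30, na_cyt = 30)
  none <- transporter("u", "uniporter", list(A = substrate_kinetics(100)),
                      vmax = 1)
  expect_equal(ion_saturation(none, ions, "inward"), 1)
  one <- transporter("s", "symporter", list(A = substrate_kinetics(100)),
                     couplings = list(ion_coupling("Na", "cotransport",
                                                   km_ion = 30)),
                     z = 1, vmax = 1)
  expect_equal(ion_saturation(one, ions, "inward"), 0.5)
  two <- transporter("s2", "symporter_antiporter",
                     list(A = substrate_kinetics(100)),
                     couplings = list(
                       ion_coupling("Na", "cotransport", km_ion = 30),
                       ion_coupling("K", "antiport", km_ion = 5)),
                     z = 0, vmax = 1)
  ions2 <- ion_conditions(na_ext = 30, na_cyt = 30, k_cyt = 5, k_ext = 5)
  expect_equal(ion_saturation(two, ions2, "inward"), 0.25)
  # a cotransported ion reads the cis face: inward sees external Na
  asym <- ion_conditions(na_ext = 140, na_cyt = 14)
  expect_equal(ion_saturation(one, asym, "inward"), 140 / (30 + 140))
  expect_equal(ion_saturation(one, asym, "outward"), 14 / (30 + 14))
})

test_that("membrane potential factor has the half-barrier form", {
  ions <- ion_conditions(potential = -0.06, temperature = 310)
  expect_equal(membrane_potential_factor(0, ions), 1)
  expect_equal(membrane_potential_factor(1, ion_conditions(potential = 0)), 1)
  b <- membrane_potential_factor(1, ions)
  expect_equal(b, exp(0.5 * 96485.33212 * 0.06 / (8.31446261815324 * 310)))
  expect_equal(b, 3.07, tolerance = 0.01)
  # exact reciprocal symmetry in z
  for (z in -3:3)
    expect_equal(membrane_potential_factor(z, ions) *
                   membrane_potential_factor(-z, ions), 1,
                 tolerance = 1e-12)
})

test_that("net-transport fraction is the empty-carrier probability", {
  s <- transporter("s", "symporter", list(A = substrate_kinetics(100)),
                   couplings = list(ion_coupling("Na", "cotransport")),
                   z = 1, vmax = 1)
  expect_equal(net_transport_fraction(s, "int", amino_acid_pool(c(A = 0))), 1)
  expect_equal(net_transport_fraction(s, "int",
                                      amino_acid_pool(c(A = 100))), 0.5)
  expect_equal(net_transport_fraction(s, "int",
                                      amino_acid_pool(c(A = 1e9))), 0,
               tolerance = 1e-6)
})

test_that("unidirectional fluxes obey the mechanism laws", {
  ions0 <- ion_conditions(potential = 0)
  # antiporter with an empty trans face cannot cycle
  anti <- transporter("x", "antiporter",
                      list(A = substrate_kinetics(100, 100),
                           B = substrate_kinetics(100, 100)), vmax = 10)
  rates <- unidirectional_flux(anti, "inward",
                               amino_acid_pool(c(A = 100, B = 100)),
                               amino_acid_pool(c(A = 0, B = 0)), ions0)
  expect_equal(unname(rates), c(0, 0))
  # neutral uniporter with equal pools: influx equals efflux per substrate
  uni <- transporter("u", "uniporter",
                     list(A = substrate_kinetics(100),
                          B = substrate_kinetics(200)), vmax = 5)
  pool <- amino_acid_pool(c(A = 150, B = 70))
  expect_equal(unidirectional_flux(uni, "inward", pool, pool, ions0),
               unidirectional_flux(uni, "outward", pool, pool, ions0))
  # symporter at zero potential, saturating ions, equal pools: symmetric
  sym <- transporter("s", "symporter", list(A = substrate_kinetics(100)),
                     couplings = list(ion_coupling("Na", "cotransport",
                                                   km_ion = 1e-6)),
                     z = 1, vmax = 5)
  p <- amino_acid_pool(c(A = 250))
  expect_equal(unidirectional_flux(sym, "inward", p, p, ions0),
               unidirectional_flux(sym, "outward", p, p, ions0),
               tolerance = 1e-6)
})

test_that("rates stay within the carrier cycle bound", {
  ions <- ion_conditions()
  set.seed(42)
  for (i in 1:25) {
    mech <- sample(c("uniporter", "symporter", "antiporter"), 1)
    km <- runif(2, 50, 500)
    subs <- list(A = substrate_kinetics(km[1]), B = substrate_kinetics(km[2]))
    cps <- if (mech == "symporter")
      list(ion_coupling("Na", "cotransport")) else list()
    tr <- transporter("r", mech, subs, couplings = cps,
                      z = if (mech == "antiporter") 0L else 1L,
                      vmax = runif(1, 1, 50))
    ext <- amino_acid_pool(c(A = runif(1, 0, 1000), B = runif(1, 0, 1000)))
    int <- amino_acid_pool(c(A = runif(1, 0, 5000), B = runif(1, 0, 5000)))
    for (dir in c("inward", "outward")) {
      r <- unidirectional_flux(tr, dir, ext, int, ions)
      expect_true(all(is.finite(r)) && all(r >= 0))
      bound <- tr$vmax * ion_saturation(tr, ions, dir) *
        max(membrane_potential_factor(tr$z, ions),
            1 / membrane_potential_factor(tr$z, ions))
      expect_lte(sum(r), bound + 1e-9)
    }
  }
})

test_that("antiporters exchange strictly 1:1", {
  ions <- ion_conditions()
  set.seed(7)
  for (i in 1:20) {
    tr <- transporter("x", "antiporter",
                      list(A = substrate_kinetics(runif(1, 30, 300),
                                                  runif(1, 1000, 30000)),
                           B = substrate_kinetics(runif(1, 30, 300),
                                                  runif(1, 1000, 30000))),
                      vmax = runif(1, 5, 50))
    ext <- amino_acid_pool(c(A = runif(1, 10, 500), B = runif(1, 10, 500)))
    int <- amino_acid_pool(c(A = runif(1, 10, 9000), B = runif(1, 10, 9000)))
    fb <- net_flux(tr, ext, int, ions)
    expect_equal(sum(fb$net), 0, tolerance = 1e-10 * sum(fb$influx))
  }
  # cystine/glutamate exchange: cystine influx matched by glutamate efflux
  xct <- transporter("xCT", "antiporter",
                     list(CySS = substrate_kinetics(100, NA),
                          Glu = substrate_kinetics(NA, 8000)), vmax = 6)
  fb <- net_flux(xct, amino_acid_pool(c(CySS = 100, Glu = 0)),
                 amino_acid_pool(c(CySS = 0, Glu = 8000)), ions)
  cyss <- fb[fb$substrate == "CySS", ]
  glu <- fb[fb$substrate == "Glu", ]
  expect_gt(cyss$net, 0)
  expect_lt(glu$net, 0)
  expect_equal(cyss$influx, glu$efflux)
})

test_that("a competitor strictly steals allocated flux", {
  ions <- ion_conditions()
  tr <- transporter("c", "uniporter",
                    list(A = substrate_kinetics(100),
                         B = substrate_kinetics(100)), vmax = 10)
  int <- amino_acid_pool(c(A = 50, B = 50))
  b_levels <- c(0, 50, 200, 1000, 5000)
  flux_a <- vapply(b_levels, function(b) {
    unidirectional_flux(tr, "inward", amino_acid_pool(c(A = 100, B = b)),
                        int, ions)[["A"]]
  }, numeric(1))
  expect_true(all(diff(flux_a) < 0))
})

test_that("symporter equilibrium never exceeds its accumulation limit", {
  # detailed balance of the rate law: zero net flux exactly at the
  # ion-saturation ratio times beta^2, which is bounded by the limit
  ions <- ion_conditions()
  set.seed(11)
  for (i in 1:20) {
    km <- runif(1, 100, 1000)
    cp <- ion_coupling("Na", "cotransport", km_ion = runif(1, 5, 5000))
    tr <- transporter("s", "symporter", list(A = substrate_kinetics(km)),
                      couplings = list(cp), z = 1, vmax = runif(1, 1, 100))
    beta <- membrane_potential_factor(1, ions)
    ratio <- (ion_saturation(tr, ions, "inward") /
                ion_saturation(tr, ions, "outward")) * beta^2
    expect_lte(ratio, thermodynamic_limit(tr, ions) * (1 + 1e-9))
    ext <- amino_acid_pool(c(A = runif(1, 10, 300)))
    int <- amino_acid_pool(c(A = ratio * as.numeric(ext)))
    fb <- net_flux(tr, ext, int, ions)
    expect_equal(fb$net, 0, tolerance = 1e-9 * fb$influx)
  }
})

test_that("pools and ion conditions validate their invariants", {
  expect_error(amino_acid_pool(c(A = -1)), ">= 0")
  expect_error(amino_acid_pool(c(1, 2)), "named")
  expect_error(pool_conc(amino_acid_pool(c(A = 1)), "B"), "not in pool")
  expect_error(ion_conditions(na_ext = 0), "> 0")
  expect_error(ion_conditions(temperature = -1), "> 0")
  expect_error(ion_conc(ion_conditions(), "Ca"), "unknown ion")
  expect_equal(ion_conc(ion_conditions(ph_ext = 7), "H", "ext"), 1e-4)
})

test_that("transporter construction enforces the second-law rules", {
  expect_error(transporter("u", "uniporter",
                           list(A = substrate_kinetics(100, 200)), vmax = 1),
               "equal extracellular and cytosolic Km")
  expect_error(transporter("s", "symporter",
                           list(A = substrate_kinetics(100, 150)), vmax = 1),
               "equal extracellular and cytosolic Km")
  expect_error(transporter("x", "antiporter",
                           list(A = substrate_kinetics(100, NA),
                                B = substrate_kinetics(100, NA)), vmax = 1),
               "each.*face|both|face")
  expect_error(transporter("u", "uniporter",
                           list(A = substrate_kinetics(100)), vmax = 0),
               "vmax")
  expect_silent(transporter("x", "antiporter",
                            list(A = substrate_kinetics(100, 10000)),
                            vmax = 1))
})
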