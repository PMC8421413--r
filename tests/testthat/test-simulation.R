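test_that("flux-to-concentration conversion is dimensionally correct", {
  m <- cell_model(list(), volume_fl = 2000, cells_per_ug = 7000)
  # 10 nmol/mg/min into 7e6 cells of 2 pL each: 1e-8 mol / 1.4e-5 L
  expect_equal(flux_increment(10, 1, m), 10e-9 / (7e6 * 2e-12) * 1e6,
               tolerance = 1e-12)
  expect_equal(flux_increment(0, 1, m), 0)
  m2 <- cell_model(list(), volume_fl = 4000, cells_per_ug = 7000)
  expect_equal(flux_increment(10, 1, m2), flux_increment(10, 1, m) / 2)
  expect_equal(flux_increment(-5, 2, m), -flux_increment(5, 2, m))
  expect_error(cell_model(list(), volume_fl = 0, cells_per_ug = 1), "> 0")
})

test_that("a step without transporters or metabolism changes nothing", {
  m <- cell_model(list(), 2000, 7000)
  st <- simulation_state(amino_acid_pool(c(A = 100)),
                         amino_acid_pool(c(A = 40)))
  st2 <- step_simulation(st, m, simulation_config(dt = 0.1))
  expect_equal(unclass(st2$cytosol), c(A = 40))
  expect_equal(st2$time, 0.1)
  expect_equal(unclass(st2$medium), unclass(st$medium))
})

test_that("first-order depletion matches the exponential solution", {
  r <- 0.05
  m <- cell_model(list(), 2000, 7000,
                  depletions = list(list(species = "A", rate = r)))
  cfg <- simulation_config(dt = 0.01, n_steps = 3000L, tol = 1e-12)
  sim <- run_simulation(m, amino_acid_pool(c(A = 100)),
                        initial = amino_acid_pool(c(A = 1000)), config = cfg)
  t_end <- max(sim$times)
  expect_equal(as.numeric(sim$cytosol), 1000 * exp(-r * t_end),
               tolerance = 1e-3)
})

test_that("stoichiometric conversion doubles the cystine-derived flux", {
  # quantitative CySS -> 2 Cys: cytosolic Cys gains twice what CySS loses
  m <- cell_model(list(), 2000, 7000,
                  conversions = list(list(from = "CySS", to = "Cys",
                                          rate = 0.1, mult = 2)))
  st <- simulation_state(amino_acid_pool(c(CySS = 0, Cys = 0)),
                         amino_acid_pool(c(CySS = 500, Cys = 0)))
  st2 <- step_simulation(st, m, simulation_config(dt = 0.1))
  lost <- 500 - as.numeric(pool_conc(st2$cytosol, "CySS"))
  expect_equal(as.numeric(pool_conc(st2$cytosol, "Cys")), 2 * lost)
  expect_equal(lost, 0.1 * 0.1 * 500)
})

test_that("a neutral uniporter equilibrates the cytosol with the medium", {
  toy <- make_toy_model("uniporter", seed = 3)
  sim <- suppressWarnings(
    run_simulation(toy$model, toy$medium,
                   initial = amino_acid_pool(c(A = 900, B = 5)),
                   config = toy$config))
  expect_true(sim$equilibrated)
  expect_equal(unclass(sim$cytosol), unclass(toy$medium), tolerance = 1e-3)
})

test_that("the reported equilibrium is a fixed point", {
  toy <- make_toy_model("loader_harmonizer", seed = 5)
  sim <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                         config = toy$config))
  expect_true(sim$equilibrated)
  again <- run_simulation(toy$model, toy$medium, initial = sim$cytosol,
                          config = toy$config)
  expect_equal(unclass(again$cytosol), unclass(sim$cytosol),
               tolerance = 1e-3)
  expect_lte(again$t_eq, toy$config$dt * 50)
})

test_that("pure exchanger trajectories conserve the cytosolic total", {
  toy <- make_toy_model("antiporter_pair", seed = 2)
  sim <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                         initial = toy$initial,
                                         config = toy$config))
  totals <- rowSums(sim$trajectory)
  expect_equal(totals, rep(toy$expectations$total, length(totals)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("halving dt leaves the equilibrium essentially unchanged", {
  toy <- make_toy_model("symporter", seed = 4)
  cfg1 <- toy$config
  cfg2 <- toy$config
  cfg2$dt <- cfg1$dt / 2
  cfg2$n_steps <- cfg1$n_steps * 2L
  s1 <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                        config = cfg1))
  s2 <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                        config = cfg2))
  expect_true(s1$equilibrated && s2$equilibrated)
  expect_equal(unclass(s1$cytosol), unclass(s2$cytosol), tolerance = 1e-3)
})

test_that("concentrations never go negative and the medium never moves", {
  toy <- make_toy_model("loader_harmonizer_controller", seed = 9)
  sim <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                         config = toy$config))
  expect_true(all(sim$trajectory >= 0))
  expect_identical(unclass(sim$medium), unclass(toy$medium))
})

test_that("divergent rosters abort with a thermodynamics diagnostic", {
  # an EAAT-type roster can accumulate beyond 1 M from a rich medium
  eaat <- transporter("EAAT1", "symporter",
                      list(Glu = substrate_kinetics(50)),
                      couplings = list(
                        ion_coupling("Na", "cotransport", count = 3,
                                     km_ion = 100),
                        ion_coupling("H", "cotransport", km_ion = 4e-5),
                        ion_coupling("K", "antiport")),
                      z = 2, vmax = 2e4)
  m <- cell_model(list(eaat), 2000, 7000)
  expect_gt(thermodynamic_limit(eaat, m$ions), 1e6)
  expect_error(
    suppressWarnings(run_simulation(m, amino_acid_pool(c(Glu = 5000)),
                                    config = simulation_config(
                                      dt = 0.05, n_steps = 100000L,
                                      tol = 1e-9))),
    "exceeded 1 M")
})

test_that("spiking an exchanger substrate displaces its partners", {
  toy <- make_toy_model("antiporter_pair", seed = 6)
  base <- suppressWarnings(
    run_simulation(toy$model, toy$medium, initial = toy$initial,
                   config = toy$config))
  spiked <- suppressWarnings(
    spike_experiment(toy$model, toy$medium,
                     spikes = c(A = 5 * as.numeric(pool_conc(toy$medium, "A"))),
                     config = toy$config, baseline = base))
  expect_gt(pool_conc(spiked$cytosol, "A"), pool_conc(base$cytosol, "A"))
  expect_lt(pool_conc(spiked$cytosol, "B"), pool_conc(base$cytosol, "B"))
  # 1:1 exchange: the displaced partner balances the gain
  expect_equal(sum(spiked$cytosol), sum(base$cytosol), tolerance = 1e-6)
  expect_error(spike_experiment(toy$model, toy$medium, c(Z = 10),
                                config = toy$config, baseline = base),
               "absent from the medium")
})

test_that("spiking a species carried by no transporter does nothing", {
  toy <- make_toy_model("uniporter", seed = 8)
  med <- amino_acid_pool(c(unclass(toy$medium), Z = 100))
  base <- run_simulation(toy$model, med, config = toy$config)
  spiked <- spike_experiment(toy$model, med, c(Z = 500),
                             config = toy$config, baseline = base)
  expect_equal(pool_conc(spiked$cytosol, "Z"), pool_conc(base$cytosol, "Z"))
})

test_that("uniform medium scaling scales a single-symporter equilibrium", {
  toy <- make_toy_model("symporter", seed = 10)
  base <- suppressWarnings(run_simulation(toy$model, toy$medium,
                                          config = toy$config))
  spiked <- suppressWarnings(
    spike_experiment(toy$model, toy$medium,
                     spikes = 5 * unclass(toy$medium),
                     config = toy$config, baseline = base))
  expect_true(spiked$equilibrated)
  expect_equal(as.numeric(spiked$cytosol), 5 * as.numeric(base$cytosol),
               tolerance = 0.01)
})

test_that("trajectory sampling and tidy export are consistent", {
  toy <- make_toy_model("antiporter_pair", seed = 1)
  sim <- run_simulation(toy$model, toy$medium, initial = toy$initial,
                        config = toy$config)
  tab <- as.data.frame(sim)
  expect_setequal(unique(tab$compartment), c("cytosol", "medium"))
  samp <- sample_trajectory(sim, c(0, max(sim$times)))
  a0 <- samp[samp$species == "A" & samp$time == 0, "concentration"]
  expect_equal(a0, as.numeric(pool_conc(toy$initial, "A")))
  # past-equilibrium samples hold the equilibrium value
  held <- sample_trajectory(sim, max(sim$times) + 60)
  expect_equal(held$concentration[held$species == "A"],
               as.numeric(pool_conc(sim$cytosol, "A")))
  expect_error(sample_trajectory(sim, -1), "outside")
  unfinished <- sim
  unfinished$equilibrated <- FALSE
  expect_error(sample_trajectory(unfinished, max(sim$times) + 1),
               "equilibrium")
})
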