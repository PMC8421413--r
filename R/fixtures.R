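# run code with a temporary RNG state seeded from `seed`; restores the
# caller's stream so generators have no hidden global side effects
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Toy cell models with known analytic behavior
#'
#' Generates minimal, fully valid cell models whose equilibrium behavior is
#' known in closed form, for testing every stage of the simulator without
#' external parameter tables. Parameters are jittered deterministically from
#' the seed; the attached expectations are computed for the drawn parameters.
#'
#' \describe{
#'   \item{"uniporter"}{one neutral uniporter, two substrates; equilibrium
#'     cytosol equals the medium (detailed balance).}
#'   \item{"symporter"}{one Na+-coupled electrogenic symporter with a single
#'     substrate and a deliberately high ion Km, so the carrier senses the
#'     full Na+ gradient; the equilibrium accumulation ratio equals the
#'     ion-saturation ratio times beta^2 and approaches the closed-form
#'     thermodynamic limit.}
#'   \item{"antiporter_pair"}{one symmetric 1:1 exchanger with two
#'     substrates; the total cytosolic amount is conserved, and the
#'     equilibrium splits that total in proportion to the extracellular
#'     concentrations.}
#'   \item{"loader_harmonizer"}{a Na+ symporter (loader) for substrate A
#'     plus an asymmetric exchanger (harmonizer) for A and B; B is elevated
#'     above the medium by tertiary active transport, and both species settle
#'     at the loader's accumulation ratio.}
#'   \item{"loader_harmonizer_controller"}{adds a low-affinity electroneutral
#'     Na+-symport/H+-antiport controller; removing the loader lowers, and
#'     removing the controller raises, the shared-substrate equilibria.}
#' }
#'
#' @param kind toy model kind (see Details).
#' @param seed integer seed; the same seed always returns the same model.
#' @return list with elements \code{model} (\code{\link{cell_model}}),
#'   \code{medium} (\code{\link{amino_acid_pool}}), \code{initial} (starting
#'   cytosol; NULL means "use the medium"), \code{config} (a
#'   \code{\link{simulation_config}} adequate for the toy's stiffness) and
#'   \code{expectations} (named list of machine-checkable expected values).
#' @export
make_toy_model <- function(kind = c("uniporter", "symporter",
                                    "antiporter_pair", "loader_harmonizer",
                                    "loader_harmonizer_controller"),
                           seed = 1L) {
  kind <- match.arg(kind)
  .with_seed(seed, {
    ions <- ion_conditions()
    switch(kind,
      uniporter = {
        km <- runif(1, 300, 700)
        vmax <- runif(1, 10, 30)
        med <- amino_acid_pool(c(A = runif(1, 100, 300),
                                 B = runif(1, 50, 150)))
        tr <- transporter("UNI", "uniporter",
                          list(A = substrate_kinetics(km),
                               B = substrate_kinetics(km)),
                          z = 0, vmax = vmax)
        list(model = cell_model(list(tr), 2000, 7000, ions,
                                name = "toy uniporter"),
             medium = med, initial = NULL,
             config = simulation_config(dt = 0.05, n_steps = 40000L,
                                        tol = 1e-6),
             expectations = list(equilibrium = unclass(med)))
      },
      symporter = {
        km <- runif(1, 300, 700)
        vmax <- runif(1, 5e4, 2e5)
        med <- amino_acid_pool(c(A = runif(1, 50, 150)))
        # ion Km far above physiological Na+, so saturation ratios track the
        # full concentration gradient and the equilibrium approaches the
        # thermodynamic limit
        cp <- ion_coupling("Na", "cotransport", km_ion = 3e4)
        tr <- transporter("SYM", "symporter",
                          list(A = substrate_kinetics(km)),
                          couplings = list(cp), z = 1, vmax = vmax)
        beta <- membrane_potential_factor(1, ions)
        ratio <- (.hill(ions$na_ext, cp$km_ion, 1) /
                    .hill(ions$na_cyt, cp$km_ion, 1)) * beta^2
        list(model = cell_model(list(tr), 2000, 7000, ions,
                                name = "toy symporter"),
             medium = med, initial = NULL,
             config = simulation_config(dt = 0.05, n_steps = 40000L,
                                        tol = 1e-5),
             expectations = list(
               ratio = ratio,
               equilibrium = unclass(med) * ratio,
               limit = thermodynamic_limit(tr, ions)))
      },
      antiporter_pair = {
        km <- runif(1, 80, 150)
        vmax <- runif(1, 30, 80)
        med <- amino_acid_pool(c(A = runif(1, 100, 200),
                                 B = runif(1, 30, 80)))
        total <- runif(1, 800, 1200)
        tr <- transporter("EXCH", "antiporter",
                          list(A = substrate_kinetics(km, km),
                               B = substrate_kinetics(km, km)),
                          z = 0, vmax = vmax)
        list(model = cell_model(list(tr), 2000, 7000, ions,
                                name = "toy antiporter pair"),
             medium = med,
             initial = amino_acid_pool(c(A = total / 2, B = total / 2)),
             config = simulation_config(dt = 0.05, n_steps = 40000L,
                                        tol = 1e-6),
             expectations = list(
               total = total,
               equilibrium = total * unclass(med) / sum(med)))
      },
      loader_harmonizer = ,
      loader_harmonizer_controller = {
        km_load <- runif(1, 200, 400)
        v_load <- runif(1, 15, 25)
        v_harm <- runif(1, 30, 50)
        med <- amino_acid_pool(c(A = 100, B = 100))
        cp <- ion_coupling("Na", "cotransport")
        loader <- transporter("LOAD", "symporter",
                              list(A = substrate_kinetics(km_load)),
                              couplings = list(cp), z = 1, vmax = v_load)
        harmonizer <- transporter("HARM", "antiporter",
                                  list(A = substrate_kinetics(100, 10000),
                                       B = substrate_kinetics(100, 10000)),
                                  z = 0, vmax = v_harm)
        beta <- membrane_potential_factor(1, ions)
        load_ratio <- (.hill(ions$na_ext, cp$km_ion, 1) /
                         .hill(ions$na_cyt, cp$km_ion, 1)) * beta^2
        roster <- list(loader, harmonizer)
        expectations <- list(
          loader_ratio = load_ratio,
          equilibrium = unclass(med) * load_ratio,
          elevated_species = "B")
        if (kind == "loader_harmonizer_controller") {
          ctrl <- transporter("CTRL", "symporter_antiporter",
                              list(A = substrate_kinetics(3000),
                                   B = substrate_kinetics(3000)),
                              couplings = list(
                                ion_coupling("Na", "cotransport"),
                                ion_coupling("H", "antiport")),
                              z = 0, vmax = runif(1, 30, 50))
          roster <- c(roster, list(ctrl))
          h_cyt <- ion_conc(ions, "H", "cyt")
          h_ext <- ion_conc(ions, "H", "ext")
          ctrl_ratio <- (.hill(ions$na_ext, cp$km_ion, 1) /
                           .hill(ions$na_cyt, cp$km_ion, 1)) *
            (.hill(h_cyt, 5e-5, 1) / .hill(h_ext, 5e-5, 1))
          expectations <- list(
            loader_ratio = load_ratio,
            controller_ratio = ctrl_ratio,
            loader = "LOAD", controller = "CTRL",
            elevated_species = "B",
            # the full-model equilibrium sits between the controller's and
            # the loader's accumulation ratios
            ratio_bounds = c(ctrl_ratio, load_ratio))
        }
        list(model = cell_model(roster, 2000, 7000, ions, name = kind),
             medium = med, initial = NULL,
             config = simulation_config(dt = 0.05, n_steps = 40000L,
                                        tol = 1e-6),
             expectations = expectations)
      })
  })
}

#' Pseudo-observed concentration table from a simulation
#'
#' Applies multiplicative log-normal noise to the simulated equilibrium
#' concentrations, emulating the sampling variability of an LC-MS
#' measurement; used to exercise the agreement statistics with known ground
#' truth. With \code{noise_cv = 0} the copy is exact; output is bit-identical
#' for a fixed seed.
#'
#' @param result an \code{aa_simulation} (or a named numeric vector of
#'   concentrations).
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   >= 0.
#' @param seed integer seed.
#' @return data frame with columns species, concentration (µM).
#' @export
make_pseudo_observations <- function(result, noise_cv = 0.1, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  conc <- if (inherits(result, "aa_simulation")) unclass(result$cytosol)
          else result
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- conc * exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog))
    data.frame(species = names(conc), concentration = unname(noisy))
  })
}
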