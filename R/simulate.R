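#' Cell model: transporter roster, geometry, ions and metabolism
#'
#' @param transporters list of \code{\link{transporter}} objects; names are
#'   taken from the transporters themselves and must be unique.
#' @param volume_fl mean cell volume in fL.
#' @param cells_per_ug correlate of protein mass and cell number
#'   (cells per µg protein); together with the volume it converts fluxes in
#'   nmol (mg protein)^-1 min^-1 into cytosolic concentration changes.
#' @param ions \code{\link{ion_conditions}}.
#' @param conversions list of metabolic conversions, each a list with
#'   \code{from}, \code{to}, \code{rate} (first-order fractional rate, min^-1)
#'   and \code{mult} (stoichiometric multiplier, e.g. 2 for cystine giving two
#'   cysteines).
#' @param depletions list of depletion terms, each a list with
#'   \code{species} and \code{rate} (min^-1); covers metabolism or protein
#'   synthesis drains.
#' @param name optional model name.
#' @return object of class \code{cell_model}.
#' @export
cell_model <- function(transporters, volume_fl, cells_per_ug,
                       ions = ion_conditions(), conversions = list(),
                       depletions = list(), name = "cell model") {
  if (!all(vapply(transporters, inherits, TRUE, "transporter")))
    stop("transporters must be a list of transporter objects", call. = FALSE)
  nm <- vapply(transporters, function(t) t$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate transporter names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(transporters) <- nm
  if (!is.finite(volume_fl) || volume_fl <= 0)
    stop("volume_fl must be > 0", call. = FALSE)
  if (!is.finite(cells_per_ug) || cells_per_ug <= 0)
    stop("cells_per_ug must be > 0", call. = FALSE)
  if (!inherits(ions, "ion_conditions"))
    stop("ions must be an ion_conditions object", call. = FALSE)
  for (cv in conversions) {
    if (!all(c("from", "to", "rate", "mult") %in% names(cv)))
      stop("each conversion needs from, to, rate, mult", call. = FALSE)
    if (cv$rate < 0) stop("conversion rates must be >= 0", call. = FALSE)
    if (cv$mult < 1) stop("conversion multiplier must be >= 1", call. = FALSE)
  }
  for (dp in depletions) {
    if (!all(c("species", "rate") %in% names(dp)))
      stop("each depletion needs species and rate", call. = FALSE)
    if (dp$rate < 0) stop("depletion rates must be >= 0", call. = FALSE)
  }
  structure(list(transporters = transporters, volume_fl = volume_fl,
                 cells_per_ug = cells_per_ug, ions = ions,
                 conversions = conversions, depletions = depletions,
                 name = name),
            class = "cell_model")
}

#' All substrate species used by a model's roster
#' @param model a \code{\link{cell_model}}.
#' @return character vector of species codes.
#' @export
model_species <- function(model) {
  unique(unlist(lapply(model$transporters,
                       function(t) names(t$substrates)), use.names = FALSE))
}

#' Simulation configuration
#'
#' @param dt time step in minutes (default 0.05, comparable to the step that
#'   puts a 3-h run at a few thousand iterations).
#' @param n_steps maximum number of iterations.
#' @param tol equilibrium tolerance: the run stops once the relative
#'   concentration change per minute of every species above the floor falls
#'   below \code{tol}.
#' @param record_stride record the trajectory every this many steps.
#' @param floor_um concentration floor (µM) below which a species is excluded
#'   from the relative-change criterion, so trace species cannot stall
#'   convergence detection.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(dt = 0.05, n_steps = 20000L, tol = 1e-4,
                              record_stride = 20L, floor_um = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (record_stride < 1) stop("record_stride must be >= 1", call. = FALSE)
  structure(list(dt = dt, n_steps = as.integer(n_steps), tol = tol,
                 record_stride = as.integer(record_stride),
                 floor_um = floor_um),
            class = "simulation_config")
}

#' Convert a transport flux into a cytosolic concentration increment
#'
#' Fluxes are expressed per mg of cell protein; the protein-to-cell correlate
#' c (cells per µg) converts 1 mg protein into 1000 c cells, whose combined
#' cytosolic volume is 1000 c V_cell. Dividing the transported amount by that
#' volume yields the concentration change.
#'
#' @param flux rate in nmol (mg protein)^-1 min^-1 (sign preserved);
#'   vectorized.
#' @param dt time interval in minutes.
#' @param model a \code{\link{cell_model}} supplying volume and correlate.
#' @return concentration change in µM over \code{dt}.
#' @examples
#' m <- cell_model(list(), volume_fl = 2000, cells_per_ug = 7000)
#' flux_increment(10, 1, m)  # about 714 µM
#' @export
flux_increment <- function(flux, dt, model) {
  vol_l <- 1000 * model$cells_per_ug * model$volume_fl * 1e-15  # L per mg
  flux * 1e-9 / vol_l * 1e6 * dt
}

#' Simulation state
#'
#' Bundles the current time, the fixed extracellular pool and the evolving
#' cytosolic pool.
#'
#' @param medium extracellular \code{\link{amino_acid_pool}} (held fixed).
#' @param cytosol cytosolic \code{\link{amino_acid_pool}}.
#' @param time current time in minutes.
#' @return object of class \code{simulation_state}.
#' @export
simulation_state <- function(medium, cytosol, time = 0) {
  if (!inherits(medium, "aa_pool")) medium <- amino_acid_pool(medium)
  if (!inherits(cytosol, "aa_pool")) cytosol <- amino_acid_pool(cytosol)
  structure(list(time = time, medium = medium, cytosol = cytosol),
            class = "simulation_state")
}

# apply first-order conversions/depletions to a named concentration vector,
# returning the per-species µM change over dt
.metabolism_delta <- function(conc, model, dt) {
  d <- numeric(length(conc))
  names(d) <- names(conc)
  for (cv in model$conversions) {
    moved <- cv$rate * dt * conc[[cv$from]]
    d[[cv$from]] <- d[[cv$from]] - moved
    d[[cv$to]] <- d[[cv$to]] + cv$mult * moved
  }
  for (dp in model$depletions)
    d[[dp$species]] <- d[[dp$species]] - dp$rate * dt * conc[[dp$species]]
  d
}

#' Advance the simulation by one time step
#'
#' One cycle of the homeostasis loop: compute the flux breakdown of every
#' transporter at the current concentrations, sum net fluxes per species,
#' convert to concentration increments through the cell volume, apply
#' first-order metabolic conversions and depletions, clamp at zero (with a
#' warning) if a step overshoots, and advance time by dt.
#'
#' @param state a \code{\link{simulation_state}}.
#' @param model a \code{\link{cell_model}}.
#' @param config a \code{\link{simulation_config}}.
#' @return the advanced \code{simulation_state}.
#' @export
step_simulation <- function(state, model, config = simulation_config()) {
  cyt <- state$cytosol
  net <- stats::setNames(numeric(length(cyt)), names(cyt))
  for (tr in model$transporters) {
    fb <- net_flux(tr, state$medium, cyt, model$ions)
    if (any(!is.finite(fb$influx)) || any(!is.finite(fb$efflux)))
      stop("non-finite flux computed for transporter ", tr$name,
           call. = FALSE)
    net[fb$substrate] <- net[fb$substrate] + fb$net
  }
  newc <- unclass(cyt) + flux_increment(net, config$dt, model) +
    .metabolism_delta(unclass(cyt), model, config$dt)
  if (any(newc < 0)) {
    warning("step overshoot: clamped ",
            paste(names(newc)[newc < 0], collapse = ", "),
            " at 0; consider a smaller dt", call. = FALSE)
    newc[newc < 0] <- 0
  }
  simulation_state(state$medium, amino_acid_pool(newc),
                   time = state$time + config$dt)
}

# ---- optimized stepping used by run_simulation --------------------------
# The extracellular pool and ion conditions are fixed during a run, so every
# extracellular-face quantity (fractional saturations, ion saturations, the
# potential factor and the outward blend factor) is precomputed once; only
# cytosolic-face quantities are recomputed per step.
.compile_transporter <- function(tr, species, medium, ions) {
  km_ext <- face_km(tr, "ext")
  km_int <- face_km(tr, "int")
  idx_ext <- match(names(km_ext), species)
  idx_int <- match(names(km_int), species)
  if (anyNA(idx_int) || anyNA(idx_ext))
    stop("substrates of ", tr$name, " missing from the simulation species",
         call. = FALSE)
  ext_conc <- pool_conc(medium, names(km_ext))
  load_ext <- ext_conc / km_ext
  frac_ext <- load_ext / (1 + sum(load_ext))
  occ_ext <- sum(frac_ext)
  isat_in <- .ion_saturation_vec(tr, ions, "inward", names(km_ext))
  isat_out <- .ion_saturation_vec(tr, ions, "outward", names(km_int))
  mech <- tr$mechanism
  electro <- !(mech %in% c("antiporter", "symporter_antiporter")) && tr$z != 0
  beta <- if (electro) membrane_potential_factor(tr$z, ions) else 1

  out <- list(name = tr$name, mech = mech, idx_ext = idx_ext,
              idx_int = idx_int, km_int = unname(km_int), beta = beta)
  if (mech == "antiporter") {
    out$w_in <- unname(tr$vmax * frac_ext * isat_in)     # x effocc_int
    out$c_out <- unname(tr$vmax * sum(frac_ext * isat_in) * isat_out)
    out$isat_out <- unname(isat_out)
  } else if (mech %in% c("symporter", "symporter_antiporter")) {
    # net-transport + exchange decomposition; the outward factor only reads
    # the fixed extracellular face, so it is a constant of the run
    out$pre_in <- unname(tr$vmax * frac_ext * isat_in)
    out$isat_out <- unname(isat_out)
    effocc_ext <- sum(frac_ext * isat_in)
    f_out <- (1 - occ_ext) / beta + effocc_ext
    out$c_out <- unname(tr$vmax * isat_out * f_out)      # x frac_int
  } else {                                               # uniporter
    f_in <- if (electro) beta else 1
    f_out <- if (electro) 1 / beta else 1
    out$base_in <- unname(tr$vmax * frac_ext * isat_in * f_in)
    out$c_out <- unname(tr$vmax * isat_out * f_out)
  }
  out
}

# net per-species rates (nmol/mg/min) for the compiled roster at cytosol
# concentrations `cyt` (plain numeric vector aligned with `species`)
.compiled_rates <- function(compiled, cyt, nspecies) {
  net <- numeric(nspecies)
  for (cp in compiled) {
    li <- cyt[cp$idx_int] / cp$km_int
    denom <- 1 + sum(li)
    frac_int <- li / denom
    if (cp$mech == "antiporter") {
      effocc_int <- sum(frac_int * cp$isat_out)
      influx <- cp$w_in * effocc_int
      efflux <- cp$c_out * frac_int
    } else if (!is.null(cp$pre_in)) {           # (mixed) symporter
      f_in <- (1 - sum(frac_int)) * cp$beta + sum(frac_int * cp$isat_out)
      influx <- cp$pre_in * f_in
      efflux <- cp$c_out * frac_int
    } else {
      influx <- cp$base_in
      efflux <- cp$c_out * frac_int
    }
    net[cp$idx_ext] <- net[cp$idx_ext] + influx
    net[cp$idx_int] <- net[cp$idx_int] - efflux
  }
  net
}

#' Run a transport simulation to equilibrium
#'
#' Evolves the cytosolic pool under a fixed extracellular medium by explicit
#' forward-Euler stepping until either \code{n_steps} is exhausted or every
#' species above the concentration floor changes by less than \code{tol}
#' (relative, per minute). The system of competing transporters is expected
#' to be inherently stable; the final state is independent of the initial
#' cytosolic concentrations (except for pure exchanger systems, whose
#' conserved total is set by the initial pool).
#'
#' @param model a \code{\link{cell_model}}.
#' @param medium extracellular \code{\link{amino_acid_pool}} (or named
#'   vector), held fixed throughout.
#' @param initial initial cytosolic pool; defaults to the medium
#'   concentrations.
#' @param config a \code{\link{simulation_config}}.
#' @return an \code{aa_simulation} object with elements \code{times},
#'   \code{trajectory} (matrix, time by species), \code{cytosol} (final
#'   pool), \code{medium}, \code{equilibrated}, \code{t_eq}, \code{flux}
#'   (final \code{flux_breakdown}), \code{clamped} (number of clamped
#'   steps) and \code{config}. Use \code{as.data.frame()} for a tidy
#'   (time, species, compartment, concentration) table.
#' @details Any concentration exceeding 1 M aborts the run: with the shipped
#'   rate laws this can only happen when a roster violates thermodynamic
#'   consistency (e.g. an active EAAT-type transporter, whose theoretical
#'   accumulation exceeds 100 M). A warning is issued if any species moves
#'   more than 5 percent of its current value in a single step, a sign that
#'   dt is too large for the stiffest transporter in the roster.
#' @export
run_simulation <- function(model, medium, initial = NULL,
                           config = simulation_config()) {
  if (!inherits(medium, "aa_pool")) medium <- amino_acid_pool(medium)
  species <- names(medium)
  missing <- setdiff(model_species(model), species)
  if (length(missing))
    stop("medium lacks roster substrates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(initial)) initial <- medium
  if (!inherits(initial, "aa_pool")) initial <- amino_acid_pool(initial)
  if (!setequal(names(initial), species))
    stop("initial cytosol must cover the same species as the medium",
         call. = FALSE)
  cyt <- pool_conc(initial, species)
  names(cyt) <- species
  for (cv in model$conversions)
    if (!all(c(cv$from, cv$to) %in% species))
      stop("conversion species missing from the pools", call. = FALSE)
  for (dp in model$depletions)
    if (!dp$species %in% species)
      stop("depletion species missing from the pools", call. = FALSE)

  compiled <- lapply(model$transporters, .compile_transporter,
                     species = species, medium = medium, ions = model$ions)
  dt <- config$dt
  ns <- length(species)
  vol_factor <- 1e-9 / (1000 * model$cells_per_ug * model$volume_fl * 1e-15) *
    1e6                                             # µM per (nmol/mg)
  n_rec <- length(seq(0L, config$n_steps, by = config$record_stride))
  traj <- matrix(NA_real_, nrow = n_rec + 1L, ncol = ns,
                 dimnames = list(NULL, species))
  times <- numeric(n_rec + 1L)
  traj[1L, ] <- cyt
  rec <- 1L
  equilibrated <- FALSE
  t_eq <- NA_real_
  clamped <- 0L
  overshoot_warned <- FALSE

  has_metab <- length(model$conversions) > 0 || length(model$depletions) > 0
  # diagnostics and the convergence test run every few steps: they cost as
  # much as a rate evaluation, and a stop a few steps late is harmless
  check_every <- 4L
  for (i in seq_len(config$n_steps)) {
    rate <- .compiled_rates(compiled, cyt, ns)           # nmol/mg/min
    delta <- rate * (vol_factor * dt)
    if (has_metab) delta <- delta + .metabolism_delta(cyt, model, dt)
    newc <- cyt + delta
    if (any(newc < 0)) {
      clamped <- clamped + 1L
      newc[newc < 0] <- 0
    }
    cyt <- newc
    if (i %% config$record_stride == 0L) {
      rec <- rec + 1L
      traj[rec, ] <- cyt
      times[rec] <- i * dt
    }
    if (i %% check_every == 0L || i == config$n_steps) {
      if (any(!is.finite(rate))) {
        culprit <- .diagnose_nonfinite(compiled, cyt, ns)
        stop("non-finite flux at t=", (i - 1) * dt, " min (transporter ",
             culprit, ")", call. = FALSE)
      }
      if (any(cyt > 1e6))
        stop("concentration of ", species[which.max(cyt)],
             " exceeded 1 M at t=", i * dt, " min: thermodynamic runaway ",
             "(check the roster against its accumulation limits)",
             call. = FALSE)
      if (!overshoot_warned) {
        big <- abs(delta) > 0.05 * pmax(cyt, config$floor_um)
        if (any(big)) {
          warning("species ", paste(species[big], collapse = ", "),
                  " changed by >5% in one step at t=", (i - 1) * dt,
                  " min; consider a smaller dt", call. = FALSE)
          overshoot_warned <- TRUE
        }
      }
      active <- cyt > config$floor_um
      if (!any(active) ||
          max(abs(delta[active]) / cyt[active]) / dt < config$tol) {
        equilibrated <- TRUE
        t_eq <- i * dt
        break
      }
    }
  }
  if (times[rec] < ifelse(equilibrated, t_eq, config$n_steps * dt)) {
    rec <- rec + 1L
    traj[rec, ] <- cyt
    times[rec] <- if (equilibrated) t_eq else config$n_steps * dt
  }
  if (clamped > 0L)
    warning(clamped, " step(s) overshot below zero and were clamped; ",
            "consider a smaller dt", call. = FALSE)

  final <- amino_acid_pool(cyt)
  structure(list(times = times[seq_len(rec)],
                 trajectory = traj[seq_len(rec), , drop = FALSE],
                 cytosol = final, medium = medium,
                 equilibrated = equilibrated, t_eq = t_eq,
                 flux = roster_flux(model$transporters, medium, final,
                                    model$ions),
                 clamped = clamped, config = config, model_name = model$name),
            class = "aa_simulation")
}

.diagnose_nonfinite <- function(compiled, cyt, ns) {
  for (cp in compiled) {
    r <- tryCatch(.compiled_rates(list(cp), cyt, ns), error = function(e) NaN)
    if (any(!is.finite(r))) return(cp$name)
  }
  "<unknown>"
}

#' @export
print.aa_simulation <- function(x, ...) {
  cat(sprintf("<aa_simulation> %s: %d species, t = %g min, %s\n",
              x$model_name, ncol(x$trajectory), max(x$times),
              if (x$equilibrated)
                sprintf("equilibrated at %g min", x$t_eq)
              else "not equilibrated"))
  cat("final cytosol (µM):\n")
  print(round(unclass(x$cytosol), 2))
  invisible(x)
}

#' Tidy trajectory of a simulation
#'
#' @param x an \code{aa_simulation}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns time (min), species, compartment
#'   ("cytosol" or "medium") and concentration (µM).
#' @export
as.data.frame.aa_simulation <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  sp <- colnames(x$trajectory)
  nt <- length(x$times)
  cyt <- data.frame(time = rep(x$times, times = length(sp)),
                    species = rep(sp, each = nt),
                    compartment = "cytosol",
                    concentration = as.vector(x$trajectory))
  med <- data.frame(time = 0, species = names(x$medium),
                    compartment = "medium",
                    concentration = as.numeric(x$medium))
  rbind(cyt, med)
}

#' Medium-spike experiment
#'
#' Equilibrates the model in the baseline medium, then raises (or lowers)
#' selected extracellular species to new values and follows the cytosolic
#' response from the baseline equilibrium, mimicking amino acid spiking of a
#' pre-equilibrated culture.
#'
#' @param model a \code{\link{cell_model}}.
#' @param medium baseline extracellular pool.
#' @param spikes named numeric vector: new extracellular concentrations (µM)
#'   for the spiked species; every name must exist in the medium.
#' @param config a \code{\link{simulation_config}} used for both phases.
#' @param baseline optional pre-computed baseline \code{aa_simulation} (saves
#'   re-equilibrating when several spikes share a baseline).
#' @return an \code{aa_simulation} for the post-spike phase, with the
#'   baseline run attached as attribute \code{"baseline"}.
#' @export
spike_experiment <- function(model, medium, spikes,
                             config = simulation_config(), baseline = NULL) {
  if (!inherits(medium, "aa_pool")) medium <- amino_acid_pool(medium)
  unknown <- setdiff(names(spikes), names(medium))
  if (length(unknown))
    stop("cannot spike species absent from the medium: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(baseline))
    baseline <- run_simulation(model, medium, config = config)
  spiked <- unclass(medium)
  spiked[names(spikes)] <- spikes
  res <- run_simulation(model, amino_acid_pool(spiked),
                        initial = baseline$cytosol, config = config)
  attr(res, "baseline") <- baseline
  res
}

#' Sample a simulated trajectory at chosen times
#'
#' Linear interpolation of the recorded trajectory, e.g. at the 0.25, 0.5, 1
#' and 2 h sampling points of an equilibration time course.
#'
#' @param result an \code{aa_simulation}.
#' @param times_min numeric vector of times (minutes). Times beyond the
#'   simulated range are allowed only for equilibrated runs, where the
#'   equilibrium concentrations are simply held.
#' @return data frame with columns time, species, concentration.
#' @export
sample_trajectory <- function(result, times_min) {
  if (any(times_min < 0))
    stop("requested times outside the simulated range", call. = FALSE)
  if (any(times_min > max(result$times)) && !result$equilibrated)
    stop("requested times outside the simulated range ",
         "(run did not reach equilibrium)", call. = FALSE)
  sp <- colnames(result$trajectory)
  out <- lapply(sp, function(s) {
    data.frame(time = times_min, species = s,
               concentration = stats::approx(result$times,
                                             result$trajectory[, s],
                                             xout = times_min, rule = 2)$y)
  })
  do.call(rbind, out)
}
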