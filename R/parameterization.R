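#' Maximal transport rate from an initial-rate flux measurement
#'
#' Inverts the Michaelis-Menten relation: a transport rate v measured at
#' substrate concentration [S] corresponds to
#' \code{Vmax = v (Km + [S]) / [S]}. Rates should be normalized to one
#' minute before conversion.
#'
#' @param v measured transport rate (nmol (mg protein)^-1 min^-1), >= 0.
#' @param km substrate Km (µM), > 0.
#' @param s substrate concentration used in the assay (µM), > 0.
#' @return Vmax in the same units as \code{v}; vectorized.
#' @examples
#' vmax_from_flux(1, 100, 100)  # 2
#' vmax_from_flux(3, 200, 100)  # 9
#' @export
vmax_from_flux <- function(v, km, s) {
  if (any(!is.finite(v)) || any(v < 0)) stop("v must be >= 0", call. = FALSE)
  if (any(!is.finite(km)) || any(km <= 0)) stop("km must be > 0", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0)) stop("s must be > 0", call. = FALSE)
  v * (km + s) / s
}

#' Vmax values proportional to relative mRNA expression
#'
#' When direct transport measurements are unavailable (e.g. for primary
#' myotubes), maximal rates can be allocated proportionally to relative mRNA
#' expression: \code{Vmax_i = total_scale * mrna_i / sum(mrna)}.
#'
#' @param relative_mrna named non-negative numeric vector of relative
#'   expression values (any common scale).
#' @param total_scale total transport capacity to distribute
#'   (nmol (mg protein)^-1 min^-1).
#' @return named numeric vector of Vmax values; proportionality to the input
#'   is preserved exactly and rescaling all inputs leaves the result
#'   unchanged.
#' @export
vmax_from_expression <- function(relative_mrna, total_scale) {
  if (is.null(names(relative_mrna)))
    stop("relative_mrna must be named by transporter", call. = FALSE)
  if (any(relative_mrna < 0))
    stop("expression values must be >= 0", call. = FALSE)
  tot <- sum(relative_mrna)
  if (tot == 0) stop("all expression values are zero", call. = FALSE)
  total_scale * relative_mrna / tot
}

#' Thermodynamic-consistency validation of a cell model
#'
#' Audits the parameter set against the second-law rules: (a) uniporters and
#' (mixed) symporters must carry equal Km on both faces; (b) a single Vmax
#' must govern forward and backward flux (structural in this implementation);
#' (c) every electrogenic symporter, simulated alone with a single substrate,
#' must settle at or below its closed-form accumulation limit. Additional
#' warnings flag Hill coefficients above the ion stoichiometry (which could
#' push the kinetic equilibrium past the ion-gradient limit) and nonzero
#' complex charges on mechanisms treated as electroneutral.
#'
#' @param model a \code{\link{cell_model}}.
#' @param audit_equilibrium run the numerical single-substrate audit of rule
#'   (c) (default TRUE; set FALSE to skip the simulations).
#' @return a \code{validation_report}: data frame with columns rule,
#'   transporter, status ("pass", "warn" or "fail") and message, plus a
#'   logical attribute \code{ok} (no failures).
#' @export
validate_model <- function(model, audit_equilibrium = TRUE) {
  rows <- list()
  add <- function(rule, tr, status, msg)
    rows[[length(rows) + 1L]] <<- data.frame(rule = rule, transporter = tr,
                                             status = status, message = msg)
  for (tr in model$transporters) {
    km_e <- vapply(tr$substrates, function(s) s$km_ext, numeric(1))
    km_i <- vapply(tr$substrates, function(s) s$km_int, numeric(1))
    if (tr$mechanism != "antiporter") {
      bad <- is.na(km_e) | is.na(km_i) | km_e != km_i
      if (any(bad))
        add("km_symmetry", tr$name, "fail",
            paste0("unequal cis/trans Km for ",
                   paste(names(tr$substrates)[bad], collapse = ", "),
                   ": would accumulate without a gradient"))
      else
        add("km_symmetry", tr$name, "pass", "cis/trans Km equal")
    } else {
      if (!any(!is.na(km_e)) || !any(!is.na(km_i)))
        add("exchange_faces", tr$name, "fail",
            "antiporter lacks substrates on one face")
      else
        add("exchange_faces", tr$name, "pass",
            "substrates present on both faces")
    }
    add("shared_vmax", tr$name,
        if (length(tr$vmax) == 1 && tr$vmax > 0) "pass" else "fail",
        "one Vmax governs forward and backward flux")
    for (cp in tr$couplings)
      if (cp$hill_n > cp$count)
        add("hill_vs_stoichiometry", tr$name, "warn",
            sprintf("%s coupling: Hill n=%g exceeds stoichiometric count %d",
                    cp$ion, cp$hill_n, cp$count))
    if (tr$mechanism %in% c("antiporter", "symporter_antiporter") &&
        tr$z != 0)
      add("electroneutral_charge", tr$name, "warn",
          "nonzero complex charge on a mechanism treated as electroneutral")
    if (audit_equilibrium && tr$mechanism == "symporter" && tr$z != 0) {
      res <- .audit_symporter_limit(tr, model)
      add("accumulation_limit", tr$name,
          if (res$ok) "pass" else "fail",
          sprintf("simulated %.1f-fold vs limit %.1f-fold (%s)",
                  res$ratio, res$limit, res$substrate))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("validation_report", "data.frame"),
            ok = !any(out$status == "fail"))
}

# single-substrate equilibrium audit: simulate the symporter alone at a low
# substrate concentration (the regime of maximal accumulation) and compare
# against the closed-form limit
.audit_symporter_limit <- function(tr, model) {
  sub <- names(tr$substrates)[1]
  km <- tr$substrates[[sub]]$km_ext
  conc <- km / 100
  toy <- cell_model(list(tr), volume_fl = model$volume_fl,
                    cells_per_ug = model$cells_per_ug, ions = model$ions)
  limit <- thermodynamic_limit(tr, model$ions)
  # stability-guided step: the fastest local relaxation rate is bounded by
  # vol_factor * vmax/km, scaled by the ion saturation and potential factor
  vol_factor <- 1e-9 / (1000 * model$cells_per_ug * model$volume_fl *
                          1e-15) * 1e6
  isat <- max(ion_saturation(tr, model$ions, "inward"),
              ion_saturation(tr, model$ions, "outward"), 1e-12)
  beta <- membrane_potential_factor(tr$z, model$ions)
  b <- vol_factor * tr$vmax / km * isat * max(beta, 1 / beta)
  dt <- min(0.05, 0.2 / b)
  med <- stats::setNames(rep(0, length(tr$substrates)), names(tr$substrates))
  med[sub] <- conc
  # the probe starts far from equilibrium on purpose; its transient
  # overshoot warnings are not informative to the caller
  sim <- suppressWarnings(
    run_simulation(toy, amino_acid_pool(med),
                   config = simulation_config(dt = dt, n_steps = 200000L,
                                              tol = 1e-6,
                                              record_stride = 1000L)))
  ratio <- as.numeric(sim$cytosol[sub]) / conc
  list(ok = ratio <= limit * 1.01, ratio = ratio, limit = limit,
       substrate = sub)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%d checks, %d fail, %d warn)\n",
              if (attr(x, "ok")) "PASS" else "FAIL", nrow(x),
              sum(x$status == "fail"), sum(x$status == "warn")))
  print.data.frame(x)
  invisible(x)
}

# ---- model config I/O ----------------------------------------------------

.coupling_to_list <- function(cp)
  list(ion = cp$ion, mode = cp$mode, count = cp$count, hill_n = cp$hill_n,
       km_ion = cp$km_ion, applies_to = cp$applies_to)

.transporter_to_list <- function(tr) {
  subs <- lapply(tr$substrates, function(s)
    list(km_ext = if (is.na(s$km_ext)) NULL else s$km_ext,
         km_int = if (is.na(s$km_int)) NULL else s$km_int,
         estimated = s$estimated))
  list(name = tr$name, mechanism = tr$mechanism, z = tr$z, vmax = tr$vmax,
       couplings = lapply(tr$couplings, .coupling_to_list),
       substrates = subs)
}

#' Write a cell model to a YAML config file
#'
#' The config is a human-editable structured-text file: one record per
#' transporter (mechanism, charge, Vmax, ion couplings and a two-sided Km
#' table per substrate, µM), plus cell geometry, ion conditions and the
#' metabolic conversion/depletion rules. \code{\link{read_cell_model}} is its
#' inverse; a written model reads back identically.
#'
#' @param model a \code{\link{cell_model}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cell_model <- function(model, path) {
  ions <- model$ions
  doc <- list(
    format = "aaflux-model/1",
    name = model$name,
    units = list(km = "uM", vmax = "nmol/mg protein/min", volume = "fL",
                 cells_per_ug = "cells/ug protein", ion_km = "mM",
                 rate = "1/min"),
    volume_fl = model$volume_fl,
    cells_per_ug = model$cells_per_ug,
    ions = list(na_ext = ions$na_ext, na_cyt = ions$na_cyt,
                k_ext = ions$k_ext, k_cyt = ions$k_cyt,
                ph_ext = ions$ph_ext, ph_cyt = ions$ph_cyt,
                potential = ions$potential, temperature = ions$temperature),
    conversions = model$conversions,
    depletions = model$depletions,
    transporters = lapply(unname(model$transporters), .transporter_to_list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a cell model from a YAML config file
#'
#' @param path path to a config written by \code{\link{write_cell_model}} (or
#'   hand-edited in the same schema).
#' @return a validated \code{\link{cell_model}}.
#' @export
read_cell_model <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse model config ", path, ": ", conditionMessage(e),
         call. = FALSE))
  req <- c("transporters", "volume_fl", "cells_per_ug")
  miss <- setdiff(req, names(doc))
  if (length(miss))
    stop("model config ", path, " lacks field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ions <- if (is.null(doc$ions)) ion_conditions() else
    do.call(ion_conditions, doc$ions)
  trs <- lapply(seq_along(doc$transporters), function(i) {
    td <- doc$transporters[[i]]
    for (f in c("name", "mechanism", "vmax", "substrates"))
      if (is.null(td[[f]]))
        stop("transporter record ", i, " in ", path, " lacks '", f, "'",
             call. = FALSE)
    subs <- lapply(td$substrates, function(s)
      substrate_kinetics(km_ext = if (is.null(s$km_ext)) NA else s$km_ext,
                         km_int = if (is.null(s$km_int)) NA else s$km_int,
                         estimated = isTRUE(s$estimated)))
    cps <- lapply(td$couplings, function(cl) do.call(ion_coupling, cl))
    transporter(td$name, td$mechanism, subs, couplings = cps,
                z = if (is.null(td$z)) 0L else td$z, vmax = td$vmax)
  })
  cell_model(trs, volume_fl = doc$volume_fl,
             cells_per_ug = doc$cells_per_ug, ions = ions,
             conversions = if (is.null(doc$conversions)) list() else
               doc$conversions,
             depletions = if (is.null(doc$depletions)) list() else
               doc$depletions,
             name = if (is.null(doc$name)) "cell model" else doc$name)
}
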