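#' Thermodynamic accumulation limit of a transporter
#'
#' Closed-form maximal cytosol/medium concentration ratio permitted by the
#' coupled ion gradients and the membrane potential: the product over
#' cotransported ions of (ext/cyt)^count, over antiported ions of
#' (cyt/ext)^count, times \code{exp(-z F dPsi / (R T))} with the full
#' potential exponent (the half-barrier of the kinetic factor shapes rates;
#' the full exponent shapes equilibria). An ion-free electroneutral carrier
#' has a limit of exactly 1: a uniporter cannot accumulate.
#'
#' @param tr a \code{\link{transporter}}.
#' @param ions \code{\link{ion_conditions}}; the package defaults give the
#'   textbook physiological gradients (Na+ 140/14 mM, K+ 5.4/140 mM,
#'   pH 7.4/7.2, -60 mV, 310 K).
#' @return maximal accumulation ratio (fold), > 0.
#' @examples
#' snat1 <- transporter("SNAT1", "symporter",
#'   list(Gln = substrate_kinetics(300)),
#'   couplings = list(ion_coupling("Na", "cotransport")), z = 1, vmax = 5)
#' thermodynamic_limit(snat1, ion_conditions())  # about 95-fold
#' @export
thermodynamic_limit <- function(tr, ions = ion_conditions()) {
  ratio <- 1
  for (cp in tr$couplings) {
    ext <- ion_conc(ions, cp$ion, "ext")
    cyt <- ion_conc(ions, cp$ion, "cyt")
    ratio <- ratio * if (cp$mode == "cotransport")
      (ext / cyt)^cp$count else (cyt / ext)^cp$count
  }
  ratio * exp(-tr$z * ions$faraday * ions$potential /
                (ions$gas_constant * ions$temperature))
}

#' Per-transporter accumulation limits of a whole model
#'
#' @param model a \code{\link{cell_model}}.
#' @return data frame with columns transporter, mechanism, z and
#'   limit_fold (the maximal cytosol/medium ratio under the model's ion
#'   conditions).
#' @export
model_limits <- function(model) {
  data.frame(
    transporter = vapply(model$transporters, function(t) t$name,
                         character(1)),
    mechanism = vapply(model$transporters, function(t) t$mechanism,
                       character(1)),
    z = vapply(model$transporters, function(t) t$z, integer(1)),
    limit_fold = vapply(model$transporters, thermodynamic_limit, numeric(1),
                        ions = model$ions),
    row.names = NULL)
}

#' In-silico knockout sensitivity analysis
#'
#' Simulates the model to equilibrium, then repeats the simulation with one
#' or several transporters removed per scenario and reports the per-species
#' equilibrium fold change relative to the full model. Removal of a loader
#' is expected to lower shared substrates; removal of a controller to raise
#' them; harmonizers give mixed or small changes.
#'
#' @param model a \code{\link{cell_model}}.
#' @param scenarios named list; each element is a character vector of
#'   transporter names to remove together. An empty vector reproduces the
#'   all-ones row.
#' @param medium extracellular \code{\link{amino_acid_pool}}.
#' @param config a \code{\link{simulation_config}}.
#' @param initial optional initial cytosolic pool shared by all runs.
#' @return a \code{knockout_matrix}: numeric matrix (scenarios + a leading
#'   "full" row, by species) of equilibrium fold changes, normalized so the
#'   full model is exactly 1.
#' @export
knockout_sensitivity <- function(model, scenarios, medium,
                                 config = simulation_config(),
                                 initial = NULL) {
  if (is.null(names(scenarios)) && length(scenarios) > 0)
    names(scenarios) <- vapply(scenarios, function(s)
      if (length(s) == 0) "none" else paste(s, collapse = "+"), character(1))
  for (sc in scenarios) {
    unknown <- setdiff(sc, names(model$transporters))
    if (length(unknown))
      stop("unknown transporter(s) in scenario: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  full <- run_simulation(model, medium, initial = initial, config = config)
  ref <- unclass(full$cytosol)
  out <- matrix(NA_real_, nrow = length(scenarios) + 1L, ncol = length(ref),
                dimnames = list(c("full", names(scenarios)), names(ref)))
  out["full", ] <- 1
  for (i in seq_along(scenarios)) {
    kept <- model$transporters[setdiff(names(model$transporters),
                                       scenarios[[i]])]
    sub <- model
    sub$transporters <- kept
    res <- run_simulation(sub, medium, initial = initial, config = config)
    out[i + 1L, ] <- unclass(res$cytosol) / ref
  }
  structure(out, class = c("knockout_matrix", "matrix", "array"))
}

#' Tidy form of a knockout matrix
#' @param x a \code{knockout_matrix}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns scenario, species, fold_change.
#' @export
as.data.frame.knockout_matrix <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(scenario = rep(rownames(x), times = ncol(x)),
             species = rep(colnames(x), each = nrow(x)),
             fold_change = as.vector(unclass(x)))
}

#' Pearson agreement between simulated and observed concentrations
#'
#' Standard Pearson correlation over the species shared by both vectors
#' (matched by name). At least three shared species are required.
#'
#' @param sim named numeric vector of simulated concentrations (µM).
#' @param obs named numeric vector of observed concentrations (µM).
#' @return Pearson correlation coefficient.
#' @export
pearson_agreement <- function(sim, obs) {
  if (is.null(names(sim)) || is.null(names(obs)))
    stop("sim and obs must be named by species", call. = FALSE)
  shared <- intersect(names(sim), names(obs))
  if (length(shared) < 3)
    stop("need at least 3 shared species, got ", length(shared),
         call. = FALSE)
  stats::cor(as.numeric(sim[shared]), as.numeric(obs[shared]),
             method = "pearson")
}

#' Signed-log2 quadrant analysis of concentration changes
#'
#' Transforms per-species concentration changes (relative to a t = 0
#' baseline) as \code{sign(x) * log2(|x|)}, with magnitudes below 1 µM
#' clamped to 0 to avoid the log blowup for near-zero changes, then assigns
#' each species to a quadrant (both up, both down, or discordant) and
#' reports the Pearson correlation of the signed-log2 pairs.
#'
#' @param sim_change named numeric vector of simulated changes (ΔµM).
#' @param obs_change named numeric vector of observed changes (ΔµM).
#' @return list with \code{table} (species, slog2_sim, slog2_obs, quadrant)
#'   and \code{r} (Pearson correlation over the transformed pairs).
#' @examples
#' signed_log2(8)   # 3
#' signed_log2(-8)  # -3
#' @export
signed_log2_quadrant <- function(sim_change, obs_change) {
  shared <- intersect(names(sim_change), names(obs_change))
  s <- signed_log2(as.numeric(sim_change[shared]))
  o <- signed_log2(as.numeric(obs_change[shared]))
  quadrant <- ifelse(s > 0 & o > 0, "both_up",
              ifelse(s < 0 & o < 0, "both_down",
              ifelse(s == 0 & o == 0, "unchanged", "discordant")))
  list(table = data.frame(species = shared, slog2_sim = s, slog2_obs = o,
                          quadrant = quadrant, row.names = NULL),
       r = if (length(shared) >= 3) stats::cor(s, o) else NA_real_)
}

#' Signed log2 transform
#'
#' \code{sign(x) * log2(|x|)}, with \code{|x| < 1} mapped to 0 (the 1 µM
#' floor keeps near-zero changes off the log scale).
#'
#' @param x numeric vector of changes (µM).
#' @return transformed vector.
#' @export
signed_log2 <- function(x) {
  out <- numeric(length(x))
  big <- abs(x) >= 1
  out[big] <- sign(x[big]) * log2(abs(x[big]))
  out
}

#' Cytosolic concentration from an extract measurement
#'
#' Back-calculates the cytosolic concentration from the concentration
#' measured in an extraction vial:
#' \code{[AA]_cyt = [AA]_vial * V_vial / (V_cell * m_protein * c)}, where
#' c converts protein mass to cell number.
#'
#' @param vial_conc concentration in the vial (µM).
#' @param v_vial_l vial volume in litres.
#' @param v_cell_fl mean cell volume in fL.
#' @param m_protein_ug protein mass of the harvested dish in µg.
#' @param cells_per_ug protein-to-cell correlate (cells per µg; e.g. about
#'   7036 for A549-type cells).
#' @return cytosolic concentration in µM; vectorized over \code{vial_conc}.
#' @examples
#' cytosolic_concentration_from_extract(1, 600e-6, 2000, 100, 7036)
#' @export
cytosolic_concentration_from_extract <- function(vial_conc, v_vial_l,
                                                 v_cell_fl, m_protein_ug,
                                                 cells_per_ug) {
  if (any(c(v_vial_l, v_cell_fl, m_protein_ug, cells_per_ug) <= 0))
    stop("volumes, protein mass and correlate must be > 0", call. = FALSE)
  cell_vol_l <- v_cell_fl * 1e-15 * m_protein_ug * cells_per_ug
  vial_conc * v_vial_l / cell_vol_l
}
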