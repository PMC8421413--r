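#' Two-sided substrate affinity for one transporter substrate
#'
#' Km values are half-saturation constants in µM for the extracellular and
#' cytosolic face. A face on which the substrate is not accepted carries
#' \code{NA} (only meaningful for antiporters, e.g. glutamate on the
#' cytosolic face of xCT). For uniporters and (mixed) symporters both faces
#' must carry the same Km — unequal values would let the carrier accumulate
#' substrate without any driving gradient, which \code{transporter()} rejects.
#' Antiporters may be strongly asymmetric; cytosolic Km values 100-1000-fold
#' above the extracellular ones are typical for amino acid exchangers.
#'
#' @param km_ext extracellular Km (µM), > 0 or NA.
#' @param km_int cytosolic Km (µM), > 0 or NA; defaults to \code{km_ext}.
#' @param estimated logical flag marking the value as an estimate rather than
#'   a measured constant (bookkeeping only; does not affect kinetics).
#' @return object of class \code{substrate_kinetics}.
#' @export
substrate_kinetics <- function(km_ext, km_int = km_ext, estimated = FALSE) {
  for (v in list(km_ext, km_int))
    if (!is.na(v) && (!is.finite(v) || v <= 0))
      stop("Km values must be > 0 (or NA for a face not accepted)",
           call. = FALSE)
  if (is.na(km_ext) && is.na(km_int))
    stop("substrate must be accepted on at least one face", call. = FALSE)
  structure(list(km_ext = km_ext, km_int = km_int,
                 estimated = isTRUE(estimated)),
            class = "substrate_kinetics")
}

# default ion half-saturation constants (mM); main-text estimates, overridable
.DEFAULT_ION_KM <- c(Na = 30, K = 10, H = 5e-5)

#' Ion coupling of a transporter
#'
#' Describes one ion species that is co- or counter-transported with the
#' substrate. Saturation of the carrier by the ion follows a Hill equation
#' with coefficient \code{hill_n} and half-saturation \code{km_ion};
#' \code{count} is the transport stoichiometry (ions moved per substrate),
#' which enters the thermodynamic accumulation limit as the exponent of the
#' ion gradient. For substrate influx a cotransported ion binds on the
#' extracellular (cis) face and an antiported ion on the cytosolic (trans)
#' face, and vice versa for efflux.
#'
#' @param ion one of "Na", "K", "H".
#' @param mode "cotransport" or "antiport" (relative to the substrate).
#' @param count stoichiometric count, integer >= 1.
#' @param hill_n Hill coefficient, > 0; defaults to \code{count}.
#' @param km_ion half-saturation constant (mM); defaults per ion species
#'   (Na 30 mM, K 10 mM, H 5e-5 mM, i.e. half-saturated near pH 7.3).
#' @param applies_to optional character vector of substrate names the
#'   coupling is restricted to (e.g. the Na+ carried only with the neutral
#'   amino acid leg of a y+LAT-type exchanger); NULL applies to all.
#' @return object of class \code{ion_coupling}.
#' @export
ion_coupling <- function(ion, mode = c("cotransport", "antiport"),
                         count = 1L, hill_n = count, km_ion = NULL,
                         applies_to = NULL) {
  mode <- match.arg(mode)
  if (!ion %in% names(.DEFAULT_ION_KM))
    stop("unknown ion species: ", ion, call. = FALSE)
  if (count < 1 || count != round(count))
    stop("count must be a positive integer", call. = FALSE)
  if (hill_n <= 0) stop("Hill coefficient must be > 0", call. = FALSE)
  if (is.null(km_ion)) km_ion <- unname(.DEFAULT_ION_KM[ion])
  if (km_ion <= 0) stop("km_ion must be > 0", call. = FALSE)
  structure(list(ion = ion, mode = mode, count = as.integer(count),
                 hill_n = hill_n, km_ion = km_ion, applies_to = applies_to),
            class = "ion_coupling")
}

.MECHANISMS <- c("uniporter", "symporter", "antiporter", "symporter_antiporter")

#' Plasma-membrane amino acid transporter
#'
#' @param name transporter name (e.g. "SNAT1").
#' @param mechanism one of "uniporter", "symporter", "antiporter",
#'   "symporter_antiporter" (Na+ cotransport combined with H+ antiport as in
#'   SNAT3/5, treated as electroneutral).
#' @param substrates named list of \code{\link{substrate_kinetics}}, one entry
#'   per substrate species.
#' @param couplings list of \code{\link{ion_coupling}} objects.
#' @param z integer charge of the fully loaded translocation complex, for the
#'   inward direction. Only uniporters and symporters are treated as
#'   electrogenic in the kinetics; the charge always enters the thermodynamic
#'   accumulation limit.
#' @param vmax maximal transport rate, nmol (mg protein)^-1 min^-1; the same
#'   Vmax governs forward and backward flux.
#' @return object of class \code{transporter}.
#' @details Validation enforces the second-law rules for input parameters:
#'   uniporters and (mixed) symporters must have equal Km on both faces, and
#'   antiporters must accept at least one substrate on each face (an
#'   exchanger with an empty face could never complete a cycle).
#' @examples
#' snat1 <- transporter("SNAT1", "symporter",
#'   substrates = list(Gln = substrate_kinetics(300)),
#'   couplings = list(ion_coupling("Na", "cotransport")),
#'   z = 1, vmax = 5)
#' @export
transporter <- function(name, mechanism, substrates, couplings = list(),
                        z = 0L, vmax) {
  if (!mechanism %in% .MECHANISMS)
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  if (!is.list(substrates) || length(substrates) == 0 ||
      is.null(names(substrates)) || any(!nzchar(names(substrates))))
    stop("substrates must be a non-empty named list", call. = FALSE)
  if (!all(vapply(substrates, inherits, TRUE, "substrate_kinetics")))
    stop("each substrate entry must be a substrate_kinetics object",
         call. = FALSE)
  if (!is.finite(vmax) || vmax <= 0)
    stop("vmax must be > 0", call. = FALSE)
  if (z != round(z)) stop("z must be an integer", call. = FALSE)
  if (!all(vapply(couplings, inherits, TRUE, "ion_coupling")))
    stop("couplings must be ion_coupling objects", call. = FALSE)

  km_ext <- vapply(substrates, function(s) s$km_ext, numeric(1))
  km_int <- vapply(substrates, function(s) s$km_int, numeric(1))
  if (mechanism != "antiporter") {
    bad <- is.na(km_ext) | is.na(km_int) | km_ext != km_int
    if (any(bad))
      stop(name, ": ", mechanism,
           " requires equal extracellular and cytosolic Km for every ",
           "substrate (violated for ",
           paste(names(substrates)[bad], collapse = ", "),
           "); unequal values would accumulate substrate without a gradient",
           call. = FALSE)
  } else {
    if (!any(!is.na(km_ext)) || !any(!is.na(km_int)))
      stop(name, ": antiporter must accept at least one substrate on each ",
           "face", call. = FALSE)
  }
  for (cp in couplings) {
    if (!is.null(cp$applies_to)) {
      missing <- setdiff(cp$applies_to, names(substrates))
      if (length(missing))
        stop(name, ": ion coupling restricted to unknown substrate(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, mechanism = mechanism, substrates = substrates,
                 couplings = couplings, z = as.integer(z), vmax = vmax),
            class = "transporter")
}

#' Substrates a transporter accepts on one membrane face
#'
#' @param tr a \code{transporter}.
#' @param face "ext" or "int".
#' @return named numeric vector of Km values (µM) for the accepted substrates.
#' @export
face_km <- function(tr, face = c("ext", "int")) {
  face <- match.arg(face)
  field <- if (face == "ext") "km_ext" else "km_int"
  km <- vapply(tr$substrates, function(s) s[[field]], numeric(1))
  km[!is.na(km)]
}

#' @export
print.transporter <- function(x, ...) {
  ions <- if (length(x$couplings) == 0) "none" else
    paste(vapply(x$couplings, function(cp)
      sprintf("%dx%s %s", cp$count, cp$ion,
              if (cp$mode == "cotransport") "co" else "anti"),
      character(1)), collapse = ", ")
  cat(sprintf("<transporter> %s (%s), z=%+d, Vmax=%g nmol/mg/min\n",
              x$name, x$mechanism, x$z, x$vmax))
  cat("  substrates:", paste(names(x$substrates), collapse = ", "), "\n")
  cat("  ion couplings:", ions, "\n")
  invisible(x)
}
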