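#' Michaelis-Menten substrate saturation
#'
#' Fraction of carriers occupied by a substrate at concentration \code{conc}
#' with half-saturation constant \code{km}: \code{conc / (km + conc)}.
#'
#' @param conc substrate concentration (µM), >= 0.
#' @param km half-saturation constant (µM), > 0.
#' @return saturation fraction in [0, 1); vectorized over \code{conc}.
#' @examples
#' substrate_saturation(100, 100)  # 0.5
#' substrate_saturation(300, 100)  # 0.75
#' @export
substrate_saturation <- function(conc, km) {
  if (any(!is.finite(km)) || any(km <= 0))
    stop("km must be > 0", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be >= 0", call. = FALSE)
  conc / (km + conc)
}

#' Apparent Km under substrate competition
#'
#' Competing substrates sharing the carrier inflate the half-saturation of
#' substrate i to \code{Km_i * (1 + sum_a [AA_a]/Km_a)}, the sum running over
#' the transporter's other substrates on the same face at their pool
#' concentrations.
#'
#' @param substrate species code of the substrate of interest.
#' @param face "ext" or "int": which membrane face the saturation refers to.
#' @param tr a \code{\link{transporter}} accepting \code{substrate} on that
#'   face.
#' @param pool \code{\link{amino_acid_pool}} on that face; must contain every
#'   substrate the transporter accepts there.
#' @return apparent Km (µM).
#' @examples
#' t <- transporter("toy", "uniporter",
#'   list(A = substrate_kinetics(100), B = substrate_kinetics(100)), vmax = 1)
#' apparent_km("A", "ext", t, amino_acid_pool(c(A = 0, B = 100)))  # 200
#' @export
apparent_km <- function(substrate, face = c("ext", "int"), tr, pool) {
  face <- match.arg(face)
  km <- face_km(tr, face)
  if (!substrate %in% names(km))
    stop(tr$name, " does not accept ", substrate, " on the ", face, " face",
         call. = FALSE)
  others <- setdiff(names(km), substrate)
  if (length(others) == 0) return(unname(km[substrate]))
  unname(km[substrate] * (1 + sum(pool_conc(pool, others) / km[others])))
}

#' Fractional saturation of every substrate on one face
#'
#' For each substrate i on the given face the occupied fraction is
#' \code{[AA_i] / (K_apps_i + [AA_i])} with the apparent Km of
#' \code{\link{apparent_km}}. The fractions of all substrates sum to the
#' carrier's total substrate occupancy on that face, which is always < 1.
#'
#' @inheritParams apparent_km
#' @return named numeric vector of fractions, one per substrate on the face.
#' @export
fractional_saturation_profile <- function(tr, face = c("ext", "int"), pool) {
  face <- match.arg(face)
  km <- face_km(tr, face)
  conc <- pool_conc(pool, names(km))
  # algebraically identical to conc_i / (K_apps_i + conc_i)
  load <- conc / km
  load / (1 + sum(load))
}

.hill <- function(conc, km, n) conc^n / (km^n + conc^n)

# per-substrate ion saturation vector for one transport direction;
# cotransported ions bind on the cis face, antiported ions on the trans face
.ion_saturation_vec <- function(tr, ions, direction, substrates) {
  sat <- rep(1, length(substrates))
  names(sat) <- substrates
  for (cp in tr$couplings) {
    cis_is_ext <- (direction == "inward")
    face <- if (cp$mode == "cotransport") {
      if (cis_is_ext) "ext" else "cyt"
    } else {
      if (cis_is_ext) "cyt" else "ext"
    }
    s <- .hill(ion_conc(ions, cp$ion, face), cp$km_ion, cp$hill_n)
    hit <- if (is.null(cp$applies_to)) rep(TRUE, length(substrates))
           else substrates %in% cp$applies_to
    sat[hit] <- sat[hit] * s
  }
  sat
}

#' Carrier saturation by coupled ions
#'
#' Product over the transporter's ion couplings of the Hill saturation
#' \code{[Ion]^n / (Km^n + [Ion]^n)}, each coupling reading the ion
#' concentration on the face it binds for the given transport direction:
#' cotransported ions on the cis face, antiported ions on the trans face.
#' A transporter without ion couplings returns 1. Couplings restricted to a
#' subset of substrates (\code{applies_to}) are included here as well; use
#' \code{\link{unidirectional_flux}} for the per-substrate resolution.
#'
#' @param tr a \code{\link{transporter}}.
#' @param ions \code{\link{ion_conditions}}.
#' @param direction "inward" or "outward" (direction of substrate movement).
#' @return saturation fraction in [0, 1].
#' @export
ion_saturation <- function(tr, ions, direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  sat <- 1
  for (cp in tr$couplings) {
    cis_is_ext <- (direction == "inward")
    face <- if (cp$mode == "cotransport") {
      if (cis_is_ext) "ext" else "cyt"
    } else {
      if (cis_is_ext) "cyt" else "ext"
    }
    sat <- sat * .hill(ion_conc(ions, cp$ion, face), cp$km_ion, cp$hill_n)
  }
  sat
}

#' Membrane-potential factor for a charged translocation complex
#'
#' Translocation of a complex with net charge z across the membrane potential
#' is accelerated or retarded by
#' \code{beta = exp(-z F 0.5 dPsi / (R T))}, assuming a symmetric barrier at
#' the midpoint of the field. Flux is multiplied by beta when translocation is
#' favored by the potential and divided by beta when it runs against it; in
#' this implementation the inward rate carries \code{beta} and the outward
#' rate \code{1/beta}, with z the inward complex charge, which realizes
#' exactly that rule. \code{beta(z) * beta(-z) == 1}.
#'
#' @param z integer charge of the loaded complex (inward direction).
#' @param ions \code{\link{ion_conditions}} supplying potential, temperature
#'   and physical constants.
#' @return beta > 0; 1 when z = 0 or the potential is 0.
#' @examples
#' membrane_potential_factor(1, ion_conditions())  # about 3.07 at -60 mV
#' @export
membrane_potential_factor <- function(z, ions) {
  exp(-z * ions$faraday * 0.5 * ions$potential /
        (ions$gas_constant * ions$temperature))
}

#' Fraction of carriers available for net transport
#'
#' An electrogenic symporter only senses the membrane potential on cycles
#' that return the empty carrier; carriers returning loaded run an
#' electroneutral exchange. The fraction capable of net transport is one
#' minus the total substrate occupancy of the trans face, so it falls
#' monotonically as trans-side substrate rises and the potential dependence
#' vanishes in the exchange-dominated limit.
#'
#' @param tr a \code{\link{transporter}}.
#' @param face the trans face ("ext" or "int") whose occupancy is read.
#' @param pool the \code{\link{amino_acid_pool}} on that face.
#' @return fraction in [0, 1].
#' @export
net_transport_fraction <- function(tr, face = c("ext", "int"), pool) {
  face <- match.arg(face)
  1 - sum(fractional_saturation_profile(tr, face, pool))
}

#' Unidirectional per-substrate transport rates
#'
#' Computes, for one direction of transport, the rate at which each substrate
#' is carried. The base rate is Vmax times the substrate's fractional
#' saturation on the cis face times the ion saturation for that direction.
#' On top of the base rate the mechanisms differ:
#' \describe{
#'   \item{uniporter}{multiplied by \code{beta} inward and \code{1/beta}
#'     outward when the complex is charged.}
#'   \item{symporter / symporter_antiporter}{multiplied by
#'     \code{ntf * beta_dir + effocc_trans}: carriers that can return empty
#'     (the net-transport fraction \code{ntf} of the trans face) run net
#'     transport and sense the membrane potential; the rest cycle in
#'     electroneutral exchange mode, whose contribution is the ion-weighted
#'     substrate occupancy of the trans face (\code{effocc_trans}) and is
#'     identical in both directions, so it cancels from the single-substrate
#'     net flux. At saturating ion concentrations this is exactly the blend
#'     \code{ntf * beta + (1 - ntf)}, and it pins the single-substrate
#'     equilibrium at \code{(isat_in/isat_out) * beta^2}, which never exceeds
#'     the closed-form accumulation limit. Mixed symporter/antiporters are
#'     electroneutral (\code{beta = 1}).}
#'   \item{antiporter}{multiplied by the ion-weighted substrate occupancy of
#'     the trans face — an exchanger cannot complete a cycle without a
#'     counter-substrate — which enforces strict 1:1 exchange.}
#' }
#'
#' @param tr a \code{\link{transporter}}.
#' @param direction "inward" or "outward".
#' @param ext_pool,int_pool extracellular and cytosolic
#'   \code{\link{amino_acid_pool}}s.
#' @param ions \code{\link{ion_conditions}}.
#' @return named numeric vector of rates (nmol (mg protein)^-1 min^-1), one
#'   per substrate accepted on the cis face; all >= 0 and finite.
#' @export
unidirectional_flux <- function(tr, direction = c("inward", "outward"),
                                ext_pool, int_pool, ions) {
  direction <- match.arg(direction)
  cis_face <- if (direction == "inward") "ext" else "int"
  cis_pool <- if (direction == "inward") ext_pool else int_pool
  frac <- fractional_saturation_profile(tr, cis_face, cis_pool)
  isat <- .ion_saturation_vec(tr, ions, direction, names(frac))
  base <- tr$vmax * frac * isat

  if (tr$mechanism == "uniporter") {
    if (tr$z == 0) return(base)
    beta <- membrane_potential_factor(tr$z, ions)
    return(base * if (direction == "inward") beta else 1 / beta)
  }

  trans_face <- if (direction == "inward") "int" else "ext"
  trans_pool <- if (direction == "inward") int_pool else ext_pool
  trans_frac <- fractional_saturation_profile(tr, trans_face, trans_pool)
  trans_dir <- if (direction == "inward") "outward" else "inward"
  trans_isat <- .ion_saturation_vec(tr, ions, trans_dir, names(trans_frac))
  effocc_trans <- sum(trans_frac * trans_isat)

  if (tr$mechanism == "antiporter") return(base * effocc_trans)

  # symporter / symporter_antiporter: net-transport + exchange components
  beta <- if (tr$mechanism == "symporter" && tr$z != 0)
    membrane_potential_factor(tr$z, ions) else 1
  beta_dir <- if (direction == "inward") beta else 1 / beta
  ntf <- 1 - sum(trans_frac)
  base * (ntf * beta_dir + effocc_trans)
}

#' Net flux breakdown of one transporter
#'
#' Influx and efflux are computed with the identical Vmax; the net rate per
#' substrate is influx minus efflux. For a pure antiporter the substrate-wise
#' net rates sum to zero (1:1 exchange): every molecule imported is matched
#' by one exported.
#'
#' @inheritParams unidirectional_flux
#' @return a \code{flux_breakdown}: data frame with columns
#'   \code{transporter}, \code{substrate}, \code{influx}, \code{efflux},
#'   \code{net} (all rates nmol (mg protein)^-1 min^-1).
#' @export
net_flux <- function(tr, ext_pool, int_pool, ions) {
  influx <- unidirectional_flux(tr, "inward", ext_pool, int_pool, ions)
  efflux <- unidirectional_flux(tr, "outward", ext_pool, int_pool, ions)
  subs <- union(names(influx), names(efflux))
  inn <- out <- stats::setNames(numeric(length(subs)), subs)
  inn[names(influx)] <- influx
  out[names(efflux)] <- efflux
  structure(
    data.frame(transporter = tr$name, substrate = subs,
               influx = unname(inn), efflux = unname(out),
               net = unname(inn - out), row.names = NULL),
    class = c("flux_breakdown", "data.frame"))
}

#' Flux breakdown for a whole transporter roster
#'
#' @param transporters list of \code{\link{transporter}}s.
#' @inheritParams net_flux
#' @return a \code{flux_breakdown} with one row per transporter-substrate
#'   pair.
#' @export
roster_flux <- function(transporters, ext_pool, int_pool, ions) {
  rows <- lapply(transporters, net_flux, ext_pool = ext_pool,
                 int_pool = int_pool, ions = ions)
  out <- if (length(rows) == 0)
    data.frame(transporter = character(), substrate = character(),
               influx = numeric(), efflux = numeric(), net = numeric())
  else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flux_breakdown", "data.frame")
  out
}
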