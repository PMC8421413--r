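#' Amino acid concentration pool
#'
#' A pool maps amino acid species to non-negative concentrations in µM.
#' Species are identified by canonical three-letter codes ("Ala", "Gln", ...)
#' plus the special species \code{"CySS"} for cystine, the oxidized cysteine
#' dimer. The species set is fixed for a simulation; looking up a species that
#' is not in the pool is an error, never a silent zero.
#'
#' @param x named numeric vector of concentrations (µM); names are species.
#' @return an object of class \code{aa_pool} (a named numeric vector).
#' @examples
#' pool <- amino_acid_pool(c(Ala = 100, Gln = 600))
#' pool_conc(pool, "Gln")
#' @export
amino_acid_pool <- function(x) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("amino_acid_pool() needs a fully named numeric vector", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate species in pool: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("pool concentrations must be finite", call. = FALSE)
  if (any(x < 0))
    stop("pool concentrations must be >= 0", call. = FALSE)
  structure(as.numeric(x), names = names(x), class = "aa_pool")
}

#' Look up species concentrations in a pool
#'
#' @param pool an \code{aa_pool}.
#' @param species character vector of species codes; every one must be present.
#' @return numeric vector of concentrations (µM).
#' @export
pool_conc <- function(pool, species) {
  idx <- match(species, names(pool))
  if (anyNA(idx))
    stop("species not in pool: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  unclass(pool)[idx]
}

#' @export
print.aa_pool <- function(x, ...) {
  cat("<aa_pool> ", length(x), " species (µM)\n", sep = "")
  print(structure(as.numeric(x), names = names(x)))
  invisible(x)
}

# CODATA 2018 values; deliberately not user-settable.
.FARADAY <- 96485.33212      # C mol^-1
.GAS_CONSTANT <- 8.31446261815324  # J mol^-1 K^-1

#' Ionic conditions across the plasma membrane
#'
#' Holds the Na+, K+ and H+ concentrations on both membrane faces, the
#' membrane potential and the temperature. H+ is specified as pH and converted
#' to mM internally. The Faraday and gas constants are CODATA values and are
#' not user-settable.
#'
#' @param na_ext,na_cyt extracellular / cytosolic Na+ (mM).
#' @param k_ext,k_cyt extracellular / cytosolic K+ (mM).
#' @param ph_ext,ph_cyt extracellular / cytosolic pH.
#' @param potential membrane potential in volts, cytosol-negative is negative
#'   (default -0.060 V).
#' @param temperature absolute temperature in kelvin (default 310 K).
#' @return an object of class \code{ion_conditions}.
#' @details The defaults (Na+ 140/14 mM, K+ 5.4/140 mM, pH 7.4/7.2,
#'   -60 mV, 310 K) are standard textbook values for a mammalian cell bathed
#'   in a Hanks-type saline and are used for all shipped accumulation-limit
#'   calculations; every field can be overridden.
#' @examples
#' ions <- ion_conditions()
#' ion_conc(ions, "Na", "ext")
#' @export
ion_conditions <- function(na_ext = 140, na_cyt = 14,
                           k_ext = 5.4, k_cyt = 140,
                           ph_ext = 7.4, ph_cyt = 7.2,
                           potential = -0.060, temperature = 310) {
  num <- c(na_ext = na_ext, na_cyt = na_cyt, k_ext = k_ext, k_cyt = k_cyt,
           ph_ext = ph_ext, ph_cyt = ph_cyt,
           potential = potential, temperature = temperature)
  if (anyNA(num) || any(!is.finite(num)))
    stop("ion_conditions fields must be finite", call. = FALSE)
  if (any(c(na_ext, na_cyt, k_ext, k_cyt) <= 0))
    stop("ion concentrations must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  structure(list(na_ext = na_ext, na_cyt = na_cyt,
                 k_ext = k_ext, k_cyt = k_cyt,
                 ph_ext = ph_ext, ph_cyt = ph_cyt,
                 potential = potential, temperature = temperature,
                 faraday = .FARADAY, gas_constant = .GAS_CONSTANT),
            class = "ion_conditions")
}

#' Ion concentration on one membrane face
#'
#' @param ions an \code{ion_conditions} object.
#' @param ion one of "Na", "K", "H".
#' @param face "ext" or "cyt".
#' @return concentration in mM (H+ converted from pH).
#' @export
ion_conc <- function(ions, ion, face = c("ext", "cyt")) {
  face <- match.arg(face)
  switch(ion,
    Na = if (face == "ext") ions$na_ext else ions$na_cyt,
    K  = if (face == "ext") ions$k_ext else ions$k_cyt,
    H  = 1000 * 10^(-(if (face == "ext") ions$ph_ext else ions$ph_cyt)),
    stop("unknown ion species: ", ion, call. = FALSE)
  )
}

#' @export
print.ion_conditions <- function(x, ...) {
  cat(sprintf(paste0(
    "<ion_conditions> Na %g/%g mM, K %g/%g mM, pH %g/%g (ext/cyt), ",
    "potential %g mV, T %g K\n"),
    x$na_ext, x$na_cyt, x$k_ext, x$k_cyt, x$ph_ext, x$ph_cyt,
    1000 * x$potential, x$temperature))
  invisible(x)
}
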