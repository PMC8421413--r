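#' Read an extracellular medium table
#'
#' The medium format is a plain CSV with columns \code{species} and
#' \code{concentration_uM} (units embedded in the header).
#'
#' @param path CSV file path.
#' @return an \code{\link{amino_acid_pool}}.
#' @export
read_medium <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "concentration_uM")
  if (!all(need %in% names(tab)))
    stop("medium table ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  amino_acid_pool(stats::setNames(tab$concentration_uM, tab$species))
}

#' Write an extracellular medium table
#' @param pool an \code{\link{amino_acid_pool}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_medium <- function(pool, path) {
  utils::write.csv(data.frame(species = names(pool),
                              concentration_uM = as.numeric(pool)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory as a tidy CSV
#'
#' Columns: time_min, species, compartment, concentration_uM.
#'
#' @param result an \code{aa_simulation}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(result, path) {
  tab <- as.data.frame(result)
  names(tab) <- c("time_min", "species", "compartment", "concentration_uM")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flux breakdown as CSV
#'
#' Columns: transporter, substrate, influx, efflux, net (all in
#' nmol per mg protein per min).
#'
#' @param flux a \code{flux_breakdown}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_flux <- function(flux, path) {
  tab <- as.data.frame(flux)
  names(tab) <- c("transporter", "substrate", "influx_nmol_mg_min",
                  "efflux_nmol_mg_min", "net_nmol_mg_min")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
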