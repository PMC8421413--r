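# Naive reference integrator, written independently of the package's
# optimized stepping path: apparent-Km route, per-species forward Euler.
# Face-constant quantities (Km tables, ion saturations, beta) are computed
# once up front from first principles; the per-step arithmetic is plain
# scalar code.

oracle_hill <- function(conc, km, n) conc^n / (km^n + conc^n)

oracle_ion_conc <- function(ions, ion, face) {
  if (ion == "Na") return(if (face == "ext") ions$na_ext else ions$na_cyt)
  if (ion == "K") return(if (face == "ext") ions$k_ext else ions$k_cyt)
  1000 * 10^(-(if (face == "ext") ions$ph_ext else ions$ph_cyt))
}

# fractional saturations of all substrates on one face through the
# apparent-Km formula, one substrate at a time
oracle_fracs <- function(conc, km) {
  out <- numeric(length(km))
  names(out) <- names(km)
  for (sub in names(km)) {
    others <- setdiff(names(km), sub)
    kapp <- km[[sub]] * (1 + sum(conc[others] / km[others]))
    out[sub] <- conc[[sub]] / (kapp + conc[[sub]])
  }
  out
}

# per-substrate ion-saturation product for one direction of transport
oracle_isats <- function(tr, ions, direction, subs) {
  s <- rep(1, length(subs))
  names(s) <- subs
  for (sub in subs) {
    for (cp in tr$couplings) {
      if (!is.null(cp$applies_to) && !(sub %in% cp$applies_to)) next
      cis_ext <- direction == "inward"
      face <- if (cp$mode == "cotransport") {
        if (cis_ext) "ext" else "cyt"
      } else if (cis_ext) "cyt" else "ext"
      s[sub] <- s[sub] * oracle_hill(oracle_ion_conc(ions, cp$ion, face),
                                     cp$km_ion, cp$hill_n)
    }
  }
  s
}

oracle_face_km <- function(tr, field) {
  km <- sapply(tr$substrates, function(x) x[[field]])
  km[!is.na(km)]
}

# forward-Euler integration to time t_end; returns the final cytosol
oracle_integrate <- function(model, medium, initial, dt, t_end) {
  ext <- as.numeric(medium)
  names(ext) <- names(medium)
  cyt <- as.numeric(initial)
  names(cyt) <- names(initial)
  ions <- model$ions
  pre <- lapply(model$transporters, function(tr) {
    km_ext <- oracle_face_km(tr, "km_ext")
    km_int <- oracle_face_km(tr, "km_int")
    beta <- if (tr$mechanism %in% c("uniporter", "symporter") && tr$z != 0)
      exp(-tr$z * ions$faraday * 0.5 * ions$potential /
            (ions$gas_constant * ions$temperature)) else 1
    list(tr = tr, km_ext = km_ext, km_int = km_int, beta = beta,
         # extracellular face never changes: fractions are constants
         frac_ext = oracle_fracs(ext, km_ext),
         isat_in = oracle_isats(tr, ions, "inward", names(km_ext)),
         isat_out = oracle_isats(tr, ions, "outward", names(km_int)))
  })
  vol_l <- 1000 * model$cells_per_ug * model$volume_fl * 1e-15
  k <- 1e-9 / vol_l * 1e6
  nstep <- round(t_end / dt)
  for (i in seq_len(nstep)) {
    net <- numeric(length(cyt))
    names(net) <- names(cyt)
    for (p in pre) {
      tr <- p$tr
      frac_int <- oracle_fracs(cyt, p$km_int)
      if (tr$mechanism == "uniporter") {
        influx <- tr$vmax * p$frac_ext * p$isat_in * p$beta
        efflux <- tr$vmax * frac_int * p$isat_out / p$beta
      } else if (tr$mechanism == "antiporter") {
        influx <- tr$vmax * p$frac_ext * p$isat_in *
          sum(frac_int * p$isat_out)
        efflux <- tr$vmax * frac_int * p$isat_out *
          sum(p$frac_ext * p$isat_in)
      } else {  # symporter / symporter_antiporter
        f_in <- (1 - sum(frac_int)) * p$beta + sum(frac_int * p$isat_out)
        f_out <- (1 - sum(p$frac_ext)) / p$beta +
          sum(p$frac_ext * p$isat_in)
        influx <- tr$vmax * p$frac_ext * p$isat_in * f_in
        efflux <- tr$vmax * frac_int * p$isat_out * f_out
      }
      for (s in names(influx)) net[s] <- net[s] + influx[s]
      for (s in names(efflux)) net[s] <- net[s] - efflux[s]
    }
    d <- net * k * dt
    for (cv in model$conversions) {
      moved <- cv$rate * dt * cyt[[cv$from]]
      d[[cv$from]] <- d[[cv$from]] - moved
      d[[cv$to]] <- d[[cv$to]] + cv$mult * moved
    }
    for (dp in model$depletions)
      d[[dp$species]] <- d[[dp$species]] - dp$rate * dt * cyt[[dp$species]]
    cyt <- pmax(cyt + d, 0)
  }
  cyt
}

toy_kinds <- c("uniporter", "symporter", "antiporter_pair",
               "loader_harmonizer", "loader_harmonizer_controller")
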