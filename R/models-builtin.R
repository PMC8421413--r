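# Built-in cell models. Rosters follow the functional classification of
# mammalian amino acid transporters into loaders (net uptake: SNAT1, CAT1,
# B0AT2), harmonizers (fast exchangers: LAT1, ASCT1/2, y+LAT2, xCT) and
# controllers (low-affinity electroneutral carriers: SNAT3/5, LAT4).
# All Km and Vmax values are order-of-magnitude estimates ("est" in the
# configs) chosen to reproduce the qualitative physiology, not a curated
# replica of any measured parameter table.

.sk <- function(km_ext, km_int = km_ext)
  substrate_kinetics(km_ext, km_int, estimated = TRUE)

.core_roster <- function() {
  list(
    # loader: Na+/neutral amino acid symporter, net uptake of small/polar AAs
    transporter("SNAT1", "symporter",
      substrates = list(Gln = .sk(300), Ala = .sk(300), Ser = .sk(400),
                        Gly = .sk(500), Met = .sk(500), His = .sk(500),
                        Asn = .sk(400)),
      couplings = list(ion_coupling("Na", "cotransport")),
      z = 1, vmax = 4),
    # loader: cationic amino acid uniporter (charged complex)
    transporter("CAT1", "uniporter",
      substrates = list(Arg = .sk(150), Lys = .sk(150), His = .sk(400)),
      z = 1, vmax = 1.5),
    # harmonizer: large neutral amino acid exchanger, strongly asymmetric
    transporter("LAT1", "antiporter",
      substrates = list(Leu = .sk(30, 3000), Ile = .sk(50, 5000),
                        Val = .sk(100, 10000), Phe = .sk(30, 3000),
                        Tyr = .sk(50, 5000), Trp = .sk(50, 5000),
                        Met = .sk(50, 5000), His = .sk(100, 10000)),
      z = 0, vmax = 25),
    # harmonizer: small/polar neutral exchanger; cytosolic glutamate is a
    # low-affinity efflux substrate, alanine efflux is limited
    transporter("ASCT2", "antiporter",
      substrates = list(Gln = .sk(70, 7000), Ala = .sk(70, 20000),
                        Ser = .sk(70, 7000), Thr = .sk(100, 10000),
                        Asn = .sk(70, 7000), Cys = .sk(100, 10000),
                        Glu = substrate_kinetics(NA, 12000,
                                                 estimated = TRUE)),
      z = 0, vmax = 30),
    # harmonizer: exchanges a neutral amino acid plus Na+ (cotransported on
    # the neutral leg only) against a cationic amino acid; overall neutral
    transporter("y+LAT2", "antiporter",
      substrates = list(Leu = .sk(100, 10000), Gln = .sk(100, 10000),
                        Met = .sk(150, 15000),
                        Arg = substrate_kinetics(NA, 300, estimated = TRUE),
                        Lys = substrate_kinetics(NA, 300, estimated = TRUE)),
      couplings = list(ion_coupling("Na", "cotransport",
                                    applies_to = c("Leu", "Gln", "Met"))),
      z = 0, vmax = 10),
    # harmonizer: cystine/glutamate exchanger; cystine import drives
    # glutamate efflux because cytosolic cystine is instantly reduced
    transporter("xCT", "antiporter",
      substrates = list(CySS = substrate_kinetics(100, NA, estimated = TRUE),
                        Glu = substrate_kinetics(NA, 8000,
                                                 estimated = TRUE)),
      z = 0, vmax = 6),
    # controller: Na+ symport / H+ antiport, electroneutral, low affinity
    transporter("SNAT3", "symporter_antiporter",
      substrates = list(Gln = .sk(3000), Ala = .sk(5000), Gly = .sk(5000),
                        Ser = .sk(5000), Asn = .sk(4000), His = .sk(5000)),
      couplings = list(ion_coupling("Na", "cotransport"),
                       ion_coupling("H", "antiport")),
      z = 0, vmax = 20),
    # controller: low-affinity facilitator for branched-chain/aromatic AAs
    transporter("LAT4", "uniporter",
      substrates = list(Leu = .sk(3000), Ile = .sk(3000), Phe = .sk(3000),
                        Val = .sk(5000)),
      z = 0, vmax = 15))
}

.extra_u87_roster <- function() {
  list(
    # loader: Na+/neutral symporter for small and branched-chain AAs
    transporter("B0AT2", "symporter",
      substrates = list(Pro = .sk(300), Gly = .sk(500), Leu = .sk(300),
                        Ile = .sk(500), Val = .sk(700)),
      couplings = list(ion_coupling("Na", "cotransport")),
      z = 1, vmax = 3),
    # harmonizer: small neutral exchanger
    transporter("ASCT1", "antiporter",
      substrates = list(Ala = .sk(70, 20000), Ser = .sk(70, 7000),
                        Gly = .sk(200, 20000), Thr = .sk(100, 10000)),
      z = 0, vmax = 12))
}

.default_conversions <- function() {
  list(
    # glutaminolysis feeds the cytosolic glutamate pool ("est" rate)
    list(from = "Gln", to = "Glu", rate = 0.004, mult = 1),
    # cystine is quantitatively reduced to two cysteines in the cytosol
    list(from = "CySS", to = "Cys", rate = 0.7, mult = 2))
}

.default_depletions <- function() {
  # slow drains on the products of conversion so they do not grow without
  # an efflux route ("est")
  list(list(species = "Glu", rate = 0.002),
       list(species = "Cys", rate = 0.01))
}

#' Built-in cell models
#'
#' Ready-made transporter rosters following the loader / harmonizer /
#' controller classification: \code{"A549-like"} (lung carcinoma-like),
#' \code{"U87MG-like"} (glioblastoma-like; additionally expresses B0AT2 and
#' ASCT1), \code{"myotube-like"} (same roster as A549-like but with Vmax
#' values allocated from relative mRNA expression via
#' \code{\link{vmax_from_expression}}), and the toy models of
#' \code{\link{make_toy_model}} by their kind names. All built-in kinetic
#' constants are estimates (flagged in the configs); the models are
#' qualitative stand-ins, not parameter replicas of any measured cell line.
#'
#' @param name model name (see description).
#' @return a validated \code{\link{cell_model}}.
#' @export
builtin_model <- function(name = c("A549-like", "U87MG-like",
                                   "myotube-like", "uniporter", "symporter",
                                   "antiporter_pair", "loader_harmonizer",
                                   "loader_harmonizer_controller")) {
  name <- match.arg(name)
  if (name %in% c("uniporter", "symporter", "antiporter_pair",
                  "loader_harmonizer", "loader_harmonizer_controller"))
    return(make_toy_model(name, seed = 1L)$model)
  switch(name,
    "A549-like" = cell_model(.core_roster(), volume_fl = 2000,
                             cells_per_ug = 7036,
                             conversions = .default_conversions(),
                             depletions = .default_depletions(),
                             name = "A549-like"),
    "U87MG-like" = cell_model(c(.core_roster(), .extra_u87_roster()),
                              volume_fl = 2500, cells_per_ug = 7092,
                              conversions = .default_conversions(),
                              depletions = .default_depletions(),
                              name = "U87MG-like"),
    "myotube-like" = {
      roster <- .core_roster()
      nm <- vapply(roster, function(t) t$name, character(1))
      # relative transcript abundances ("est"), renormalized to the total
      # transport capacity of the core roster
      expr <- c(SNAT1 = 2, CAT1 = 1, LAT1 = 8, ASCT2 = 10, `y+LAT2` = 4,
                xCT = 2, SNAT3 = 8, LAT4 = 6)
      total <- sum(vapply(roster, function(t) t$vmax, numeric(1)))
      vmax <- vmax_from_expression(expr[nm], total)
      roster <- lapply(seq_along(roster), function(i) {
        t <- roster[[i]]
        t$vmax <- unname(vmax[i])
        t
      })
      cell_model(roster, volume_fl = 5000, cells_per_ug = 3000,
                 conversions = .default_conversions(),
                 depletions = .default_depletions(),
                 name = "myotube-like")
    })
}

#' Standard extracellular media
#'
#' \code{"uniform100"}: every species carried by the built-in rosters at
#' 100 µM (the equilibration-buffer design used for spike experiments);
#' \code{"bme-like"}: a basal-medium-like formulation with glutamine at
#' 600 µM, nonessential amino acids present and cystine included;
#' \code{"plasma-like"}: rough human plasma concentrations.
#'
#' @param kind medium name.
#' @return an \code{\link{amino_acid_pool}} (µM).
#' @export
standard_medium <- function(kind = c("uniform100", "bme-like",
                                     "plasma-like")) {
  kind <- match.arg(kind)
  species <- c("Ala", "Arg", "Asn", "Gln", "Glu", "Gly", "His", "Ile",
               "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
               "Tyr", "Val", "Cys", "CySS")
  conc <- switch(kind,
    uniform100 = stats::setNames(rep(100, length(species)), species),
    "bme-like" = c(Ala = 100, Arg = 150, Asn = 50, Gln = 600, Glu = 100,
                   Gly = 100, His = 100, Ile = 200, Leu = 200, Lys = 200,
                   Met = 50, Phe = 100, Pro = 100, Ser = 100, Thr = 200,
                   Trp = 20, Tyr = 100, Val = 200, Cys = 0, CySS = 100),
    "plasma-like" = c(Ala = 350, Arg = 80, Asn = 50, Gln = 550, Glu = 50,
                      Gly = 250, His = 80, Ile = 60, Leu = 120, Lys = 180,
                      Met = 25, Phe = 60, Pro = 180, Ser = 110, Thr = 140,
                      Trp = 50, Tyr = 60, Val = 220, Cys = 0, CySS = 40))
  amino_acid_pool(conc[species])
}
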