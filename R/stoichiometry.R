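## Nanodisc / vesicle lipid stoichiometry arithmetic.
##
## Deterministic composition and geometry calculations: how many anionic
## lipids a disc leaflet carries, how many accessible PIP molecules a
## vesicle presents, the lipid area of a disc leaflet, and the dye mass
## fraction of a labelled disc.

#' Nanodisc composition specification
#'
#' Defaults describe the standard MSP1D1 disc used in Nanodisc pulldown
#' assays: ~80 lipids per leaflet, two leaflets, gel-phase DMPC at
#' 0.50 nm^2 per lipid. Percent compositions are mole fractions of total
#' lipid.
#'
#' @param lipidsPerLeaflet total lipids per leaflet (default 80).
#' @param anionicFraction anionic lipid (e.g. DMPS) mole fraction in \[0, 1\].
#' @param pipFraction phosphoinositide mole fraction in \[0, 1\].
#' @param areaPerLipid nm^2 per lipid headgroup (default 0.50, gel-phase
#'   DMPC).
#' @param leaflets leaflets per disc (default 2).
#' @return A [DiscSpec-class] object.
#' @examples
#' discSpec(anionicFraction = 0.15)
#' @export
discSpec <- function(lipidsPerLeaflet = 80, anionicFraction = 0,
                     pipFraction = 0, areaPerLipid = 0.50, leaflets = 2) {
  new("DiscSpec", lipidsPerLeaflet = lipidsPerLeaflet,
      anionicFraction = anionicFraction, pipFraction = pipFraction,
      areaPerLipid = areaPerLipid, leaflets = leaflets)
}

#' Vesicle specification
#'
#' Defaults describe a 50-nm small unilamellar vesicle with fluid-phase
#' lipids at 0.65 nm^2 per lipid.
#'
#' @param diameter outer diameter, nm.
#' @param areaPerLipid nm^2 per lipid (default 0.65, fluid phase).
#' @param pipFraction phosphoinositide mole fraction in \[0, 1\].
#' @return A [VesicleSpec-class] object.
#' @export
vesicleSpec <- function(diameter = 50, areaPerLipid = 0.65,
                        pipFraction = 0) {
  new("VesicleSpec", diameter = diameter, areaPerLipid = areaPerLipid,
      pipFraction = pipFraction)
}

#' Mass inventory of a dye-labelled Nanodisc
#'
#' Defaults describe a DiD-labelled MSP1D1 disc: two DiD dyes (1,052 Da),
#' two scaffold proteins (24,662 Da for MSP1D1) and 160 DMPC-class lipids
#' (678 Da).
#'
#' @param nDye,dyeMw dye count and molecular weight (Da).
#' @param nScaffold,scaffoldMw scaffold-protein count and weight (Da).
#' @param nLipids,lipidMw lipid count and weight (Da).
#' @return A [MassModel-class] object.
#' @export
massModel <- function(nDye = 2, dyeMw = 1052, nScaffold = 2,
                      scaffoldMw = 24662, nLipids = 160, lipidMw = 678) {
  new("MassModel", nDye = nDye, dyeMw = dyeMw, nScaffold = nScaffold,
      scaffoldMw = scaffoldMw, nLipids = nLipids, lipidMw = lipidMw)
}

#' Anionic lipids per disc leaflet
#'
#' Number of anionic lipid molecules per leaflet: the anionic mole
#' fraction times the lipids per leaflet, rounded half away from zero.
#' A 15% DMPS disc with 80 lipids per leaflet carries 12 DMPS per leaflet.
#'
#' @param spec a [DiscSpec-class].
#' @return Integer count of anionic lipids per leaflet.
#' @examples
#' anionicPerLeaflet(discSpec(anionicFraction = 0.15))  # 12
#' @export
anionicPerLeaflet <- function(spec) {
  stopifnot(is(spec, "DiscSpec"))
  validObject(spec)
  roundCount(spec@anionicFraction * spec@lipidsPerLeaflet)
}

#' Accessible PIP molecules on a vesicle
#'
#' Proteins in lysate can only reach the outer leaflet of a vesicle, so the
#' accessible PIP count is the outer-leaflet lipid count (sphere surface
#' area `4 * pi * (d/2)^2` divided by the area per lipid) times the PIP
#' mole fraction. A 50-nm vesicle with 5% PIP at 0.65 nm^2 per lipid
#' presents ~600 PIP molecules.
#'
#' @param spec a [VesicleSpec-class].
#' @param round round the result to a whole molecule count (half away from
#'   zero)? Default TRUE.
#' @return PIP molecule count on the outer leaflet.
#' @examples
#' suvAccessiblePipCount(vesicleSpec(50, 0.65, 0.05))  # 604
#' @export
suvAccessiblePipCount <- function(spec, round = TRUE) {
  stopifnot(is(spec, "VesicleSpec"))
  validObject(spec)
  outer_lipids <- 4 * pi * (spec@diameter / 2)^2 / spec@areaPerLipid
  n <- spec@pipFraction * outer_lipids
  if (round) roundCount(n) else n
}

#' Lipid surface area of a disc leaflet
#'
#' Per-leaflet lipid area in nm^2: lipids per leaflet times area per lipid.
#' The standard 80-lipid leaflet at 0.50 nm^2 per lipid gives ~40 nm^2.
#'
#' @param spec a [DiscSpec-class].
#' @return Leaflet lipid area, nm^2.
#' @examples
#' discLipidArea(discSpec())  # 40
#' @export
discLipidArea <- function(spec) {
  stopifnot(is(spec, "DiscSpec"))
  validObject(spec)
  spec@lipidsPerLeaflet * spec@areaPerLipid
}

#' Dye mass fraction of a labelled disc
#'
#' Percentage of total disc mass contributed by the dye:
#' `100 * nDye * dyeMw / (nDye * dyeMw + nScaffold * scaffoldMw +
#' nLipids * lipidMw)`. The default DiD-labelled MSP1D1 disc gives ~1%.
#'
#' @param model a [MassModel-class].
#' @return Dye mass fraction in percent, in the range 0 to 100.
#' @examples
#' dyeMassFraction(massModel())  # ~1.3%
#' @export
dyeMassFraction <- function(model) {
  stopifnot(is(model, "MassModel"))
  validObject(model)
  dye <- model@nDye * model@dyeMw
  total <- dye + model@nScaffold * model@scaffoldMw +
    model@nLipids * model@lipidMw
  100 * dye / total
}

#' PIP molecules per leaflet and per disc
#'
#' Reports the PIP count both per leaflet and per whole disc, since a
#' "percent PIP" composition statement can be read against either base
#' (a 5-10% disc carries 4-8 PIPs per leaflet, i.e. 8-16 per disc).
#'
#' @param spec a [DiscSpec-class].
#' @return Named list with `perLeaflet` and `perDisc` integer counts.
#' @examples
#' discPipCount(discSpec(pipFraction = 0.05))
#' @export
discPipCount <- function(spec) {
  stopifnot(is(spec, "DiscSpec"))
  validObject(spec)
  per <- roundCount(spec@pipFraction * spec@lipidsPerLeaflet)
  list(perLeaflet = per, perDisc = per * spec@leaflets)
}

#' Computed composition table for a set of disc specifications
#'
#' Expands each disc specification into its derived composition (anionic
#' lipids per leaflet, PIP per leaflet/disc, leaflet area) for CSV export.
#'
#' @param specs a list of [DiscSpec-class] objects, optionally named.
#' @param file optional path; when given the table is also written as CSV.
#' @return A data.frame, one row per specification.
#' @export
compositionTable <- function(specs, file = NULL) {
  if (is(specs, "DiscSpec")) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    pip <- discPipCount(s)
    data.frame(
      name = if (!is.null(names(specs)) && nzchar(names(specs)[i]))
        names(specs)[i] else paste0("disc", i),
      lipidsPerLeaflet = s@lipidsPerLeaflet,
      anionicFraction = s@anionicFraction,
      pipFraction = s@pipFraction,
      areaPerLipid = s@areaPerLipid,
      anionicPerLeaflet = anionicPerLeaflet(s),
      pipPerLeaflet = pip$perLeaflet,
      pipPerDisc = pip$perDisc,
      leafletArea_nm2 = discLipidArea(s))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Read disc specifications from a YAML configuration
#'
#' The configuration is a named map of disc entries; each entry may set
#' `lipids_per_leaflet`, `anionic_fraction`, `pip_fraction`,
#' `area_per_lipid` and `leaflets` (missing keys take the [discSpec()]
#' defaults).
#'
#' @param path path to a YAML file.
#' @return Named list of [DiscSpec-class] objects.
#' @export
readDiscConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(e) {
    discSpec(
      lipidsPerLeaflet = e$lipids_per_leaflet %||% 80,
      anionicFraction = e$anionic_fraction %||% 0,
      pipFraction = e$pip_fraction %||% 0,
      areaPerLipid = e$area_per_lipid %||% 0.50,
      leaflets = e$leaflets %||% 2)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
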