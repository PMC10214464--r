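#' Construct a Reaction
#'
#' Builds a validated [Reaction-class] from a named coefficient vector
#' (products positive, reactants negative).  Unless `check = FALSE`, the
#' reaction is checked for elemental and charge balance against the species
#' table.
#'
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param electronDonor Optional species name of the electron donor (must
#'   be a reactant).
#' @param species Species table with composition and charge columns, as
#'   returned by [formationEnergies()].
#' @param tol Per-element balance tolerance (bundled reactions balance
#'   exactly; user reactions entered as floats are accepted to `1e-6`).
#' @param check Check balance on construction?
#' @return A [Reaction-class] object.
#' @examples
#' Reaction(c(acetate = -1, H2O = -1, CH4 = 1, `HCO3-` = 1),
#'          electronDonor = "acetate")
#' @export
Reaction <- function(stoichiometry, electronDonor = NA_character_,
                     species = formationEnergies(), tol = 1e-6,
                     check = TRUE) {
  rx <- new("Reaction", stoichiometry = stoichiometry,
            electronDonor = as.character(electronDonor))
  if (check) checkBalance(rx, species, tol = tol)
  rx
}

#' Check elemental and charge balance of a reaction
#'
#' @param reaction A [Reaction-class].
#' @param species Species table (see [formationEnergies()]).
#' @param tol Per-element tolerance.
#' @return Invisibly `TRUE`; otherwise an error listing every unbalanced
#'   element (and/or charge) with its residual.
#' @export
checkBalance <- function(reaction, species = formationEnergies(),
                         tol = 1e-6) {
  st <- reaction@stoichiometry
  if (length(st) == 0) return(invisible(TRUE))
  idx <- match(names(st), species$species)
  if (anyNA(idx))
    stop("species not in the formation-energy table: ",
         paste(names(st)[is.na(idx)], collapse = ", "))
  elems <- c("C", "H", "O", "N", "S", "Fe", "charge")
  resid <- vapply(elems, function(e)
    sum(st * species[[e]][idx]), numeric(1))
  bad <- abs(resid) > tol
  if (any(bad))
    stop("reaction is not balanced: ",
         paste(sprintf("%s (residual %.3g)", elems[bad], resid[bad]),
               collapse = ", "))
  invisible(TRUE)
}

#' Free-energy change of a reaction at physiological standard state
#'
#' Sums coefficient times formation free energy over all species of a
#' balanced reaction: `sum(nu_i * dGf_i)` at pH 7, 298.15 K, 1 M, 1 bar.
#' Negative values mean the reaction is exergonic as written.
#'
#' @param reaction A [Reaction-class].
#' @param species Formation-energy table ([formationEnergies()] by
#'   default).
#' @param tol Balance tolerance forwarded to [checkBalance()].
#' @return Free-energy change in kJ per mole of reaction as written.
#' @examples
#' acet <- Reaction(c(acetate = -1, H2O = -1, CH4 = 1, `HCO3-` = 1),
#'                  electronDonor = "acetate")
#' reactionDeltaG(acet)  # about -31 kJ/mol
#' @export
reactionDeltaG <- function(reaction, species = formationEnergies(),
                           tol = 1e-6) {
  st <- reaction@stoichiometry
  if (length(st) == 0) return(0)
  idx <- match(names(st), species$species)
  if (anyNA(idx))
    stop("no formation energy for species: ",
         paste(names(st)[is.na(idx)], collapse = ", "))
  checkBalance(reaction, species, tol = tol)
  sum(st * species$dGf[idx])
}

#' Catabolic free energy per mole of electron donor
#'
#' The whole-reaction free energy of a guild's catabolism divided by the
#' absolute stoichiometric coefficient of its electron donor.  When the
#' metabolism carries a fixed `dGcat` (as every entry of the default
#' catalogue does) that value is returned unless `source = "reaction"`
#' forces evaluation of the explicit catabolic reaction.
#'
#' @param metabolism A [MetabolismSpec-class].
#' @param species Formation-energy table.
#' @param source `"fixed"` prefers the stored constant, `"reaction"`
#'   requires the explicit reaction.
#' @return kJ per mole of electron donor (negative: exergonic).
#' @examples
#' cat <- defaultCatalogue()
#' deltaGcat(cat[["Sulphate reducer (H2)"]], source = "reaction")  # ~ -38
#' @export
deltaGcat <- function(metabolism, species = formationEnergies(),
                      source = c("fixed", "reaction")) {
  source <- match.arg(source)
  if (source == "fixed" && !is.na(metabolism@dGcat))
    return(metabolism@dGcat)
  rx <- metabolism@catabolism
  if (is.null(rx))
    stop("metabolism '", metabolism@name,
         "' has no explicit catabolic reaction")
  if (is.na(rx@electronDonor))
    stop("catabolic reaction of '", metabolism@name,
         "' does not declare an electron donor")
  reactionDeltaG(rx, species) / abs(rx@stoichiometry[[rx@electronDonor]])
}

#' Anabolic free energy per mole of biomass
#'
#' Returns the stored anabolic free energy, or evaluates the explicit
#' anabolic reaction (one mole of `biomass` product) when no fixed value is
#' present.
#'
#' @inheritParams deltaGcat
#' @return kJ per mole biomass (may be negative).
#' @export
deltaGana <- function(metabolism, species = formationEnergies()) {
  if (!is.na(metabolism@dGana)) return(metabolism@dGana)
  rx <- metabolism@anabolism
  if (is.null(rx))
    stop("metabolism '", metabolism@name,
         "' has neither a fixed dGana nor an anabolic reaction")
  reactionDeltaG(rx, species) / rx@stoichiometry[["biomass"]]
}

#' Gibbs energy dissipated during biomass synthesis
#'
#' Returns the metabolism's fixed dissipation constant when present
#' (the default catalogue pins each guild to its reference constant);
#' otherwise evaluates the Gibbs-dissipation correlation
#' [heijnenDissipation()] on the carbon source's `(C, gamma)`.
#'
#' @param metabolism A [MetabolismSpec-class].
#' @return kJ per mole biomass (positive).
#' @examples
#' deltaGdis(defaultCatalogue()[["Aerobic heterotroph"]])  # 236
#' @export
deltaGdis <- function(metabolism) {
  if (!is.na(metabolism@dissipation)) return(metabolism@dissipation)
  if (is.na(metabolism@carbonC) || is.na(metabolism@carbonGamma))
    stop("metabolism '", metabolism@name,
         "' has neither a dissipation constant nor a (C, gamma) pair")
  heijnenDissipation(metabolism@carbonC, metabolism@carbonGamma)
}

#' Gibbs-dissipation correlation for heterotrophic growth
#'
#' The empirical correlation for the energy dissipated per carbon-mole of
#' biomass formed, as a function of the carbon-source chain length `C` and
#' its degree of reduction per carbon `gamma`:
#'
#' \deqn{\Delta G_{dis} = 200 + 18(6 - C)^{1.8} +
#'   \exp\{[(3.8-\gamma)^2]^{0.16} (3.6 + 0.4C)\}}
#'
#' in kJ per mole biomass.  Glucose (C = 6, gamma = 4) gives about 236 and
#' acetate (C = 2, gamma = 4) about 432.  For autotrophic growth the
#' correlation does not apply; the conventional constants are 1000 (no
#' reversed electron transport) or 3500 kJ/mol (with reversed electron
#' transport), supplied as fixed constants in the catalogue.
#'
#' @param C Carbon atoms of the carbon source (`1..6`).
#' @param gamma Degree of reduction per carbon of the carbon source.
#' @return kJ per mole biomass.
#' @export
heijnenDissipation <- function(C, gamma) {
  stopifnot(C >= 1, is.finite(gamma))
  200 + 18 * (6 - C)^1.8 + exp(((3.8 - gamma)^2)^0.16 * (3.6 + 0.4 * C))
}

#' Maximum energetic (growth) yield
#'
#' The dimensionless maximum yield `|dGcat| / (dGana + dGdis)`: joules of
#' energy directed into biomass per joule of catabolic energy.  `dGcat` is
#' stored negative (energy released); the magnitude is used so that the
#' conventional yield equation and the sign convention of the energy table
#' agree.  The denominator must be positive -- a non-positive
#' `dGana + dGdis` would mean biomass synthesis releases more energy than
#' it dissipates, which the model treats as unphysical.
#'
#' @param dGcat Catabolic free energy per mole electron donor (kJ/mol,
#'   negative).
#' @param dGana Anabolic free energy per mole biomass (kJ/mol).
#' @param dGdis Dissipated free energy per mole biomass (kJ/mol, positive).
#' @return Dimensionless yield (vectorized over the three arguments).
#' @examples
#' energeticYield(-363, -43, 3500)  # ANAMOX, about 0.10
#' energeticYield(-204, -29, 236)   # fermenting heterotroph, about 0.99
#' @export
energeticYield <- function(dGcat, dGana, dGdis) {
  denom <- dGana + dGdis
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("dGana + dGdis must be positive (unphysical anabolism/",
         "dissipation pair)")
  abs(dGcat) / denom
}

#' Build the per-guild energy table
#'
#' Computes one energy profile (`dG_cat`, `dG_ana`, `dG_dis`, `yield`) per
#' metabolism in a catalogue.  With the default catalogue this reproduces
#' the reference energy table of the 16 recognized guilds; the two guilds
#' whose printed yields are not reproducible from their own free-energy
#' entries are marked `flagged` and their `printed_yield` column carries
#' the reference value (see [defaultCatalogue()]).
#'
#' @param catalogue Named list of [MetabolismSpec-class] objects.
#' @param species Formation-energy table.
#' @return `data.frame` with columns `guild`, `dG_cat`, `dG_ana`,
#'   `dG_dis`, `yield`, `printed_yield`, `flagged`,
#'   `substrate_complexity`.  `yield` is the full-precision computed value;
#'   round for display.
#' @examples
#' et <- buildEnergyTable()
#' head(et[, c("guild", "dG_cat", "yield")])
#' @export
buildEnergyTable <- function(catalogue = defaultCatalogue(),
                             species = formationEnergies()) {
  if (length(catalogue) == 0) stop("empty metabolism catalogue")
  nm <- vapply(catalogue, function(m) m@name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate guild names in catalogue: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rows <- lapply(catalogue, function(m) {
    gc <- deltaGcat(m, species)
    ga <- deltaGana(m, species)
    gd <- deltaGdis(m)
    data.frame(guild = m@name, dG_cat = gc, dG_ana = ga, dG_dis = gd,
               yield = energeticYield(gc, ga, gd),
               printed_yield = m@printedYield, flagged = m@flagged,
               substrate_complexity = m@substrateComplexity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an energy table as TSV
#'
#' @param x Energy table from [buildEnergyTable()].
#' @param path File path.
#' @return `writeEnergyTable` invisibly returns `path`;
#'   `readEnergyTable` returns the `data.frame`.
#' @export
writeEnergyTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyTable
#' @export
readEnergyTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
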