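#' @import methods
NULL

#' Reaction: a stoichiometric (bio)chemical reaction
#'
#' A reaction is a named numeric vector of stoichiometric coefficients
#' (products positive, reactants negative) over species known to a
#' formation-energy table, optionally declaring its electron donor.
#'
#' @slot stoichiometry Named numeric vector; names are species identifiers,
#'   values are signed coefficients (products `> 0`, reactants `< 0`).
#' @slot electronDonor Single character naming the electron donor species,
#'   or `NA_character_` when no donor is declared.
#'
#' @seealso [Reaction()], [reactionDeltaG()], [checkBalance()]
#' @export
setClass("Reaction",
  representation(stoichiometry = "numeric", electronDonor = "character"),
  prototype(stoichiometry = numeric(0), electronDonor = NA_character_)
)

setIsValidReaction <- function(object) {
  st <- object@stoichiometry
  msg <- character(0)
  if (length(st) > 0 && (is.null(names(st)) || any(!nzchar(names(st)))))
    msg <- c(msg, "all stoichiometric coefficients must be named")
  if (anyDuplicated(names(st)))
    msg <- c(msg, "duplicated species in stoichiometry")
  if (any(!is.finite(st)) || any(st == 0))
    msg <- c(msg, "coefficients must be finite and non-zero")
  if (length(object@electronDonor) != 1)
    msg <- c(msg, "electronDonor must be a single string (or NA)")
  if (!is.na(object@electronDonor) &&
      !(object@electronDonor %in% names(st)))
    msg <- c(msg, sprintf("electron donor '%s' is not a reaction species",
                          object@electronDonor))
  if (!is.na(object@electronDonor) &&
      isTRUE(st[object@electronDonor] > 0))
    msg <- c(msg, "electron donor must be a reactant (negative coefficient)")
  if (length(msg)) msg else TRUE
}
setValidity("Reaction", setIsValidReaction)

setClassUnion("ReactionOrNULL", c("Reaction", "NULL"))

#' MetabolismSpec: one functional guild's energetics
#'
#' Describes how a guild earns and spends free energy: an (optional)
#' explicit catabolic reaction, fixed catabolic/anabolic free energies
#' (kJ per mole electron donor and kJ per mole biomass respectively),
#' and either a fixed dissipation constant (kJ per mole biomass) or the
#' `(C, gamma)` pair of its carbon source for the Gibbs-dissipation
#' correlation.
#'
#' @slot name Guild label (one of the 16 recognized guilds in the default
#'   catalogue, but arbitrary labels are allowed for user catalogues).
#' @slot catabolism A [Reaction-class] or `NULL`.
#' @slot anabolism A [Reaction-class] producing one mole of biomass
#'   (`CH1.8O0.5N0.2`), or `NULL`.
#' @slot dGcat Fixed catabolic free energy per mole of electron donor
#'   (kJ/mol, negative for exergonic), or `NA` to compute from `catabolism`.
#' @slot dGana Fixed anabolic free energy per mole biomass (kJ/mol; may be
#'   negative), or `NA` to compute from `anabolism`.
#' @slot dissipation Fixed dissipation constant (kJ per mole biomass,
#'   `> 0`), or `NA` to use the correlation on `(carbonC, carbonGamma)`.
#' @slot carbonC,carbonGamma Carbon count and degree of reduction of the
#'   carbon source, used by the dissipation correlation when no fixed
#'   constant is given.
#' @slot substrateComplexity `"simple"` or `"complex"`.
#' @slot flagged `TRUE` when the printed growth yield of this guild is not
#'   reproducible from its own free-energy entries (see [defaultCatalogue()]).
#' @slot printedYield Reference growth yield as printed in the source energy
#'   table, or `NA`.
#'
#' @seealso [MetabolismSpec()], [defaultCatalogue()], [buildEnergyTable()]
#' @export
setClass("MetabolismSpec",
  representation(
    name = "character",
    catabolism = "ReactionOrNULL",
    anabolism = "ReactionOrNULL",
    dGcat = "numeric",
    dGana = "numeric",
    dissipation = "numeric",
    carbonC = "numeric",
    carbonGamma = "numeric",
    substrateComplexity = "character",
    flagged = "logical",
    printedYield = "numeric"
  ),
  prototype(
    catabolism = NULL, anabolism = NULL,
    dGcat = NA_real_, dGana = NA_real_, dissipation = NA_real_,
    carbonC = NA_real_, carbonGamma = NA_real_,
    substrateComplexity = "simple", flagged = FALSE,
    printedYield = NA_real_
  )
)

setValidity("MetabolismSpec", function(object) {
  msg <- character(0)
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!object@substrateComplexity %in% c("simple", "complex"))
    msg <- c(msg, "substrateComplexity must be 'simple' or 'complex'")
  if (!is.na(object@dissipation) && object@dissipation <= 0)
    msg <- c(msg, "dissipation must be positive")
  if (is.na(object@dissipation) &&
      (is.na(object@carbonC) || is.na(object@carbonGamma)))
    msg <- c(msg, "need a fixed dissipation constant or a (C, gamma) pair")
  if (is.na(object@dGcat) && is.null(object@catabolism))
    msg <- c(msg, "need a fixed dGcat or a catabolic reaction")
  if (!is.null(object@catabolism) && is.na(object@catabolism@electronDonor))
    msg <- c(msg, "catabolic reaction must declare its electron donor")
  if (length(msg)) msg else TRUE
})

#' GuildedCounts: per-sample, per-guild species-abundance vectors
#'
#' The result of assigning genus-level taxonomy to functional guilds and
#' aggregating an OTU table: a long-format table of counts at (sample,
#' guild, taxon) resolution plus per-sample bookkeeping (biome label, total
#' reads, unassigned reads).  Count conservation -- guild counts plus
#' unassigned equal the sample total -- is enforced by the validity method.
#'
#' @slot counts `data.frame` with columns `sample`, `biome`, `guild`,
#'   `taxon`, `count` (non-negative integers; taxa are genera by default).
#' @slot samples `data.frame` with one row per sample: `sample`, `biome`,
#'   `total`, `unassigned`.
#'
#' @seealso [aggregateCounts()], [poolAndEstimate()]
#' @export
setClass("GuildedCounts",
  representation(counts = "data.frame", samples = "data.frame")
)

setValidity("GuildedCounts", function(object) {
  msg <- character(0)
  need <- c("sample", "biome", "guild", "taxon", "count")
  if (!all(need %in% names(object@counts)))
    msg <- c(msg, paste("counts must have columns",
                        paste(need, collapse = ", ")))
  needS <- c("sample", "biome", "total", "unassigned")
  if (!all(needS %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns",
                        paste(needS, collapse = ", ")))
  if (length(msg)) return(msg)
  cnt <- object@counts$count
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (anyDuplicated(object@samples$sample))
    msg <- c(msg, "duplicated sample names")
  if (!all(object@counts$sample %in% object@samples$sample))
    msg <- c(msg, "counts reference unknown samples")
  assigned <- tapply(object@counts$count, object@counts$sample, sum)
  for (s in object@samples$sample) {
    a <- if (s %in% names(assigned)) assigned[[s]] else 0
    i <- match(s, object@samples$sample)
    if (a + object@samples$unassigned[i] != object@samples$total[i])
      msg <- c(msg, sprintf(
        "count conservation violated in sample '%s' (%d assigned + %d unassigned != %d total)",
        s, as.integer(a), as.integer(object@samples$unassigned[i]),
        as.integer(object@samples$total[i])))
  }
  if (length(msg)) msg else TRUE
})

#' ThetaEstimate: maximum-likelihood fundamental biodiversity number
#'
#' The Ewens-sampling-formula estimate of Hubbell's fundamental
#' biodiversity number theta for one species-abundance pool, together with
#' the pool size `J`, species count `S`, the log-likelihood at the optimum
#' and a 95% profile-likelihood interval.  Degenerate pools are flagged:
#' `S == J` gives `theta = Inf` (`boundary = "upper"`), `S == 1` gives
#' `theta = 0` (`boundary = "lower"`).
#'
#' @slot theta Estimated theta (`> 0`, possibly `Inf` or `0` at boundaries).
#' @slot J Total individuals in the pool.
#' @slot S Number of species.
#' @slot loglik Ewens log-likelihood (theta-dependent part) at the optimum.
#' @slot ciLo,ciHi 95% profile-likelihood interval bounds.
#' @slot boundary `"none"`, `"lower"` or `"upper"`.
#'
#' @seealso [ewensThetaMLE()]
#' @export
setClass("ThetaEstimate",
  representation(theta = "numeric", J = "numeric", S = "numeric",
                 loglik = "numeric", ciLo = "numeric", ciHi = "numeric",
                 boundary = "character"),
  prototype(boundary = "none")
)

setValidity("ThetaEstimate", function(object) {
  msg <- character(0)
  if (object@S > object@J) msg <- c(msg, "S cannot exceed J")
  if (object@S < 1) msg <- c(msg, "S must be at least 1")
  if (!object@boundary %in% c("none", "lower", "upper"))
    msg <- c(msg, "boundary must be 'none', 'lower' or 'upper'")
  if (object@boundary == "none" &&
      !(object@ciLo <= object@theta && object@theta <= object@ciHi))
    msg <- c(msg, "confidence interval must contain theta")
  if (length(msg)) msg else TRUE
})
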