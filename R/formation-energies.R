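#' Standard formation free energies at physiological conditions
#'
#' A reference table of Gibbs free energies of formation for the aqueous
#' and gaseous species used by the bundled metabolism catalogue, at
#' 298.15 K, 1 bar, 1 M, pH 7.  Values are the classical compilation of
#' Thauer, Jungermann and Decker (1977, Bacteriol. Rev. 41:100-180); the
#' pH-7 standard state is carried entirely by the proton entry, whose
#' formation energy is RT ln(1e-7) = -39.87 kJ/mol, so every reaction
#' consuming or producing protons is automatically corrected to
#' physiological pH.  Biomass is the Roels unit carbon-mole CH1.8O0.5N0.2
#' with the Heijnen-convention formation energy of -67 kJ/mol.
#'
#' @return A `data.frame` with one row per species and columns `species`,
#'   the elemental composition (`C`, `H`, `O`, `N`, `S`, `Fe`), `charge`,
#'   `dGf` (kJ/mol at pH 7), `phase` and `carbons`/`gamma` (carbon count
#'   and degree of reduction, derived from composition -- see
#'   [degreeOfReduction()]).
#'
#' @examples
#' fe <- formationEnergies()
#' fe[fe$species == "acetate", ]
#' @export
formationEnergies <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
species      C  H    O    N    S  Fe charge  dGf      phase
H2O          0  2    1    0    0  0   0     -237.17   l
H+           0  1    0    0    0  0   1      -39.87   aq
H2           0  2    0    0    0  0   0        0.00   g
O2           0  0    2    0    0  0   0        0.00   g
CO2          1  0    2    0    0  0   0     -394.36   g
HCO3-        1  1    3    0    0  0  -1     -586.85   aq
CH4          1  4    0    0    0  0   0      -50.75   g
methanol     1  4    1    0    0  0   0     -175.39   aq
glucose      6 12    6    0    0  0   0     -917.22   aq
acetate      2  3    2    0    0  0  -1     -369.41   aq
lactate      3  5    3    0    0  0  -1     -517.81   aq
NH4+         0  4    0    1    0  0   1      -79.37   aq
NO2-         0  0    2    1    0  0  -1      -37.20   aq
NO3-         0  0    3    1    0  0  -1     -111.34   aq
N2           0  0    0    2    0  0   0        0.00   g
SO4--        0  0    4    0    1  0  -2     -744.63   aq
HS-          0  1    0    0    1  0  -1       12.05   aq
S0           0  0    0    0    1  0   0        0.00   s
Fe++         0  0    0    0    0  1   2      -78.87   aq
Fe+++        0  0    0    0    0  1   3       -4.60   aq
biomass      1  1.8  0.5  0.2  0  0   0      -67.00   s
")
  df$carbons <- df$C
  df$gamma <- degreeOfReduction(df)
  df
}

#' Degree of reduction of a species
#'
#' Electron equivalents per mole under the standard biomass valence
#' convention: C = +4, H = +1, O = -2, N = -3, S = +6, Fe = +3, with the
#' ionic charge subtracted.  Fully oxidized reference species (CO2, SO4--,
#' NH4+, H2O) have gamma = 0; glucose has 4 per carbon and the biomass
#' unit carbon-mole CH1.8O0.5N0.2 has 4.2.
#'
#' @param x A `data.frame` with elemental composition columns `C`, `H`,
#'   `O`, `N`, `S`, `Fe` and a `charge` column (as in
#'   [formationEnergies()]).
#' @return Numeric vector of degrees of reduction.
#' @export
degreeOfReduction <- function(x) {
  4 * x$C + x$H - 2 * x$O - 3 * x$N + 6 * x$S + 3 * x$Fe - x$charge
}
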