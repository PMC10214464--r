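# Shared fixtures built in code.

# The 16-row reference energy table as printed (guild, dGcat, dGana, dGdis,
# growth yield), used to check the shipped catalogue against its source.
printedEnergyTable <- function() {
  read.table(header = TRUE, sep = "|", strip.white = TRUE,
             stringsAsFactors = FALSE, text = "
guild | dG_cat | dG_ana | dG_dis | yield
ANAMOX | -363 | -43 | 3500 | 0.10
Acetoclastic methanogen | -31 | 30 | 432 | 0.07
Aerobic heterotroph | -2841 | -24 | 236 | 13.42
Ammonia oxidizer | -283 | 274 | 3500 | 0.07
Methylotrophic methanogen | -79 | -33 | 651 | 0.13
Iron III reducer | -809 | 30 | 1088 | 0.72
Fermenting heterotroph | -204 | -29 | 236 | 0.99
Hydrogen oxidizing methanogen | -34 | -25 | 1088 | 0.03
Hydrogen oxidizer | -237 | -25 | 1088 | 0.22
Methanotroph | -813 | 46 | 986 | 1.26
Methylotroph (methanol) | -689 | -216 | 986 | 0.89
Nitrite oxidizer | -79 | 313 | 3500 | 0.02
Sulphur oxidizer | -797 | 55 | 1088 | 0.70
Sulphate reducer (complete ox) | -100 | 26 | 377 | 0.25
Sulphate reducer (H2) | -38 | -25 | 1088 | 0.04
Sulphate reducer (partial ox to acetate) | -14 | 26 | 377 | 0.03
")
}

# Independent grid-search maximizer of the Ewens log-likelihood: coarse
# grid iteratively refined around the argmax.  Never calls the package's
# root-finding solver.
gridSearchTheta <- function(S, J, lo = 1e-6, hi = NULL, refinements = 6) {
  if (is.null(hi)) hi <- 10 * J
  for (r in seq_len(refinements)) {
    grid <- seq(lo, hi, length.out = 2001)
    ll <- S * log(grid) + lgamma(grid) - lgamma(grid + J)
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
  }
  grid[i]
}

# Tiny 3-sample OTU fixture with known genera.
tinyOTUFixture <- function() {
  otu <- matrix(c(5L, 3L, 0L,
                  2L, 0L, 4L,
                  1L, 1L, 1L,
                  0L, 6L, 2L,
                  3L, 0L, 0L),
                nrow = 5, byrow = TRUE,
                dimnames = list(paste0("OTU_", 1:5),
                                c("s1", "s2", "s3")))
  tax <- c(
    "k__Bacteria; p__; c__; o__; f__; g__Nitrosomonas; s__",
    "k__Bacteria; p__; c__; o__; f__; g__Pseudomonas; s__",
    "k__Bacteria; p__; c__; o__; f__; g__; s__",
    "k__Bacteria; p__; c__; o__; f__; g__Methanosarcina; s__",
    "k__Bacteria; p__; c__; o__; f__; g__Nitrosospira; s__")
  list(otu = otu, taxonomy = data.frame(otu_id = rownames(otu),
                                        lineage = tax,
                                        stringsAsFactors = FALSE))
}
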