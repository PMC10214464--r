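# GuildEnergy

Why are some bacterial functional guilds — ammonia oxidizers, sulphate
reducers, aerobic heterotrophs — so much more diverse than others?  One
candidate answer is thermodynamic: guilds exploiting richer redox couples
have more free energy to turn into biomass, and that energy budget may set
an upper bound on how much taxonomic diversity a guild can sustain.
GuildEnergy implements the full analysis needed to test this idea on
taxa-by-sample count tables: it is written for microbial ecologists and
bioinformaticians working with 16S OTU tables who want to go from taxonomy
annotations to a per-biome energy–diversity regression in a handful of
calls.

## The model

For each guild the **maximum energetic yield** is computed from three free
energies at physiological standard state (pH 7, 298.15 K, 1 M, 1 bar):

```
yield = |ΔG_cat| / (ΔG_ana + ΔG_dis)
```

where ΔG_cat is the catabolic free energy per mole of electron donor
(negative, from the stoichiometry of the redox couple and a
formation-energy table), ΔG_ana the anabolic free energy per mole of
biomass CH₁.₈O₀.₅N₀.₂, and ΔG_dis the energy dissipated during biomass
synthesis (fixed reference constants, with the Heijnen dissipation
correlation available as an alternative).  Yields span almost three orders
of magnitude, from ~0.02 (nitrite oxidizers) to ~13 (aerobic
heterotrophs).

Guild **diversity** is summarized two ways: the inverse Simpson index per
sample, and Hubbell's fundamental biodiversity number θ per (biome, guild)
pool — the metacommunity diversity that would explain the taxa observed
locally under neutral assembly.  θ is estimated by the Ewens sampling
formula maximum-likelihood equation

```
S = Σ_{i=0}^{J−1} θ / (θ + i)
```

which depends on the data only through the species count S and pool size
J, with a 95% profile-likelihood interval.

The relationship is then fitted by ordinary least squares of ln θ on
ln(yield) (or on ln|ΔG_cat|), per biome and pooled, and the ranking
consistency of guild diversity across biomes is checked with Friedman's
test.  A seeded neutral-community simulator (`generateDataset`) emits OTU
tables, taxonomy, guild maps and ground truth with a planted log–log
slope, so the entire pipeline is testable end to end without any external
data.

## Worked example

```r
library(GuildEnergy)

## The per-guild energy table (16 guilds; 2 d.p. shown)
et <- buildEnergyTable()
head(transform(et[, c("guild","dG_cat","dG_ana","dG_dis")],
               yield = round(et$yield, 2)), 4)
#>                    guild dG_cat dG_ana dG_dis yield
#>                   ANAMOX   -363    -43   3500  0.11
#>  Acetoclastic methanogen    -31     30    432  0.07
#>      Aerobic heterotroph  -2841    -24    236 13.40
#>         Ammonia oxidizer   -283    274   3500  0.07

## A synthetic multi-biome survey with a planted slope of 0.73
cfg <- simulationConfig(samples_per_biome = 5, J_s = 3500, seed = 42)
ds  <- generateDataset(cfg)
res <- runPipeline(ds$otu_table, ds$taxonomy, ds$guild_map, ds$biomes)
res$guilded
#> GuildedCounts: 30 sample(s), 14 guild(s), 5013 taxa
#>   biomes: Freshwater, Human, Marine, Soil, Volcanic, WWT
#>   unassigned fraction: median 0.000 (range 0.000-0.000)

res$fits
#>       biome slope intercept p_slope p_intercept r2_adjusted  n
#>  Freshwater  1.11      4.39 1.3e-03     1.5e-05        0.56 14
#>       Human  0.39      2.53 6.6e-02     1.3e-04        0.19 14
#>      Marine  0.55      2.43 4.5e-02     1.1e-03        0.24 14
#>        Soil  0.83      3.51 1.5e-03     7.4e-06        0.58 13
#>    Volcanic  1.06      3.64 9.0e-03     6.4e-04        0.40 14
#>         WWT  0.59      2.54 5.9e-02     2.4e-03        0.20 14
#>     overall  0.76      3.17 5.3e-10     5.8e-21        0.37 83

summarizeSlopes(res$fits)$median_significant_slope
#> [1] 0.94
friedmanRankConsistency(res$diversity)
#> Friedman chi-squared = 30.9, df = 13, p-value = 0.002
```

The pooled slope (0.76, 95% CI covering the planted 0.73) says that a
ten-fold increase in energetic yield multiplies metacommunity diversity by
about 10^0.76 ≈ 6; the adjusted R² of 0.37 reflects the noise level the
generator plants around the log–log line; the significant Friedman test
says the guilds are ranked consistently across biomes.  Per-biome slopes
scatter around the planted value, as expected at 14 points per biome.

The theta estimator can also be used directly:

```r
ewensThetaMLE(S = 20, J = 100)
#> ThetaEstimate: 7.244 (95% PL interval 4.066-12.26)  [J = 100, S = 20]
```

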