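test_that("reaction free energies: empty sum, cancellation, linearity, reversal", {
  expect_equal(reactionDeltaG(new("Reaction")), 0)

  # A -> A identity collapses to an empty net stoichiometry, so its dG is
  # the empty sum; cancellation is checked through reversal and linearity.
  acet <- Reaction(c(acetate = -1, H2O = -1, CH4 = 1, `HCO3-` = 1),
                   electronDonor = "acetate")
  rev <- Reaction(c(acetate = 1, H2O = 1, CH4 = -1, `HCO3-` = -1))
  expect_equal(reactionDeltaG(rev), -reactionDeltaG(acet))
  expect_equal(reactionDeltaG(acet) + reactionDeltaG(rev), 0)

  # linearity: dG of a summed reaction equals the sum of dGs
  hox <- Reaction(c(H2 = -1, O2 = -0.5, H2O = 1), electronDonor = "H2")
  both <- Reaction(c(acetate = -1, CH4 = 1, `HCO3-` = 1,
                     H2 = -1, O2 = -0.5))  # acet + hox, H2O cancels
  expect_equal(reactionDeltaG(both),
               reactionDeltaG(acet) + reactionDeltaG(hox))
})

test_that("balance checking rejects unbalanced and unknown species", {
  expect_error(Reaction(c(H2 = -1, H2O = 1)), "not balanced")
  expect_error(Reaction(c(H2 = -1, O2 = -0.5, H2O = 1.0000005)),
               "not balanced")
  # float slack within 1e-6 per element passes
  expect_s4_class(Reaction(c(H2 = -1, O2 = -0.5, H2O = 1 + 1e-9)),
                  "Reaction")
  expect_error(reactionDeltaG(new("Reaction",
                                  stoichiometry = c(unobtainium = 1))),
               "unobtainium")
})

test_that("catabolic energy is per mole of electron donor", {
  cat_ <- defaultCatalogue()
  # H2 sulphate reduction: whole reaction / 4
  srb <- cat_[["Sulphate reducer (H2)"]]
  whole <- reactionDeltaG(srb@catabolism)
  expect_equal(deltaGcat(srb, source = "reaction"), whole / 4)
  expect_equal(deltaGcat(srb, source = "reaction"), -38, tolerance = 0.01)
  # donor coefficient 1: per-donor equals whole-reaction value
  aco <- cat_[["Acetoclastic methanogen"]]
  expect_equal(deltaGcat(aco, source = "reaction"),
               reactionDeltaG(aco@catabolism))
  # hydrogenotrophic methanogenesis per H2
  hm <- cat_[["Hydrogen oxidizing methanogen"]]
  expect_equal(deltaGcat(hm, source = "reaction"), -34, tolerance = 0.01)
  # undeclared donor errors
  rx <- Reaction(c(H2 = -1, O2 = -0.5, H2O = 1))
  m <- MetabolismSpec("no donor", dGcat = -1, dissipation = 100)
  m@catabolism <- rx
  expect_error(deltaGcat(m, source = "reaction"), "electron donor")
})

test_that("dissipation: fixed constant wins; correlation covers the rest", {
  m <- MetabolismSpec("aerobic", dGcat = -2841, dissipation = 236,
                      carbonC = 6, carbonGamma = 4)
  expect_equal(deltaGdis(m), 236)  # fixed beats correlation
  m2 <- MetabolismSpec("auto", dGcat = -283, dissipation = 3500)
  expect_equal(deltaGdis(m2), 3500)
  # correlation on glucose ~236, acetate ~432 (the fixed constants'
  # provenance)
  expect_equal(heijnenDissipation(6, 4), 236, tolerance = 0.5)
  expect_equal(heijnenDissipation(2, 4), 432, tolerance = 0.5)
  expect_error(MetabolismSpec("neither", dGcat = -1),
               "dissipation|gamma")
})

test_that("energetic yield matches the reference rows and is monotone", {
  expect_equal(energeticYield(-363, -43, 3500), 0.105, tolerance = 1e-2)
  expect_equal(round(energeticYield(-204, -29, 236), 2), 0.99)
  # symmetry: (-X, 0, X) -> 1 for any X > 0
  for (X in c(0.5, 1, 237, 3500))
    expect_equal(energeticYield(-X, 0, X), 1)
  expect_error(energeticYield(-100, -300, 200), "positive")
  # monotone in |dGcat| and in dGdis
  y <- energeticYield(c(-10, -20, -40), -25, 1088)
  expect_true(all(diff(y) > 0))
  y2 <- energeticYield(-100, -25, c(500, 1000, 2000))
  expect_true(all(diff(y2) < 0))
})

test_that("default energy table matches the printed reference", {
  ref <- printedEnergyTable()
  et <- buildEnergyTable()
  expect_equal(nrow(et), 16)
  et <- et[match(ref$guild, et$guild), ]
  expect_equal(et$dG_cat, ref$dG_cat)
  expect_equal(et$dG_ana, ref$dG_ana)
  expect_equal(et$dG_dis, ref$dG_dis)
  # every catabolic energy is exergonic
  expect_true(all(et$dG_cat < 0))
  # 14 consistent rows reproduce the printed yield; 2 flagged rows do not
  ok <- !et$flagged
  expect_equal(sum(ok), 14)
  expect_true(all(abs(et$yield[ok] - ref$yield[ok]) <= 0.005 + 2e-4))
  expect_true(all(abs(et$yield[!ok] - ref$yield[!ok]) > 0.005))
  expect_setequal(et$guild[!ok], c("Aerobic heterotroph", "Methanotroph"))
})

test_that("energy table plumbing: errors, composition, TSV round-trip", {
  expect_error(buildEnergyTable(list()), "empty")
  cat_ <- defaultCatalogue()
  expect_error(buildEnergyTable(cat_[c(1, 1)]), "duplicate")
  one <- buildEnergyTable(cat_["ANAMOX"])
  expect_equal(nrow(one), 1)
  expect_equal(one$yield, energeticYield(one$dG_cat, one$dG_ana,
                                         one$dG_dis))
  p <- withr::local_tempfile(fileext = ".tsv")
  et <- buildEnergyTable()
  writeEnergyTable(et, p)
  back <- readEnergyTable(p)
  expect_equal(back$guild, et$guild)
  expect_equal(back$yield, et$yield, tolerance = 1e-12)
})

test_that("species table is internally consistent (composition vs gamma)", {
  fe <- formationEnergies()
  expect_equal(fe$carbons, fe$C)
  expect_equal(fe$gamma, degreeOfReduction(fe))
  # fully oxidized references have zero degree of reduction
  zero <- c("H2O", "CO2", "HCO3-", "SO4--", "NH4+", "H+")
  expect_true(all(fe$gamma[fe$species %in% zero] == 0))
  expect_equal(fe$gamma[fe$species == "glucose"], 24)
  expect_equal(fe$gamma[fe$species == "biomass"], 4.2)
})
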