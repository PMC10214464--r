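test_that("taxonomy parsing extracts genera and normalizes messy input", {
  rec <- parseTaxonomy(c(
    "k__Bacteria; p__; c__; o__; f__; g__Nitrosomonas; s__",
    "k__Bacteria; p__; c__; o__; f__; g__; s__",
    "k__Bacteria; p__; c__; o__; f__; g__[Clostridium]; s__x"))
  expect_equal(rec$genus, c("Nitrosomonas", NA, "Clostridium"))

  # trailing whitespace / case variation assign like the clean form
  map <- readGuildMap()
  clean <- assignGuilds(parseTaxonomy("k__B; g__Nitrosomonas; s__"), map)
  messy <- assignGuilds(parseTaxonomy("k__B;  g__nitrosomonas ; s__"), map)
  expect_equal(messy$guild, clean$guild)
  expect_equal(messy$genus, clean$genus)  # canonical spelling restored

  expect_warning(parseTaxonomy("gibberish with no rank structure"),
                 "rank structure")
})

test_that("guild map fixture is valid and covers the recognized guilds", {
  map <- readGuildMap()
  expect_true(all(map$guild[!map$exclude_flag] %in% guildNames()))
  expect_length(guildNames(), 16)
  expect_false(any(map$genus[map$exclude_flag] %in%
                     map$genus[!map$exclude_flag]))
  expect_gte(sum(!map$exclude_flag), 50)
  # every guild has at least one fixture genus
  expect_setequal(unique(map$guild[!map$exclude_flag]), guildNames())
})

test_that("assignment: known genera, exclusions, degenerate maps", {
  map <- readGuildMap()
  fx <- tinyOTUFixture()
  plan <- assignGuilds(parseTaxonomy(fx$taxonomy), map)
  expect_equal(plan$guild[plan$genus %in% "Nitrosomonas"],
               "Ammonia oxidizer")
  expect_equal(plan$status[plan$genus %in% "Methanosarcina"], "excluded")
  expect_equal(plan$status[is.na(plan$genus)], "genus_absent")
  # every OTU gets exactly one guild or a reason
  expect_true(all(xor(is.na(plan$guild), plan$status == "assigned")))

  nomatch <- data.frame(otu_id = "x", lineage = "g__Zzz",
                        genus = "Zzz", stringsAsFactors = FALSE)
  expect_warning(p2 <- assignGuilds(nomatch, map), "unassigned")
  expect_true(all(is.na(p2$guild)))
})

test_that("aggregation conserves counts and sums same-genus OTUs", {
  map <- readGuildMap()
  fx <- tinyOTUFixture()
  plan <- assignGuilds(parseTaxonomy(fx$taxonomy), map)
  gc <- aggregateCounts(fx$otu, plan,
                        biomes = c(s1 = "A", s2 = "A", s3 = "B"))
  expect_s4_class(gc, "GuildedCounts")
  si <- sampleInfo(gc)
  expect_equal(si$total, unname(colSums(fx$otu)))
  agg <- tapply(guildCounts(gc)$count, guildCounts(gc)$sample, sum)
  expect_equal(as.vector(agg[si$sample]) + si$unassigned, si$total)

  # two OTUs of the same genus merge additively
  otu <- matrix(c(3L, 4L), ncol = 1,
                dimnames = list(c("a", "b"), "s1"))
  tx <- parseTaxonomy(rep("k__B; g__Pseudomonas; s__", 2),
                      otu_ids = c("a", "b"))
  g2 <- aggregateCounts(otu, assignGuilds(tx, map), biomes = "A")
  expect_equal(guildCounts(g2)$count, 7L)
  expect_equal(nrow(guildCounts(g2)), 1)
})

test_that("aggregation matches a brute-force nested-loop oracle on random tables", {
  map <- readGuildMap()
  set.seed(42)
  genera <- c(sample(map$genus, 15), "Unknownia")
  for (rep in 1:5) {
    n <- 30
    ids <- paste0("OTU_", seq_len(n))
    gen <- sample(genera, n, replace = TRUE)
    lin <- sprintf("k__B; p__; c__; o__; f__; g__%s; s__", gen)
    otu <- matrix(rpois(n * 4, 3), nrow = n,
                  dimnames = list(ids, paste0("s", 1:4)))
    storage.mode(otu) <- "integer"
    plan <- assignGuilds(parseTaxonomy(lin, otu_ids = ids), map)
    gc <- aggregateCounts(otu, plan, biomes = "X")

    # oracle: explicit nested loops over samples x guilds x genera
    cnt <- guildCounts(gc)
    for (s in colnames(otu)) {
      for (g in unique(stats::na.omit(plan$guild))) {
        for (taxon in unique(plan$genus[plan$guild %in% g])) {
          tot <- 0
          for (i in seq_len(n))
            if (!is.na(plan$guild[i]) && plan$guild[i] == g &&
                plan$genus[i] == taxon)
              tot <- tot + otu[i, s]
          got <- cnt$count[cnt$sample == s & cnt$guild == g &
                             cnt$taxon == taxon]
          expect_equal(sum(got), tot)
        }
      }
    }
    # order-independence: permuting rows yields identical counts
    pm <- sample(n)
    gc2 <- aggregateCounts(otu[pm, ], plan[pm, ], biomes = "X")
    o1 <- guildCounts(gc)
    o2 <- guildCounts(gc2)
    key <- function(d) d[order(d$sample, d$guild, d$taxon), ]
    expect_equal(key(o1), key(o2), ignore_attr = TRUE)
  }
})

test_that("OTU tables round-trip through TSV and read from BIOM", {
  fx <- tinyOTUFixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  writeOTUTable(fx$otu, p)
  expect_identical(readOTUTable(p), fx$otu)

  bp <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(fx$otu), bp)
  m <- readOTUTable(bp)
  expect_equal(m[rownames(fx$otu), colnames(fx$otu)], fx$otu)
})

test_that("dimension mismatches and bad counts are fatal", {
  map <- readGuildMap()
  fx <- tinyOTUFixture()
  plan <- assignGuilds(parseTaxonomy(fx$taxonomy), map)
  expect_error(aggregateCounts(fx$otu[1:3, ], plan, biomes = "A"),
               "disagree")
  bad <- fx$otu
  bad[1, 1] <- -1L
  expect_error(aggregateCounts(bad, plan, biomes = "A"), "non-negative")
})
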