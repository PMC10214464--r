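test_that("inverse Simpson: closed forms, invariances, bounds", {
  expect_equal(inverseSimpson(rep(5, 4)), 4)     # uniform equals S
  expect_equal(inverseSimpson(9), 1)             # monoculture
  expect_equal(inverseSimpson(c(3, 1)), 1.6)     # 1/(0.75^2+0.25^2)
  expect_error(inverseSimpson(integer(0)), "empty")
  # agrees with the direct formula, is permutation- and scale-invariant,
  # and lies in [1, S]
  set.seed(1)
  for (i in 1:20) {
    v <- rpois(sample(2:20, 1), 5) + 1
    d <- inverseSimpson(v)
    expect_equal(d, 1 / sum((v / sum(v))^2))
    expect_equal(inverseSimpson(sample(v)), d)
    expect_equal(inverseSimpson(v * 7L), d)
    expect_gte(d, 1)
    expect_lte(d, length(v) + 1e-12)
  }
})

test_that("Ewens theta MLE: boundaries, self-consistency, monotonicity", {
  expect_equal(thetaValue(ewensThetaMLE(rep(1, 10))), Inf)  # S == J
  expect_equal(ewensThetaMLE(rep(1, 10))@boundary, "upper")
  expect_equal(thetaValue(ewensThetaMLE(c(10))), 0)         # S == 1
  expect_equal(ewensThetaMLE(c(10))@boundary, "lower")
  expect_error(ewensThetaMLE(S = 21, J = 20), "exceed")
  expect_error(ewensThetaMLE(S = 0, J = 20), "at least 1")

  # self-consistency: expected S at theta-hat equals observed S
  for (sj in list(c(20, 100), c(5, 1000), c(300, 5000))) {
    est <- ewensThetaMLE(S = sj[1], J = sj[2])
    expect_equal(GuildEnergy:::ewensExpectedS(thetaValue(est), sj[2]),
                 sj[1], tolerance = 1e-7)
    expect_true(est@ciLo < thetaValue(est) & thetaValue(est) < est@ciHi)
  }

  # strictly increasing in S at fixed J; decreasing in J at fixed S
  th_s <- vapply(c(5, 10, 20, 40), function(S)
    thetaValue(ewensThetaMLE(S = S, J = 200)), numeric(1))
  expect_true(all(diff(th_s) > 0))
  th_j <- vapply(c(100, 200, 800, 3200), function(J)
    thetaValue(ewensThetaMLE(S = 30, J = J)), numeric(1))
  expect_true(all(diff(th_j) < 0))
})

test_that("solver agrees with an independent grid-search likelihood oracle", {
  est <- ewensThetaMLE(S = 20, J = 100)
  oracle <- gridSearchTheta(20, 100, hi = 100)
  expect_equal(thetaValue(est), oracle, tolerance = 1e-6)

  set.seed(99)
  for (i in 1:12) {
    J <- sample(50:2000, 1)
    S <- sample(2:(J - 1), 1)
    est <- thetaValue(ewensThetaMLE(S = S, J = J))
    expect_equal(est, gridSearchTheta(S, J), tolerance = 1e-6)
  }
})

test_that("pooling sums within (biome, guild) and matches direct recomputation", {
  cnt <- data.frame(
    sample = rep(c("s1", "s2"), each = 3),
    biome = "B", guild = "Ammonia oxidizer",
    taxon = c("a", "b", "c", "a", "b", "d"),
    count = c(4L, 2L, 1L, 3L, 2L, 2L), stringsAsFactors = FALSE)
  samp <- data.frame(sample = c("s1", "s2"), biome = "B",
                     total = c(7L, 7L), unassigned = c(0L, 0L),
                     stringsAsFactors = FALSE)
  gc <- new("GuildedCounts", counts = cnt, samples = samp)
  res <- poolAndEstimate(gc)
  # direct recomputation oracle: pool by hand, estimate directly
  pooled <- c(a = 7, b = 4, c = 1, d = 2)
  direct <- ewensThetaMLE(pooled)
  expect_equal(res$theta, thetaValue(direct))
  expect_equal(res$J, 14)
  expect_equal(res$S, 4)

  # one sample: identical to direct estimation on that sample
  gc1 <- new("GuildedCounts", counts = cnt[cnt$sample == "s1", ],
             samples = samp[1, ])
  res1 <- poolAndEstimate(gc1)
  expect_equal(res1$theta, thetaValue(ewensThetaMLE(c(4, 2, 1))))

  # two identical samples: same S, doubled J, finite theta
  expect_equal(res1$S, 3)
  gc2 <- new("GuildedCounts",
             counts = transform(rbind(cnt[1:3, ], cnt[1:3, ]),
                                sample = rep(c("s1", "s2"), each = 3)),
             samples = samp)
  res2 <- poolAndEstimate(gc2)
  expect_equal(res2$S, res1$S)
  expect_equal(res2$J, 2 * res1$J)
  expect_true(is.finite(res2$theta))

  expect_error(poolAndEstimate(gc, scope = "nope"), "scope")
})

test_that("Friedman rank consistency: identical rankings, null, errors", {
  # identical rankings across 5 biomes over 6 guilds: maximal statistic
  div <- expand.grid(biome = paste0("b", 1:5), guild = paste0("g", 1:6),
                     stringsAsFactors = FALSE)
  div$theta <- rep(1:6, each = 5) * 10
  ft <- friedmanRankConsistency(div)
  expect_lt(ft$p.value, 0.01)
  expect_equal(unname(ft$statistic), 25)  # k(n-1) = 5 * 5, perfect blocks

  # permutation oracle for the maximal-statistic p-value at small size
  set.seed(3)
  nperm <- 2000
  stat0 <- unname(ft$statistic)
  perm <- replicate(nperm, {
    d2 <- div
    d2$theta <- ave(d2$theta, d2$biome, FUN = sample)
    unname(friedmanRankConsistency(d2)$statistic)
  })
  expect_lt(mean(perm >= stat0), 0.01)

  expect_error(friedmanRankConsistency(div[div$biome == "b1", ]),
               "2 biomes")
  # incomplete block after intersection names the missing guilds
  expect_error(
    friedmanRankConsistency(div[!(div$biome == "b1" &
                                    div$guild != "g1"), ]),
    "incomplete block")
})
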