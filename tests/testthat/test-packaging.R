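test_that("hitchhiker arithmetic reproduces the printed chain", {
  est <- hitchhikerFraction(packagingCounts(634740, 108219, 47851, 6110, 8))
  expect_equal(round(est@normHelper, 2), 13.26)
  expect_equal(round(est@normSatellite, 2), 17.71)
  expect_equal(round(est@particleEquiv, 2), 2.21)
  expect_equal(hitchhikerPct(est), 16L)
  expect_equal(hitchhikerPct(est, full = TRUE),
               100 * (108219 / 6110 / 8) / (634740 / 47851))
})

test_that("hitchhiker percentage edge cases: zero and equality", {
  zero <- hitchhikerFraction(packagingCounts(1000, 0, 1000, 100, 2))
  expect_equal(hitchhikerPct(zero), 0L)
  expect_equal(hitchhikerPct(zero, full = TRUE), 0)
  eq <- hitchhikerFraction(packagingCounts(1000, 200, 1000, 100, 2))
  expect_equal(eq@particleEquiv, eq@normHelper)
  expect_equal(hitchhikerPct(eq), 100L)
})

test_that("full-precision output equals the algebraic closed form", {
  set.seed(81)
  for (i in 1:10) {
    rh <- as.numeric(sample(1e4:1e6, 1)); rs <- as.numeric(sample(1e3:1e5, 1))
    lh <- as.numeric(sample(2e4:6e4, 1)); ls <- as.numeric(sample(3e3:9e3, 1))
    k <- as.numeric(sample(2:10, 1))
    est <- hitchhikerFraction(packagingCounts(rh, rs, lh, ls, k))
    expect_equal(hitchhikerPct(est, full = TRUE),
                 100 * (rs * lh) / (rh * ls * k), tolerance = 1e-12)
  }
})

test_that("headful copy number minimizes the capsid-fill deviation", {
  expect_equal(headfulCopyNumber(47851, 6110), 8L)
  expect_equal(headfulCopyNumber(5000, 5000), 1L)
  expect_equal(headfulCopyNumber(10000, 3000), 3L)
  expect_equal(headfulCopyNumber(9000, 6000), 2L)   # tie goes to the larger k
  expect_error(headfulCopyNumber(3000, 10000), "lenSatellite")
})

test_that("reads classify as helper, satellite, hybrid or unassigned", {
  set.seed(91)
  helper <- rand_dna(3000)
  unit <- rand_dna(900)
  conc <- strrep(unit, 3)
  pick <- function(ref, n, w = 150) {
    st <- sample(nchar(ref) - w + 1, n)
    substring(ref, st, st + w - 1)
  }
  reads <- c(pick(helper, 5), pick(conc, 5),
             paste0(substring(helper, 101, 175), substring(conc, 201, 275)),
             rand_dna(150))
  counts <- classifyReads(reads, helper, unit, minAnchor = 50)
  calls <- attr(counts, "calls")
  expect_equal(calls[1:5], rep("helper", 5))
  expect_equal(calls[6:10], rep("satellite", 5))
  expect_equal(calls[11], "hybrid")
  expect_equal(calls[12], "unassigned")
  expect_equal(counts@readsHybrid, 1)
})

test_that("hybrid calls equal the planted chimera count on generator reads", {
  cfg <- simulationConfig(seed = 92, nReads = 40L, readLen = 150L,
                          chimeraRate = 0.1, hitchhikerFraction = 0.3,
                          helperLen = 4000L, elementLen = 6110L,
                          concatemerCopies = 2L)
  sim <- simulateReads(cfg, emitSequences = TRUE)
  counts <- classifyReads(sim$shortReadSeqs, sim$helperRef, sim$unitRef,
                          minAnchor = 50)
  expect_equal(counts@readsHybrid, unname(sim$truth$perRead["chimera"]))
})

test_that("concatemer mapping recovers phases on both strands", {
  set.seed(93)
  unit <- rand_dna(300)
  # 2.5 unit copies starting at unit offset 100 (0-based)
  read <- substring(strrep(unit, 4), 101, 101 + 750 - 1)
  hit <- mapConcatemerReads(c(r1 = read), unit, nUnits = 4)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$phase_start, 100)
  expect_equal(hit$end_on_ref - hit$start_on_ref, 750)

  exact <- mapConcatemerReads(c(r2 = unit), unit, nUnits = 4)
  expect_equal(exact$phase_start, 0)

  rc <- as.character(reverseComplement(DNAString(read)))
  hit_rc <- mapConcatemerReads(c(r3 = rc), unit, nUnits = 4)
  expect_equal(hit_rc$phase_start, 100)
  expect_equal(hit_rc$strand, "-")
})

test_that("low-identity reads are dropped and oversized reads are refused", {
  set.seed(94)
  unit <- rand_dna(300)
  junk <- rand_dna(250)
  expect_message(out <- mapConcatemerReads(c(j = junk), unit, nUnits = 4),
                 "dropped")
  expect_equal(nrow(out), 0)
  long <- rand_dna(1300)
  expect_error(mapConcatemerReads(c(l = long), unit, nUnits = 4), "nUnits")
})

test_that("extremity test separates fixed from uniform phase patterns", {
  fixed <- rep(42, 100)
  res <- extremityRandomnessTest(fixed, bins = 20, unitLen = 6110)
  expect_lt(res$p_value, 1e-6)
  expect_match(res$verdict, "fixed")

  half <- rep(c(0, 3055), 50)
  res2 <- extremityRandomnessTest(half, bins = 2, unitLen = 6110)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_match(res2$verdict, "random")

  expect_error(extremityRandomnessTest(rep(1, 10), unitLen = 100),
               "underpowered")
})

test_that("planted hitchhiker fractions are recovered from counts", {
  for (f in c(0.05, 0.30)) {
    cfg <- simulationConfig(seed = round(100 * f), hitchhikerFraction = f,
                            nReads = 100000L, chimeraRate = 0)
    sim <- simulateReads(cfg)
    est <- estimateHitchhikerFraction(sim$counts)
    expect_lt(abs(est$fraction - f), 3 * est$se)
  }
})
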