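test_that("a forced minimal configuration yields a nuclear family", {
  cfg <- cohortSimConfig(nFoundingCouples = 1, generations = 2,
                         offspringMean = 2, targetSize = 4,
                         sizeTolerance = 0, seed = 2)
  p <- simulatePedigree(cfg)
  expect_equal(nrow(individuals(p)), 4)
  expect_equal(length(founders(p)), 2)
  expect_equal(max(generationDepth(p)), 1)
})

test_that("island-scale defaults produce pedigrees near the census size", {
  sizes <- sapply(1:20, function(s) {
    p <- simulatePedigree(cohortSimConfig(seed = s))
    c(nrow(individuals(p)), length(founders(p)))
  })
  expect_true(all(abs(sizes[1, ] - 288) <= 0.3 * 288))
  # founder count of the emulated genealogy is in a plausible band
  expect_gt(mean(sizes[2, ]), 60)
  expect_lt(mean(sizes[2, ]), 110)
})

test_that("consanguineous unions create inbred individuals", {
  found <- FALSE
  for (s in 1:15) {
    cfg <- cohortSimConfig(nFoundingCouples = 2, generations = 4,
                           offspringMean = 2.5, consanguinityProb = 0.5,
                           targetSize = NULL, seed = 400 + s)
    p <- simulatePedigree(cfg)
    if (any(inbreeding(kinshipMatrix(p)) > 1e-9)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("phenotype model recovers its generating parameters", {
  # flat population with carrier fraction pinned at the calibration value
  n <- 20000
  ids <- paste0("i", seq_len(n))
  sex <- rep(c("male", "female"), n / 2)
  p <- Pedigree(id = ids, sex = sex)
  g <- setNames(as.integer(seq_len(n) %% 16 %in% c(0, 1)), ids)  # 12.5% carriers, both sexes
  cfg <- cohortSimConfig()
  aff <- simulatePhenotypes(p, g, cfg, seed = 51)
  affL <- aff == "affected"
  prev <- prevalenceBySex(affL, sex)
  expect_lt(abs(prev["male"] - 0.25), 3 * sqrt(0.25 * 0.75 / (n / 2)))
  expect_lt(abs(prev["female"] - 0.27), 3 * sqrt(0.27 * 0.73 / (n / 2)))
  pen <- penetrancePhenocopySummary(g >= 1, affL)
  expect_lt(abs(pen$penetrance - 0.76), 3 * sqrt(0.76 * 0.24 / sum(g >= 1)))
  # degenerate settings: affected iff carrier
  cfg2 <- cohortSimConfig(penetranceCarrier = 1,
                          baselineRiskMale = 0, baselineRiskFemale = 0)
  aff2 <- simulatePhenotypes(p, g, cfg2, seed = 52)
  expect_equal(aff2 == "affected", g >= 1, ignore_attr = TRUE)
})

test_that("baseline risk calibration solves the prevalence identity", {
  b <- calibrateBaselineRisk(0.25)
  expect_equal(0.125 * 0.76 + 0.875 * b, 0.25)
  expect_equal(calibrateBaselineRisk(0.27), 0.2)
  expect_error(calibrateBaselineRisk(0.01), "outside")
})

test_that("simulated cohorts are deterministic and carry the planted variant", {
  co1 <- simulateCohort(cohortSimConfig(seed = 61))
  co2 <- simulateCohort(cohortSimConfig(seed = 61))
  expect_identical(co1$genotypes, co2$genotypes)
  expect_identical(individuals(co1$ped), individuals(co2$ped))
  expect_length(co1$carrierFounders, 2)
  expect_true(all(co1$carrierFounders %in% founders(co1$ped)))
  expect_true(all(co1$genotypes[co1$carrierFounders] == 1))
})

test_that("exome fixtures are deterministic with calibrated depths", {
  s1 <- simulateExomeCohort(exomeSimConfig(nBackgroundVariants = 200, seed = 71))
  s2 <- simulateExomeCohort(exomeSimConfig(nBackgroundVariants = 200, seed = 71))
  expect_identical(s1$records, s2$records)
  d <- simulateReadDepth(20000, seed = 72)
  expect_gte(mean(d >= 10), 0.9)
  expect_lt(abs(mean(d) - 56), 1.5)
  # read-evidence invariants hold on every generated record
  expect_true(all(s1$records$variant_reads <= s1$records$depth))
  expect_true(all(s1$records$unique_start_sites <= s1$records$variant_reads))
})

test_that("planted variants associate more strongly than matched null variants", {
  set.seed(81)
  nC <- 40
  wins <- 0; total <- 0
  for (s in seq_len(nC)) {
    co <- simulateCohort(cohortSimConfig(seed = 800 + s))
    d <- individuals(co$ped)
    if (sum(co$genotypes >= 1) < 3) next
    km <- kinshipMatrix(co$ped)
    K <- genotypeCorrelation(km)
    Kchol <- chol(K)
    A <- transformPhenotypes(co$ped)[d$id]
    pPlanted <- mqlsTest(co$genotypes[d$id] / 2, A, K, Kchol = Kchol)$p
    g0 <- simulateGenotypes(co$ped, founderFreq = 0.05)
    pNull <- mqlsTest(g0[d$id] / 2, A, K, Kchol = Kchol)$p
    total <- total + 1
    if (pPlanted < pNull) wins <- wins + 1
  }
  bt <- binom.test(wins, total, p = 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})
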