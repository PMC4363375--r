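test_that("phenotype weights encode affected, unaffected and unknown", {
  p <- trioPed(affection = c("unaffected", "unknown", "affected"))
  Tv <- transformPhenotypes(p, kMale = 0.25, kFemale = 0.27)
  expect_equal(unname(Tv["kid"]), 1)
  expect_equal(unname(Tv["dad"]), -0.25 / 0.75)    # -1/3
  expect_equal(unname(Tv["mum"]), 0)
  expect_error(transformPhenotypes(p, kMale = 1.2), "strictly between")
})

test_that("ungenotyped relatives enrich the weight vector through kinship", {
  p <- nuclearPed(2)
  d <- individuals(p)
  d$affection <- c("unknown", "unknown", "unaffected", "affected")
  p@data <- d
  km <- kinshipMatrix(p)
  Tv <- transformPhenotypes(p)
  # k1 genotyped, affected full sib k2 ungenotyped:
  # A = T + (1/2)^-1 * (1/4) * 1 = T + 1/2
  A <- enrichPhenotypes(Tv, "k1", km, ungenotypedIds = "k2")
  expect_equal(unname(A["k1"]), unname(Tv["k1"]) + 0.5)
  # with no ungenotyped relatives A reduces to T
  A0 <- enrichPhenotypes(Tv, c("k1", "k2"), km, ungenotypedIds = character(0))
  expect_equal(A0, Tv[c("k1", "k2")])
})

test_that("adding phenotyped-ungenotyped individuals changes A, not its length", {
  cfg <- cohortSimConfig(seed = 31)
  co <- simulateCohort(cfg)
  d <- individuals(co$ped)
  km <- kinshipMatrix(co$ped)
  Tv <- transformPhenotypes(co$ped)
  pheno <- d$id[d$affection != "unknown"]
  N <- sample(pheno, 60)
  M <- sample(setdiff(pheno, N), 11)
  A0 <- enrichPhenotypes(Tv, N, km, ungenotypedIds = character(0))
  A1 <- enrichPhenotypes(Tv, N, km, ungenotypedIds = M)
  expect_length(A1, length(A0))
  expect_false(isTRUE(all.equal(A0, A1)))
})

test_that("BLUE allele frequency weights by the genotype correlation", {
  expect_equal(blueAlleleFreq(c(1, 0.5, 0, 0), diag(4)), 0.375) # sample mean
  expect_equal(blueAlleleFreq(rep(0, 5), diag(5)), 0)
  # parent-offspring pair: K symmetric in the two -> equal weights
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(blueAlleleFreq(c(0.5, 0), K), 0.25)
  expect_error(blueAlleleFreq(numeric(0), diag(0)), "no genotyped")
})

test_that("the quasi-likelihood score matches the hand-evaluated closed form", {
  y <- c(1, 0.5, 0, 0)
  A <- c(1, 1, -1/3, -1/3)
  r <- mqlsTest(y, A, diag(4))
  expect_equal(r$W, 4.8)
  expect_equal(r$p, pchisq(4.8, 1, lower.tail = FALSE))
  expect_equal(r$alleleFreq, 0.375)
  expect_true(r$testable)
})

test_that("monomorphic variants are untestable and allele relabelling is neutral", {
  A <- c(1, 1, -1/3, -1/3)
  r0 <- mqlsTest(rep(0, 4), A, diag(4))
  expect_false(r0$testable)
  expect_equal(r0$p, 1)
  y <- c(1, 0.5, 0, 0)
  r1 <- mqlsTest(y, A, diag(4))
  r2 <- mqlsTest(1 - y, A, diag(4))
  expect_equal(r2$W, r1$W)
  expect_equal(r2$p, r1$p)
})

test_that("the statistic is invariant under permuting individuals", {
  p <- twelvePed()
  d <- individuals(p)
  d$affection <- rep(c("affected", "unaffected"), 6)
  p@data <- d
  K <- genotypeCorrelation(kinshipMatrix(p))
  Tv <- transformPhenotypes(p)
  set.seed(4)
  y <- setNames(sample(c(0, 0.5, 1), 12, replace = TRUE), d$id)
  A <- Tv[d$id]
  r1 <- mqlsTest(y, A, K)
  perm <- sample(d$id)
  r2 <- mqlsTest(y[perm], A[perm], K[perm, perm])
  expect_equal(r2$W, r1$W)
  expect_equal(r2$alleleFreq, r1$alleleFreq)
})

test_that("with identity kinship the test reduces to the classical quasi-score", {
  set.seed(9)
  n <- 40
  y <- sample(c(0, 0.5, 1), n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  aff <- runif(n) < 0.3
  A <- ifelse(aff, 1, -0.25 / 0.75)
  r <- mqlsTest(y, A, diag(n))
  # independent closed form for unrelated individuals
  ph <- mean(y)
  W <- sum(A * (y - ph))^2 /
    ((ph * (1 - ph) / 2) * (sum(A^2) - sum(A)^2 / n))
  expect_equal(r$W, W)
})

test_that("association scans report Bonferroni thresholds and X exclusion", {
  co <- simulateCohort(cohortSimConfig(seed = 13))
  ids <- individuals(co$ped)$id
  set.seed(13)
  G <- matrix(rbinom(length(ids) * 8, 2, 0.2), ncol = 8,
              dimnames = list(ids, paste0("v", 1:8)))
  scan <- associationScan(G, co$ped)
  expect_equal(attr(scan, "bonferroni"), 0.05 / 8)
  expect_equal(nrow(scan), 8)
  expect_warning(
    scanX <- associationScan(G, co$ped, chrom = c(rep("4", 7), "X")),
    "X-linked")
  expect_equal(nrow(scanX), 7)
  expect_equal(attr(scanX, "bonferroni"), 0.05 / 7)
  G1 <- G[, 1, drop = FALSE]
  expect_equal(attr(associationScan(G1, co$ped), "bonferroni"), 0.05)
})

test_that("a null scan of unrelated individuals is nominally calibrated", {
  n <- 300
  ids <- paste0("u", seq_len(n))
  p <- Pedigree(id = ids, sex = rep(c("male", "female"), n / 2))
  set.seed(77)
  d <- individuals(p)
  d$affection <- ifelse(runif(n) < ifelse(d$sex == "male", 0.25, 0.27),
                        "affected", "unaffected")
  p@data <- d
  G <- matrix(rbinom(n * 100, 2, 0.3), ncol = 100,
              dimnames = list(ids, NULL))
  scan <- associationScan(G, p)
  hits <- sum(scan$p < 0.05 & scan$testable)
  # 99.9% binomial band around the nominal 5/100
  expect_lte(hits, qbinom(0.9995, 100, 0.05))
})

test_that("cohort frequency summaries reproduce reported arithmetic", {
  ids <- paste0("i", 1:111)
  g <- setNames(c(rep(1, 25), rep(0, 86)), ids)
  sli <- ids[c(1:19, 26:55)]             # 19 carriers among 49 affected
  s <- cohortFrequencySummary(g, list(all = ids, SLI = sli,
                                      none = character(0)))
  expect_equal(s$allele_freq[s$subgroup == "all"], 25 / 222, tolerance = 1e-12)
  expect_equal(round(s$allele_freq[s$subgroup == "all"], 3), 0.113)
  expect_equal(round(s$allele_freq[s$subgroup == "SLI"], 3), 0.194)
  expect_equal(round(s$freq_het[s$subgroup == "SLI"], 3), 0.388)
  expect_equal(s$n[s$subgroup == "none"], 0L)
  expect_equal(s$allele_freq[s$subgroup == "none"], NA_real_)
  g0 <- setNames(rep(0, 10), paste0("z", 1:10))
  s0 <- cohortFrequencySummary(g0, list(all = names(g0)))
  expect_equal(s0$allele_freq, 0)
})

test_that("penetrance and phenocopy rates follow their definitions", {
  carrier <- c(rep(TRUE, 25), rep(FALSE, 86))
  affected <- c(rep(TRUE, 19), rep(FALSE, 6), rep(TRUE, 30), rep(FALSE, 56))
  s <- penetrancePhenocopySummary(carrier, affected)
  expect_equal(s$penetrance, 0.76)
  expect_equal(s$phenocopyRate, 30 / 49)
  expect_equal(round(s$phenocopyRate, 2), 0.61)
  # all affected are carriers -> no phenocopies
  s2 <- penetrancePhenocopySummary(c(TRUE, TRUE, FALSE),
                                   c(TRUE, TRUE, FALSE))
  expect_equal(s2$phenocopyRate, 0)
  s3 <- penetrancePhenocopySummary(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_true(is.na(s3$penetrance))
  expect_match(s3$flag, "no carriers", all = FALSE)
})

test_that("sex-specific prevalences recover printed child-cohort counts", {
  sex <- c(rep("male", 7), rep("female", 9),      # affected children
           rep("male", 8 + 13), rep("female", 15 + 9))
  affected <- c(rep(TRUE, 16), rep(FALSE, 45))
  prev <- prevalenceBySex(affected, sex)
  expect_equal(unname(prev["male"]), 0.25)
  expect_equal(unname(prev["female"]), 9 / 33)
  expect_equal(round(unname(prev["female"]), 2), 0.27)
})
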