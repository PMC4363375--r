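test_that("boundary founder frequencies give degenerate drops", {
  p <- twelvePed()
  r0 <- dropAlleles(p, founderFreq = 0, nReplicates = 500, seed = 1)
  expect_true(all(dropFreqs(r0) == 0))
  r1 <- dropAlleles(p, founderFreq = 1, nReplicates = 500, seed = 1)
  expect_true(all(dropFreqs(r1) == 1))
})

test_that("a heterozygous founder transmits Mendelian expectations", {
  p <- trioPed()
  r <- dropAlleles(p, carrierIds = "dad", targetIds = "kid",
                   nReplicates = 50000, seed = 11)
  f <- dropFreqs(r)
  # child allele frequency is 0 or 1/2 with equal probability
  expect_setequal(unique(f), c(0, 0.5))
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.25), 3 * se)
  expect_lt(abs(mean(f > 0) - 0.5), 3 * sqrt(0.25 / length(f)))
})

test_that("carrier ids must be founders and modes are exclusive", {
  p <- trioPed()
  expect_error(dropAlleles(p, carrierIds = "kid"), "founders")
  expect_error(dropAlleles(p), "exactly one")
  expect_error(dropAlleles(p, carrierIds = "dad", founderFreq = 0.1),
               "exactly one")
})

test_that("exact enumeration reproduces Punnett-square distributions", {
  p <- trioPed()
  e <- enumerateExact(p, carrierIds = "dad", targetIds = "kid")
  expect_equal(e$freq, c(0, 0.5))
  expect_equal(e$prob, c(0.5, 0.5))
  # both parents heterozygous: child genotype (0,1,2)/2 with (1/4,1/2,1/4)
  n <- nuclearPed(1)
  e2 <- enumerateExact(n, carrierIds = c("dad", "mum"), targetIds = "k1")
  expect_equal(e2$freq, c(0, 0.5, 1))
  expect_equal(e2$prob, c(0.25, 0.5, 0.25))
  expect_error(enumerateExact(nuclearPed(10), carrierIds = "dad"),
               "too large")
})

test_that("enumeration pmf is normalised and matches Monte-Carlo drops", {
  p <- twelvePed()
  e <- enumerateExact(p, carrierIds = c("A1", "B1"),
                      targetIds = c("K1", "K2", "K3", "K4"))
  expect_equal(sum(e$prob), 1, tolerance = 1e-12)
  mc <- dropAlleles(p, carrierIds = c("A1", "B1"),
                    targetIds = c("K1", "K2", "K3", "K4"),
                    nReplicates = 30000, seed = 5)
  obs <- table(factor(round(dropFreqs(mc), 12), levels = round(e$freq, 12)))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = e$prob))
  expect_gt(gof$p.value, 0.001)
})

test_that("gene drops are reproducible and founder-exchangeable", {
  p <- twelvePed()
  a <- dropAlleles(p, founderFreq = 0.3, nReplicates = 2000, seed = 17)
  b <- dropAlleles(p, founderFreq = 0.3, nReplicates = 2000, seed = 17)
  expect_identical(dropFreqs(a), dropFreqs(b))
  # relabelling which founders matter cannot change the distribution
  x <- dropAlleles(p, founderFreq = 0.4, nReplicates = 20000, seed = 2)
  y <- dropAlleles(p, founderFreq = 0.4, nReplicates = 20000, seed = 9)
  ks <- suppressWarnings(ks.test(dropFreqs(x), dropFreqs(y)))
  expect_gt(ks$p.value, 0.001)
})

test_that("unconditional expected frequency is preserved across the drop", {
  p <- twelvePed()
  sw <- expectedFrequencySweep(p, qValues = c(0.05, 0.2, 0.5),
                               nReplicates = 20000, seed = 23)
  se <- sw$sd / sqrt(sw$n_kept)
  expect_true(all(abs(sw$mean - sw$q) <= 3 * se))
})

test_that("conditioning on carrier founders raises descendant frequency", {
  # closed form for a trio: E[child freq | father carrier at HW freq q]
  # = (1/(2-q) + q)/2
  p <- trioPed()
  q <- 0.3
  sw <- expectedFrequencySweep(p, qValues = q, targetIds = "kid",
                               nReplicates = 200000, seed = 31,
                               conditionOn = "dad")
  expect_gt(sw$mean, q)
  se <- sw$sd / sqrt(sw$n_kept)
  expect_lt(abs(sw$mean - (1 / (2 - q) + q) / 2), 3.5 * se)
  # on the 12-member fixture, conditioning on both top founders
  sw12 <- expectedFrequencySweep(twelvePed(), qValues = 0.1,
                                 targetIds = c("K1", "K2", "K3", "K4"),
                                 nReplicates = 50000, seed = 37,
                                 conditionOn = c("A1", "B1"))
  expect_gt(sw12$mean, 0.1)
})

test_that("a founder-frequency sweep emits one summarised row per q", {
  p <- simulatePedigree(cohortSimConfig(seed = 41))
  qs <- seq(0.03, 0.09, by = 0.02)
  sw <- expectedFrequencySweep(p, qValues = qs, nReplicates = 2000, seed = 43)
  expect_equal(sw$q, qs)
  expect_true(all(c("mean", "sd", "q2.5", "q97.5") %in% names(sw)))
  expect_true(all(sw$q2.5 <= sw$mean & sw$mean <= sw$q97.5))
})
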