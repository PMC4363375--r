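test_that("heterozygote detection probability follows the binomial model", {
  expect_equal(hetDetectionProbability(10, 2), 1 - 11 / 1024)
  expect_equal(hetDetectionProbability(11, 2), 1 - 12 / 2048)
  expect_equal(hetDetectionProbability(25, 0), 1)     # certain event
  expect_equal(hetDetectionProbability(3, 5), 0)      # more reads than depth
  # nondecreasing in depth and per-read probability
  d <- 0:60
  pr <- hetDetectionProbability(d, 4)
  expect_true(all(diff(pr) >= -1e-15))
  q <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(hetDetectionProbability(20, 4, q)) >= -1e-15))
})

test_that("minimum depth for a detection confidence brackets correctly", {
  expect_equal(minDepthForConfidence(2, 0.985), 10)
  expect_equal(minDepthForConfidence(1, 0.5), 1)
  # the "99%" at depth 10 is a rounded 0.9893: exact 0.99 needs 11 reads
  expect_equal(minDepthForConfidence(2, 0.99), 11)
  # nonincreasing in per-read probability
  ds <- sapply(c(0.3, 0.4, 0.5, 0.6), function(q)
    minDepthForConfidence(2, 0.95, q))
  expect_true(all(diff(ds) <= 0))
})

test_that("quality filter applies inclusive start-site and VAF thresholds", {
  r <- makeRecords(3, depth = c(26L, 100L, 0L),
                   variant_reads = c(4L, 20L, 0L),
                   unique_start_sites = c(4L, 3L, 0L))
  out <- qualityFilter(r)
  expect_equal(out$kept$pos, r$pos[1])        # VAF 4/26 = 0.1538 >= 0.15
  expect_equal(nrow(out$removed), 2)
  expect_equal(out$removed$reason[out$removed$pos == r$pos[3]], "no coverage")
  expect_equal(out$removed$reason[out$removed$pos == r$pos[2]],
               "unique start sites")
})

test_that("consequence filter keeps deleterious classes only", {
  r <- makeRecords(3, consequence = c("missense", "canonical_splice",
                                      "synonymous"))
  out <- consequenceFilter(r)
  expect_setequal(out$kept$consequence, c("missense", "canonical_splice"))
  expect_equal(out$removed$consequence, "synonymous")
  r$consequence[1] <- NA
  expect_error(consequenceFilter(r), "consequence")
})

test_that("novelty filter matches allele-aware variant identity", {
  r <- makeRecords(2, pos = c(100L, 200L), alt = c("T", "G"))
  cat1 <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T")
  out <- noveltyFilter(r, cat1)
  expect_equal(out$kept$pos, 200L)
  expect_true(out$removed$known)
  # same position, different alt allele counts as novel
  cat2 <- data.frame(chrom = "1", pos = 200L, ref = "A", alt = "C")
  out2 <- noveltyFilter(r, cat2)
  expect_equal(nrow(out2$kept), 2)
  out3 <- noveltyFilter(r, cat1[0, ])
  expect_equal(nrow(out3$kept), 2)            # empty catalogue keeps all
})

test_that("sharing filter keeps variants in at least minShared samples", {
  r <- rbind(makeRecords(1, sample_id = "A", pos = 100L),
             makeRecords(1, sample_id = "B", pos = 100L),
             makeRecords(1, sample_id = "C", pos = 100L),
             makeRecords(1, sample_id = "A", pos = 200L),
             makeRecords(1, sample_id = "B", pos = 200L))
  out <- sharingFilter(r, minShared = 3, nSamples = 5)
  expect_equal(out$pos, 100L)
  expect_equal(out$n_carriers, 3L)
  expect_equal(out$carriers, "A,B,C")
  expect_error(sharingFilter(r, minShared = 6, nSamples = 5), "exceeds")
})

test_that("linkage-region annotation uses 1-based inclusive intervals", {
  regions <- data.frame(chrom = c("2", "6"), start = c(1000L, 500L),
                        end = c(2000L, 600L))
  r <- makeRecords(4, chrom = c("4", "2", "2", "2"),
                   pos = c(47907320L, 1000L, 2000L, 2001L))
  ann <- annotateLinkageRegions(r, regions)
  expect_equal(ann$in_linkage_region, c(FALSE, TRUE, TRUE, FALSE))
  ann0 <- annotateLinkageRegions(r, regions[0, ])
  expect_false(any(ann0$in_linkage_region))
})

test_that("BED regions convert to 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t999\t2000\tlinked", f)
  reg <- readRegionsBed(f)
  expect_equal(reg$start, 1000L)
  expect_equal(reg$end, 2000L)
})

test_that("the cascade recovers exactly the planted variants", {
  sim <- simulateExomeCohort(exomeSimConfig(seed = 21))
  res <- filterCascade(sim$records, known = sim$known)
  expect_setequal(survivors(res$report), sim$truth$key[sim$truth$planted])
  expect_equal(nrow(res$shared), 9)
  st <- stageCounts(res$report)
  expect_true(all(st$kept + st$removed == st$input))
  expect_equal(st$input[-1], st$kept[-nrow(st)])
})

test_that("an all-known background leaves only planted variants after novelty", {
  sim <- simulateExomeCohort(exomeSimConfig(nBackgroundVariants = 300,
                                            knownFraction = 1, seed = 3))
  res <- filterCascade(sim$records, known = sim$known)
  st <- stageCounts(res$report)
  novKept <- st$kept[st$stage == "novelty"]
  keys <- paste(sim$records$chrom, sim$records$pos, sim$records$ref,
                sim$records$alt, sep = ":")
  expect_equal(novKept, sum(keys %in% sim$truth$key[sim$truth$planted]))
  expect_setequal(survivors(res$report), sim$truth$key[sim$truth$planted])
})

test_that("per-record filters commute", {
  sim <- simulateExomeCohort(exomeSimConfig(nBackgroundVariants = 400,
                                            seed = 8))
  r <- sim$records
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, x$sample_id)
  o1 <- noveltyFilter(consequenceFilter(qualityFilter(r)$kept)$kept,
                      sim$known)$kept
  o2 <- qualityFilter(consequenceFilter(noveltyFilter(r, sim$known)$kept)$kept)$kept
  o3 <- consequenceFilter(noveltyFilter(qualityFilter(r)$kept,
                                        sim$known)$kept)$kept
  expect_setequal(key(o2), key(o1))
  expect_setequal(key(o3), key(o1))
})
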