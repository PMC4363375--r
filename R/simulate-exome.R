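#' Configuration for the exome fixture simulator
#'
#' Parameters of [simulateExomeCohort()]. Defaults emulate a small
#' exome screen: five affected samples, a few thousand background
#' variants, nine planted novel deleterious variants shared by at least
#' three samples, and read depths drawn from a negative binomial with
#' mean 56 (at which ~98% of sites reach 10-fold coverage).
#'
#' @param nSamples number of sequenced samples (default 5).
#' @param nBackgroundVariants background variants that must *not* survive
#'   the cascade (default 2000).
#' @param nPlantedShared planted variants that must survive (default 9).
#' @param minSharedPlanted minimum number of samples sharing each planted
#'   variant (default 3).
#' @param consequenceMix named proportions over consequence classes used
#'   for background variants (must sum to 1).
#' @param knownFraction fraction of background variants placed in the
#'   known-variant catalogue (default 0.5).
#' @param depthMean,depthDispersion negative-binomial read-depth model
#'   (mean 56, size 3).
#' @param seed integer seed (optional).
#' @return list of class `"ExomeSimConfig"`.
#' @export
exomeSimConfig <- function(nSamples = 5, nBackgroundVariants = 2000,
                           nPlantedShared = 9, minSharedPlanted = 3,
                           consequenceMix = c(missense = 0.25, nonsense = 0.02,
                                              frameshift = 0.02,
                                              canonical_splice = 0.03,
                                              synonymous = 0.25,
                                              intronic = 0.28,
                                              nongenic = 0.10, utr = 0.05),
                           knownFraction = 0.5,
                           depthMean = 56, depthDispersion = 3, seed = NULL) {
  if (abs(sum(consequenceMix) - 1) > 1e-9)
    stop("consequenceMix proportions must sum to 1")
  if (minSharedPlanted > nSamples)
    stop("minSharedPlanted exceeds nSamples")
  structure(list(nSamples = nSamples,
                 nBackgroundVariants = nBackgroundVariants,
                 nPlantedShared = nPlantedShared,
                 minSharedPlanted = minSharedPlanted,
                 consequenceMix = consequenceMix,
                 knownFraction = knownFraction,
                 depthMean = depthMean, depthDispersion = depthDispersion,
                 seed = seed),
            class = "ExomeSimConfig")
}

#' Simulate read depths
#'
#' Negative-binomial per-site read depths (mean `depthMean`, size
#' `depthDispersion`) — the depth model behind the exome fixture
#' generator.
#'
#' @param n number of sites.
#' @param depthMean mean depth (default 56).
#' @param depthDispersion negative-binomial size parameter (default 3).
#' @param seed integer seed (optional).
#' @return integer vector of depths.
#' @export
simulateReadDepth <- function(n, depthMean = 56, depthDispersion = 3,
                              seed = NULL) {
  withSeed(seed, stats::rnbinom(n, size = depthDispersion, mu = depthMean))
}

# Read evidence guaranteed to pass the quality filter (>= 4 unique start
# sites, VAF >= 0.15).
.passingEvidence <- function(n, cfg) {
  depth <- pmax(simulateReadDepth(n, cfg$depthMean, cfg$depthDispersion), 12L)
  vr <- stats::rbinom(n, depth, 0.5)
  need <- pmax(4L, as.integer(ceiling(0.15 * depth)))
  vr <- pmax(vr, need)
  uss <- pmin(vr, pmax(4L, as.integer(round(0.8 * vr))))
  data.frame(depth = depth, variant_reads = vr, unique_start_sites = uss)
}

# Read evidence guaranteed to fail the quality filter.
.failingEvidence <- function(n, cfg) {
  mode <- sample(c("uss", "vaf", "nocov"), n, replace = TRUE,
                 prob = c(0.5, 0.4, 0.1))
  depth <- pmax(simulateReadDepth(n, cfg$depthMean, cfg$depthDispersion), 28L)
  vr <- integer(n); uss <- integer(n)
  isU <- mode == "uss"
  vr[isU] <- pmax(stats::rbinom(sum(isU), depth[isU], 0.5),
                  as.integer(ceiling(0.15 * depth[isU])))
  uss[isU] <- sample(0:3, sum(isU), replace = TRUE)
  vr[isU] <- pmax(vr[isU], uss[isU])
  isV <- mode == "vaf"
  vr[isV] <- pmax(0L, as.integer(floor(0.149 * depth[isV])))
  uss[isV] <- pmin(vr[isV], 4L + stats::rbinom(sum(isV), 3, 0.5))
  isN <- mode == "nocov"
  depth[isN] <- 0L; vr[isN] <- 0L; uss[isN] <- 0L
  data.frame(depth = depth, variant_reads = vr, unique_start_sites = uss)
}

.randomAlleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(ref = ref, alt = unname(alt))
}

#' Simulate a per-sample exome variant fixture with known truth
#'
#' Generates per-sample variant record tables for testing the filter
#' cascade. *Planted* variants are novel, deleterious (nonsynonymous or
#' canonical splice), shared by at least `minSharedPlanted` samples and
#' carry passing read evidence, so they must survive the cascade.
#' *Background* variants are each constructed with at least one
#' disqualifying property — present in the known catalogue, a
#' non-deleterious consequence, shared by too few samples, or failing
#' read evidence — so that the cascade's surviving set is exactly the
#' planted set, providing exact truth labels.
#'
#' @param cfg an [exomeSimConfig()].
#' @return list with `records` (variant record `data.frame` across all
#'   samples), `known` (known-variant catalogue `data.frame`), `truth`
#'   (`data.frame` of variant keys with `planted` / `should_survive`
#'   flags) and `cfg`.
#' @export
simulateExomeCohort <- function(cfg = exomeSimConfig()) {
  withSeed(cfg$seed, {
    ns <- cfg$nSamples
    samples <- sprintf("S%02d", seq_len(ns))
    nB <- cfg$nBackgroundVariants
    nP <- cfg$nPlantedShared
    nV <- nB + nP
    pos <- sample.int(2e8, nV)
    chrom <- as.character(sample(1:22, nV, replace = TRUE))
    al <- .randomAlleles(nV)
    gene <- sprintf("GENE%05d", sample.int(20000, nV, replace = TRUE))

    # background variants: assign one disqualifying mechanism each
    doom <- sample(c("known", "consequence", "sharing", "evidence"), nB,
                   replace = TRUE,
                   prob = c(cfg$knownFraction,
                            (1 - cfg$knownFraction) / 3,
                            (1 - cfg$knownFraction) / 3,
                            (1 - cfg$knownFraction) / 3))
    mix <- cfg$consequenceMix
    badMix <- mix[names(mix) %in% c("synonymous", "intronic", "nongenic", "utr")]
    consequence <- character(nV)
    bi <- seq_len(nB)
    consequence[bi] <- sample(names(mix), nB, replace = TRUE, prob = mix)
    cdoom <- bi[doom == "consequence"]
    consequence[cdoom] <- sample(names(badMix), length(cdoom), replace = TRUE,
                                 prob = badMix)
    # deleterious background variants must fail some other way: variants
    # doomed by "known"/"sharing"/"evidence" keep their drawn consequence
    pi <- nB + seq_len(nP)
    consequence[pi] <- sample(c("missense", "nonsense", "canonical_splice",
                                "frameshift"), nP, replace = TRUE,
                              prob = c(0.7, 0.1, 0.15, 0.05))

    nCarriers <- integer(nV)
    nCarriers[bi] <- sample(seq_len(ns), nB, replace = TRUE)
    sdoom <- doom == "sharing"
    nCarriers[bi[sdoom]] <- sample(seq_len(max(1L, cfg$minSharedPlanted - 1L)),
                                   sum(sdoom), replace = TRUE)
    nCarriers[pi] <- sample(cfg$minSharedPlanted:ns, nP, replace = TRUE)

    rows <- lapply(seq_len(nV), function(v) {
      carr <- sample(samples, nCarriers[v])
      ev <- if (v <= nB && doom[v] == "evidence")
              .failingEvidence(length(carr), cfg)
            else .passingEvidence(length(carr), cfg)
      data.frame(sample_id = carr, chrom = chrom[v], pos = pos[v],
                 ref = al$ref[v], alt = al$alt[v], gene = gene[v],
                 consequence = consequence[v],
                 known = v <= nB && doom[v] == "known",
                 depth = ev$depth, variant_reads = ev$variant_reads,
                 unique_start_sites = ev$unique_start_sites)
    })
    records <- do.call(rbind, rows)
    known <- data.frame(chrom = chrom[bi], pos = pos[bi], ref = al$ref[bi],
                        alt = al$alt[bi])[doom == "known", , drop = FALSE]
    rownames(known) <- NULL
    key <- paste(chrom, pos, al$ref, al$alt, sep = ":")
    truth <- data.frame(key = key,
                        planted = seq_len(nV) > nB,
                        should_survive = seq_len(nV) > nB)
    list(records = records, known = known, truth = truth, cfg = cfg)
  })
}
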