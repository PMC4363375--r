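#' Calibrate the non-carrier baseline risk from a target prevalence
#'
#' Given a target population prevalence `k`, a carrier fraction `c` and a
#' carrier penetrance `f`, the baseline (phenocopy) risk that makes the
#' overall prevalence come out at `k` is `(k - c f) / (1 - c)`.
#'
#' @param prevalence target overall prevalence.
#' @param carrierFreq fraction of individuals carrying the risk variant
#'   (default 0.125).
#' @param penetrance carrier penetrance (default 0.76).
#' @return baseline affection probability for non-carriers.
#' @examples
#' calibrateBaselineRisk(0.25)   # 0.177
#' calibrateBaselineRisk(0.27)   # 0.2
#' @export
calibrateBaselineRisk <- function(prevalence, carrierFreq = 0.125,
                                  penetrance = 0.76) {
  b <- (prevalence - carrierFreq * penetrance) / (1 - carrierFreq)
  if (any(b < 0) || any(b > 1))
    stop("parameters imply a baseline risk outside [0, 1]")
  b
}

#' Configuration for the cohort simulator
#'
#' Bundles the demographic and phenotype-model parameters of
#' [simulatePedigree()], [simulateGenotypes()] and
#' [simulatePhenotypes()]. The defaults emulate an island founder
#' population: about eight founding couples expanded over five
#' generations to roughly three hundred individuals, a consanguineous
#' mate-choice probability of 0.14, two carrier founders introducing the
#' risk variant, carrier penetrance 0.76, and non-carrier baseline risks
#' calibrated so the overall prevalence is about 0.25 in males and 0.27
#' in females.
#'
#' @param nFoundingCouples number of generation-0 couples (default 8).
#' @param generations total number of generations, >= 2 (default 5).
#' @param offspringMean Poisson mean number of children per couple
#'   (default 2.2).
#' @param marriageProb probability that a non-final-generation child
#'   forms a couple (default 0.85).
#' @param targetSize if non-`NULL`, condition the genealogy on a final
#'   size within `sizeTolerance` of this census count by rejection
#'   (default 288); set `NULL` for unconditioned branching.
#' @param sizeTolerance relative half-width of the accepted size window
#'   (default 0.3).
#' @param consanguinityProb probability that a marrying child takes a
#'   within-pedigree mate rather than a married-in founder (default 0.14).
#' @param carrierFounders number of founders set heterozygous for the
#'   risk variant (default 2), or a character vector of founder ids.
#' @param penetranceCarrier carrier penetrance (default 0.76).
#' @param kMale,kFemale target overall prevalences (defaults 0.25, 0.27).
#' @param baselineRiskMale,baselineRiskFemale non-carrier affection
#'   probabilities; by default calibrated from the prevalences via
#'   [calibrateBaselineRisk()].
#' @param missingPhenotypeProb,missingGenotypeProb per-individual masking
#'   probabilities (defaults 0).
#' @param seed integer seed (optional).
#' @return list of class `"CohortSimConfig"`.
#' @export
cohortSimConfig <- function(nFoundingCouples = 8, generations = 5,
                            offspringMean = 2.2, marriageProb = 0.85,
                            targetSize = 288, sizeTolerance = 0.3,
                            consanguinityProb = 0.14, carrierFounders = 2,
                            penetranceCarrier = 0.76,
                            kMale = 0.25, kFemale = 0.27,
                            baselineRiskMale = calibrateBaselineRisk(kMale),
                            baselineRiskFemale = calibrateBaselineRisk(kFemale),
                            missingPhenotypeProb = 0,
                            missingGenotypeProb = 0, seed = NULL) {
  if (generations < 2) stop("generations must be >= 2")
  .assertProb(c(marriageProb, consanguinityProb, penetranceCarrier,
                baselineRiskMale, baselineRiskFemale,
                missingPhenotypeProb, missingGenotypeProb), "probabilities")
  structure(list(nFoundingCouples = nFoundingCouples,
                 generations = generations, offspringMean = offspringMean,
                 marriageProb = marriageProb, targetSize = targetSize,
                 sizeTolerance = sizeTolerance,
                 consanguinityProb = consanguinityProb,
                 carrierFounders = carrierFounders,
                 penetranceCarrier = penetranceCarrier,
                 kMale = kMale, kFemale = kFemale,
                 baselineRiskMale = baselineRiskMale,
                 baselineRiskFemale = baselineRiskFemale,
                 missingPhenotypeProb = missingPhenotypeProb,
                 missingGenotypeProb = missingGenotypeProb,
                 seed = seed),
            class = "CohortSimConfig")
}

# Number of (strict) descendants of each individual, named by id.
.descendantCounts <- function(ped) {
  d <- ped@data
  ord <- rev(.topoOrder(d))          # descendants before ancestors
  desc <- stats::setNames(vector("list", nrow(d)), d$id)
  for (i in ord) {
    kids <- d$id[!is.na(d$father) & (d$father == d$id[i] | d$mother == d$id[i])]
    desc[[d$id[i]]] <- unique(c(kids, unlist(desc[kids])))
  }
  vapply(desc, length, 0L)
}

# One attempt at growing a pedigree; returns NULL on extinction.
.growPedigree <- function(cfg) {
  id <- character(0); father <- character(0); mother <- character(0)
  sex <- character(0)
  addInd <- function(i, f, m, s) {
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s)
  }
  couples <- list()
  for (k in seq_len(cfg$nFoundingCouples)) {
    h <- sprintf("G0M%02d", k); w <- sprintf("G0F%02d", k)
    addInd(h, NA, NA, "male"); addInd(w, NA, NA, "female")
    couples[[k]] <- c(h, w)
  }
  for (g in seq_len(cfg$generations - 1L)) {
    kids <- character(0); kidSex <- character(0)
    ck <- 0L
    for (cp in couples) {
      nk <- stats::rpois(1L, cfg$offspringMean)
      for (j in seq_len(nk)) {
        ck <- ck + 1L
        s <- if (stats::runif(1) < 0.5) "male" else "female"
        kid <- sprintf("G%dI%03d", g, ck)
        addInd(kid, cp[1L], cp[2L], s)
        kids <- c(kids, kid); kidSex <- c(kidSex, s)
      }
    }
    if (!length(kids)) return(NULL)
    if (g == cfg$generations - 1L) break
    couples <- list()
    married <- character(0)
    sibsOf <- stats::setNames(paste(father[match(kids, id)],
                                    mother[match(kids, id)]), kids)
    mk <- 0L
    for (i in seq_along(kids)) {
      kid <- kids[i]
      if (kid %in% married) next
      if (stats::runif(1) >= cfg$marriageProb) next
      mate <- NULL
      if (stats::runif(1) < cfg$consanguinityProb) {
        # within-pedigree mate: same generation, opposite sex, unmarried,
        # not a full sibling
        cand <- kids[kidSex != kidSex[i] & !(kids %in% married) &
                     sibsOf != sibsOf[kid]]
        if (length(cand)) mate <- cand[sample.int(length(cand), 1L)]
      }
      if (is.null(mate)) {       # married-in founder
        mk <- mk + 1L
        ms <- if (kidSex[i] == "male") "female" else "male"
        mate <- sprintf("G%dS%03d", g, mk)
        addInd(mate, NA, NA, ms)
      } else married <- c(married, mate)
      married <- c(married, kid)
      cpl <- if (kidSex[i] == "male") c(kid, mate) else c(mate, kid)
      if (sex[match(cpl[1L], id)] != "male") cpl <- rev(cpl)
      couples[[length(couples) + 1L]] <- cpl
    }
    if (!length(couples)) return(NULL)
  }
  Pedigree(id = id, father = father, mother = mother, sex = sex,
           familyId = "SIM1")
}

#' Simulate a multi-generation founder pedigree
#'
#' Grows a pedigree generation by generation: founding couples produce
#' Poisson numbers of children; non-final-generation children marry with
#' probability `marriageProb`, choosing a within-pedigree (non-sibling,
#' same-generation) mate with probability `consanguinityProb` and a
#' married-in founder otherwise. Extinct attempts (a generation with no
#' children or no couples) are retried. When `cfg$targetSize` is set, the
#' genealogy is additionally conditioned by rejection on a final size
#' within `sizeTolerance` of the target — emulating a population whose
#' census count is known while keeping Mendelian/branching structure
#' intact.
#'
#' @param cfg a [cohortSimConfig()].
#' @param maxTries retry bound for extinct or out-of-window attempts
#'   (default 200).
#' @return a [Pedigree-class] (deterministic for a fixed `cfg$seed`).
#' @export
simulatePedigree <- function(cfg = cohortSimConfig(), maxTries = 200) {
  withSeed(cfg$seed, {
    for (t in seq_len(maxTries)) {
      p <- .growPedigree(cfg)
      if (is.null(p)) next
      if (!is.null(cfg$targetSize)) {
        n <- nrow(p@data)
        lo <- cfg$targetSize * (1 - cfg$sizeTolerance)
        hi <- cfg$targetSize * (1 + cfg$sizeTolerance)
        if (n < lo || n > hi) next
      }
      return(p)
    }
    stop("no acceptable pedigree in ", maxTries,
         " attempts (extinct or outside the target size window)")
  })
}

#' Simulate genotypes by dropping a founder variant
#'
#' Drops a single biallelic variant through the pedigree (one gene-drop
#' replicate) and returns per-individual allele counts. Founder
#' assignment is as in [dropAlleles()]: designated heterozygous carrier
#' founders, or Hardy-Weinberg founder alleles at frequency
#' `founderFreq`.
#'
#' @param ped a [Pedigree-class].
#' @param carrierIds,founderFreq founder assignment (exactly one).
#' @param seed integer seed (optional).
#' @return named integer vector of allele counts (0, 1, 2) over all
#'   individuals.
#' @export
simulateGenotypes <- function(ped, carrierIds = NULL, founderFreq = NULL,
                              seed = NULL) {
  if (is.null(carrierIds) == is.null(founderFreq))
    stop("supply exactly one of carrierIds or founderFreq")
  if (!is.null(carrierIds)) {
    nonF <- setdiff(carrierIds, founders(ped))
    if (length(nonF))
      stop("carrierIds must be founders; not founders: ",
           paste(nonF, collapse = ", "))
  }
  withSeed(seed, .dropGenotypesOnce(ped, carrierIds, founderFreq))
}

.dropGenotypesOnce <- function(ped, carrierIds, founderFreq) {
  d <- ped@data
  ord <- .topoOrder(d)
  ids <- d$id[ord]
  fi <- match(d$father[ord], ids)
  mi <- match(d$mother[ord], ids)
  n <- length(ids)
  a1 <- integer(n); a2 <- integer(n)
  fixed <- !is.null(carrierIds)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      if (fixed) {
        if (ids[i] %in% carrierIds) a1[i] <- 1L
      } else {
        a1[i] <- stats::rbinom(1L, 1L, founderFreq)
        a2[i] <- stats::rbinom(1L, 1L, founderFreq)
      }
    } else {
      a1[i] <- if (stats::runif(1) < 0.5) a1[fi[i]] else a2[fi[i]]
      a2[i] <- if (stats::runif(1) < 0.5) a1[mi[i]] else a2[mi[i]]
    }
  }
  g <- a1 + a2
  stats::setNames(g[match(d$id, ids)], d$id)
}

#' Simulate affection statuses under incomplete penetrance
#'
#' Two-penetrance Bernoulli phenotype model: carriers of the risk variant
#' are affected with probability `penetranceCarrier`; non-carriers with
#' the sex-specific baseline risk (phenocopies). Statuses are then masked
#' to `"unknown"` with probability `missingPhenotypeProb`.
#'
#' @param ped a [Pedigree-class].
#' @param genotypes named allele-count vector (see
#'   [simulateGenotypes()]).
#' @param cfg a [cohortSimConfig()] supplying the penetrance, baselines
#'   and masking probability.
#' @param seed integer seed (optional; defaults to none so the caller's
#'   RNG stream is used).
#' @return named character vector of affection statuses.
#' @export
simulatePhenotypes <- function(ped, genotypes, cfg = cohortSimConfig(),
                               seed = NULL) {
  d <- ped@data
  g <- genotypes[d$id]
  withSeed(seed, {
    base <- ifelse(d$sex == "male", cfg$baselineRiskMale,
            ifelse(d$sex == "female", cfg$baselineRiskFemale,
                   (cfg$baselineRiskMale + cfg$baselineRiskFemale) / 2))
    pAff <- ifelse(!is.na(g) & g >= 1, cfg$penetranceCarrier, base)
    aff <- ifelse(stats::runif(nrow(d)) < pAff, "affected", "unaffected")
    mask <- stats::runif(nrow(d)) < cfg$missingPhenotypeProb
    aff[mask] <- "unknown"
    stats::setNames(aff, d$id)
  })
}

#' Simulate a complete cohort: pedigree, genotypes and phenotypes
#'
#' Convenience wrapper over [simulatePedigree()], [simulateGenotypes()]
#' and [simulatePhenotypes()]: grows a pedigree, designates carrier
#' founders (by default the requested number of male founders of the
#' founding generation), drops the risk variant, assigns phenotypes, and
#' applies genotype masking.
#'
#' @param cfg a [cohortSimConfig()].
#' @return list with `ped` (a [Pedigree-class] with affection and
#'   genotyped flags set), `genotypes` (named allele counts with `NA`
#'   where masked), `carrierFounders` and `cfg`.
#' @export
simulateCohort <- function(cfg = cohortSimConfig()) {
  withSeed(cfg$seed, {
    cfg2 <- cfg; cfg2$seed <- NULL
    ped <- simulatePedigree(cfg2)
    f <- founders(ped)
    carriers <- if (is.character(cfg$carrierFounders)) cfg$carrierFounders
                else {
                  # the founders heading the largest lineages, mirroring a
                  # founder pair to whom most of the population traces back
                  fm <- f[ped@data$sex[match(f, ped@data$id)] == "male"]
                  nd <- .descendantCounts(ped)[fm]
                  utils::head(fm[order(-nd)], cfg$carrierFounders)
                }
    g <- .dropGenotypesOnce(ped, carrierIds = carriers, founderFreq = NULL)
    aff <- simulatePhenotypes(ped, g, cfg2)
    gObs <- g
    gObs[stats::runif(length(g)) < cfg$missingGenotypeProb] <- NA
    d <- ped@data
    d$affection <- unname(aff[d$id])
    d$genotyped <- !is.na(gObs[d$id])
    ped@data <- d
    list(ped = ped, genotypes = gObs, carrierFounders = carriers, cfg = cfg)
  })
}
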