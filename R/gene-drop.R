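# Core allele-dropping engine, vectorised across replicates.
# Returns a list with per-replicate target-set allele frequency and, when
# conditionIds is given, a logical matrix of carrier status for those ids.
.geneDrop <- function(ped, nReplicates, carrierIds = NULL, founderFreq = NULL,
                      targetIds, conditionIds = NULL) {
  d <- ped@data
  ord <- .topoOrder(d)
  ids <- d$id[ord]
  fi <- match(d$father[ord], ids)
  mi <- match(d$mother[ord], ids)
  n <- length(ids)
  R <- nReplicates
  a1 <- matrix(0L, R, n)
  a2 <- matrix(0L, R, n)
  fixed <- !is.null(carrierIds)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      if (fixed) {
        if (ids[i] %in% carrierIds) a1[, i] <- 1L     # heterozygous carrier
      } else {
        a1[, i] <- stats::rbinom(R, 1L, founderFreq)
        a2[, i] <- stats::rbinom(R, 1L, founderFreq)
      }
    } else {
      pickF <- stats::rbinom(R, 1L, 0.5) == 1L
      pickM <- stats::rbinom(R, 1L, 0.5) == 1L
      a1[, i] <- ifelse(pickF, a1[, fi[i]], a2[, fi[i]])
      a2[, i] <- ifelse(pickM, a1[, mi[i]], a2[, mi[i]])
    }
  }
  ti <- match(targetIds, ids)
  freqs <- rowMeans((a1[, ti, drop = FALSE] + a2[, ti, drop = FALSE]) / 2)
  out <- list(freqs = freqs)
  if (!is.null(conditionIds)) {
    ci <- match(conditionIds, ids)
    out$carrier <- (a1[, ci, drop = FALSE] + a2[, ci, drop = FALSE]) >= 1L
  }
  out
}

.leafIds <- function(ped) {
  d <- ped@data
  d$id[!(d$id %in% c(d$father, d$mother))]
}

#' Gene-drop (allele-dropping) simulation through a pedigree
#'
#' Simulates Mendelian transmission of a biallelic variant from the
#' founders down the pedigree and records, per replicate, the
#' variant-allele frequency in a target set of individuals. Founder
#' genotypes are assigned either in *fixed-carrier* mode (the designated
#' founders are heterozygous, everyone else homozygous reference — the
#' scenario where specific founders are inferred to have introduced the
#' variant) or in *random-frequency* mode (each founder allele is the
#' variant independently with probability `founderFreq`, i.e.
#' Hardy-Weinberg in the founder pool). Each non-founder inherits one
#' uniformly chosen allele from each parent.
#'
#' @param ped a [Pedigree-class].
#' @param carrierIds founder ids set heterozygous (fixed-carrier mode);
#'   mutually exclusive with `founderFreq`.
#' @param founderFreq founder-population allele frequency
#'   (random-frequency mode).
#' @param targetIds individuals whose allele frequency is recorded;
#'   default: all individuals without descendants (the "current"
#'   generation).
#' @param nReplicates number of Monte-Carlo replicates (default 10000).
#' @param seed integer seed for reproducibility (optional).
#' @return A [GeneDropResult-class].
#' @examples
#' trio <- Pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"), sex = c("male", "female", "unknown"))
#' dropAlleles(trio, carrierIds = "f", nReplicates = 1000, seed = 1)
#' @export
dropAlleles <- function(ped, carrierIds = NULL, founderFreq = NULL,
                        targetIds = NULL, nReplicates = 10000, seed = NULL) {
  nReplicates <- .assertCount(nReplicates, "nReplicates", min = 1)
  if (is.null(carrierIds) == is.null(founderFreq))
    stop("supply exactly one of carrierIds (fixed mode) or founderFreq (random mode)")
  if (!is.null(founderFreq)) .assertProb(founderFreq, "founderFreq")
  if (!is.null(carrierIds)) {
    if (!length(carrierIds)) stop("carrierIds must be non-empty in fixed mode")
    nonF <- setdiff(carrierIds, founders(ped))
    if (length(nonF))
      stop("carrierIds must be founders; not founders: ",
           paste(nonF, collapse = ", "))
  }
  if (is.null(targetIds)) targetIds <- .leafIds(ped)
  miss <- setdiff(targetIds, ped@data$id)
  if (length(miss)) stop("target ids not in pedigree: ", paste(miss, collapse = ", "))
  res <- withSeed(seed, .geneDrop(ped, nReplicates, carrierIds, founderFreq,
                                  targetIds))
  new("GeneDropResult", targetIds = as.character(targetIds),
      freqs = res$freqs,
      mode = if (is.null(founderFreq)) "fixed_carriers" else "random_frequency",
      nReplicates = nReplicates,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname GeneDropResult-accessors
#' @export
setMethod("dropFreqs", "GeneDropResult", function(x) x@freqs)

#' GeneDropResult accessors and summary
#'
#' `dropFreqs()` returns the per-replicate target-set allele frequencies;
#' `summary()` their mean, standard deviation and 2.5% / 97.5% quantiles.
#'
#' @param x,object a [GeneDropResult-class].
#' @param ... unused.
#' @name GeneDropResult-accessors
NULL

#' @rdname GeneDropResult-accessors
#' @export
setMethod("summary", "GeneDropResult", function(object, ...) {
  f <- object@freqs
  c(mean = mean(f), sd = stats::sd(f),
    q2.5 = unname(stats::quantile(f, 0.025)),
    q97.5 = unname(stats::quantile(f, 0.975)))
})

setMethod("show", "GeneDropResult", function(object) {
  s <- summary(object)
  cat("GeneDropResult (", object@mode, "): ", object@nReplicates,
      " replicates over ", length(object@targetIds), " target individuals\n",
      sep = "")
  cat(sprintf("  freq mean %.4f, sd %.4f, 95%% interval [%.4f, %.4f]\n",
              s["mean"], s["sd"], s["q2.5"], s["q97.5"]))
})

#' Predicted present-day frequency across a grid of founder frequencies
#'
#' Runs the random-frequency gene drop for each founder allele frequency
#' `q` and summarises the target-set frequency distribution, optionally
#' conditioning on designated individuals being carriers (the scenario
#' where specific founders are known to have carried the variant).
#' Unconditionally, Mendelian transmission preserves the expectation, so
#' the mean present-day frequency equals `q`; conditioning on carrier
#' founders raises it among their descendants.
#'
#' @param ped a [Pedigree-class].
#' @param qValues numeric vector of founder allele frequencies.
#' @param targetIds target individuals (default: leaves, see
#'   [dropAlleles()]).
#' @param nReplicates replicates per `q` (default 100000).
#' @param seed integer seed (optional).
#' @param conditionOn optional ids; replicates where any of them is not a
#'   carrier are discarded before summarising.
#' @return `data.frame` with one row per `q`: `q`, `n_kept`, `mean`,
#'   `sd`, `q2.5`, `q97.5`.
#' @export
expectedFrequencySweep <- function(ped, qValues, targetIds = NULL,
                                   nReplicates = 100000, seed = NULL,
                                   conditionOn = NULL) {
  if (!length(qValues)) stop("qValues must be non-empty")
  if (is.null(targetIds)) targetIds <- .leafIds(ped)
  res <- withSeed(seed, lapply(qValues, function(q) {
    r <- .geneDrop(ped, nReplicates, founderFreq = q, targetIds = targetIds,
                   conditionIds = conditionOn)
    f <- r$freqs
    if (!is.null(conditionOn)) f <- f[rowSums(r$carrier) == length(conditionOn)]
    data.frame(q = q, n_kept = length(f),
               mean = if (length(f)) mean(f) else NA_real_,
               sd = if (length(f) > 1) stats::sd(f) else NA_real_,
               q2.5 = if (length(f)) unname(stats::quantile(f, 0.025)) else NA_real_,
               q97.5 = if (length(f)) unname(stats::quantile(f, 0.975)) else NA_real_)
  }))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exact distribution of the target-set allele frequency
#'
#' Exhaustively enumerates all Mendelian transmission patterns (two per
#' non-founder) — and, in random-frequency mode, all ordered founder
#' allele configurations weighted by Hardy-Weinberg — to produce the
#' exact probability mass function of the variant-allele frequency in the
#' target set. Feasible only for small pedigrees; used as the testing
#' oracle for [dropAlleles()].
#'
#' @param ped a [Pedigree-class] with at most 8 non-founders (16 meioses;
#'   in random mode total enumerated bits are capped at 18).
#' @param carrierIds,founderFreq founder assignment, as in
#'   [dropAlleles()].
#' @param targetIds target individuals (default: leaves).
#' @return `data.frame` with columns `freq` and `prob` (summing to 1).
#' @examples
#' trio <- Pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"), sex = c("male", "female", "unknown"))
#' enumerateExact(trio, carrierIds = "f", targetIds = "c")
#' @export
enumerateExact <- function(ped, carrierIds = NULL, founderFreq = NULL,
                           targetIds = NULL) {
  if (is.null(carrierIds) == is.null(founderFreq))
    stop("supply exactly one of carrierIds or founderFreq")
  if (!is.null(carrierIds)) {
    nonF <- setdiff(carrierIds, founders(ped))
    if (length(nonF))
      stop("carrierIds must be founders; not founders: ",
           paste(nonF, collapse = ", "))
  }
  if (is.null(targetIds)) targetIds <- .leafIds(ped)
  d <- ped@data
  ord <- .topoOrder(d)
  ids <- d$id[ord]
  fi <- match(d$father[ord], ids)
  mi <- match(d$mother[ord], ids)
  nf <- sum(!is.na(fi))
  fixed <- !is.null(carrierIds)
  founderBits <- if (fixed) 0L else 2L * sum(is.na(fi))
  B <- 2L * nf + founderBits
  if (2L * nf > 16L || B > 18L)
    stop("pedigree too large for exact enumeration (", 2L * nf,
         " meioses, ", B, " total bits)")
  grid <- as.matrix(expand.grid(rep(list(0:1), B)))
  R <- nrow(grid)
  n <- length(ids)
  a1 <- matrix(0L, R, n)
  a2 <- matrix(0L, R, n)
  w <- rep(1 / 2^(2 * nf), R)       # uniform transmission weight
  bit <- 0L
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      if (fixed) {
        if (ids[i] %in% carrierIds) a1[, i] <- 1L
      } else {
        z1 <- grid[, bit + 1L]; z2 <- grid[, bit + 2L]; bit <- bit + 2L
        a1[, i] <- z1
        a2[, i] <- z2
        w <- w * ifelse(z1 == 1L, founderFreq, 1 - founderFreq) *
                 ifelse(z2 == 1L, founderFreq, 1 - founderFreq)
      }
    } else {
      z1 <- grid[, bit + 1L]; z2 <- grid[, bit + 2L]; bit <- bit + 2L
      a1[, i] <- ifelse(z1 == 1L, a1[, fi[i]], a2[, fi[i]])
      a2[, i] <- ifelse(z2 == 1L, a1[, mi[i]], a2[, mi[i]])
    }
  }
  ti <- match(targetIds, ids)
  freqs <- rowMeans((a1[, ti, drop = FALSE] + a2[, ti, drop = FALSE]) / 2)
  pm <- tapply(w, factor(round(freqs, 12)), sum)
  data.frame(freq = as.numeric(names(pm)), prob = as.numeric(pm))
}
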