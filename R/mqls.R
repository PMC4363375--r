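#' Prevalence-transformed phenotype weights
#'
#' The quasi-likelihood score test distinguishes unaffected controls from
#' controls of unknown phenotype by transforming affection status into a
#' weight `T`: affected individuals get 1, unaffected individuals get
#' `-k / (1 - k)` with `k` the sex-specific population prevalence, and
#' individuals of unknown phenotype get 0. Individuals of unknown sex use
#' the mean of the male and female prevalences.
#'
#' @param ped a [Pedigree-class] with affection statuses.
#' @param kMale,kFemale sex-specific prevalences, strictly in (0, 1)
#'   (defaults 0.25 and 0.27).
#' @return named numeric vector `T` over all individuals in `ped`.
#' @export
transformPhenotypes <- function(ped, kMale = 0.25, kFemale = 0.27) {
  .assertProb(kMale, "kMale", open = TRUE)
  .assertProb(kFemale, "kFemale", open = TRUE)
  d <- ped@data
  k <- ifelse(d$sex == "male", kMale,
       ifelse(d$sex == "female", kFemale, (kMale + kFemale) / 2))
  tv <- ifelse(d$affection == "affected", 1,
        ifelse(d$affection == "unaffected", -k / (1 - k), 0))
  stats::setNames(tv, d$id)
}

#' Enrich genotyped phenotype weights with ungenotyped relatives
#'
#' Phenotype information of relatives who were never genotyped still
#' carries signal through the kinship structure. With `N` the genotyped
#' set and `M` the ungenotyped-but-phenotyped set, the enriched weight
#' vector is `A = T_N + Phi_NN^{-1} Phi_NM T_M`, where `Phi` is the
#' kinship matrix. With `M` empty, `A = T_N`.
#'
#' @param T named phenotype weight vector (see [transformPhenotypes()])
#'   covering at least `genotypedIds` and `ungenotypedIds`.
#' @param genotypedIds ids of genotyped individuals (the set `N`).
#' @param km a [KinshipMatrix-class] covering the union of the two sets.
#' @param ungenotypedIds ids of ungenotyped individuals whose phenotype is
#'   known (default: ids in `T` with nonzero weight, outside `N`).
#' @return named numeric vector `A` over `genotypedIds`.
#' @export
enrichPhenotypes <- function(T, genotypedIds, km, ungenotypedIds = NULL) {
  if (is.null(ungenotypedIds))
    ungenotypedIds <- setdiff(names(T)[T != 0], genotypedIds)
  ungenotypedIds <- intersect(ungenotypedIds, km@ids)
  A <- T[genotypedIds]
  if (length(ungenotypedIds)) {
    phiNN <- kinship(km, genotypedIds)
    phiNM <- kinship(km)[genotypedIds, ungenotypedIds, drop = FALSE]
    A <- A + drop(.solveSPD(phiNN, phiNM %*% T[ungenotypedIds]))
  }
  stats::setNames(drop(A), genotypedIds)
}

# Cholesky of an SPD matrix; refuses near-singular systems (pivot-ratio
# condition estimate > 1e12) rather than silently pseudo-inverting.
.cholSPD <- function(S) {
  R <- tryCatch(chol(as.matrix(S)), error = function(e)
    stop("kinship submatrix is not positive definite"))
  dg <- diag(R)
  if (min(dg) <= 0 || (max(dg) / min(dg))^2 > 1e12)
    stop("kinship submatrix is near-singular (condition > 1e12)")
  R
}

.solveSPD <- function(S, b, R = NULL) {
  if (is.null(R)) R <- .cholSPD(S)
  backsolve(R, forwardsolve(t(R), b))
}

#' Best linear unbiased estimate of the allele frequency in a pedigree
#'
#' Generalised-least-squares estimate of the allele frequency from
#' half-count genotypes `y` (0, 1/2, 1) of related individuals:
#' `p = (1' K^{-1} y) / (1' K^{-1} 1)` where `K` is the genotype
#' correlation matrix (`K[i,i] = 1 + h[i]`, `K[i,j] = 2 phi[i,j]`). For
#' unrelated individuals (`K` = identity) this reduces to the sample
#' frequency.
#'
#' @param y numeric genotype vector in `{0, 1/2, 1}` (no missing values;
#'   drop missing individuals from both `y` and `K` first).
#' @param K genotype correlation matrix aligned with `y`
#'   (see [genotypeCorrelation()]).
#' @param Kchol optional precomputed `chol(K)`, for repeated estimation
#'   against the same kinship structure.
#' @return estimated allele frequency.
#' @export
blueAlleleFreq <- function(y, K, Kchol = NULL) {
  if (!length(y)) stop("no genotyped individuals")
  if (any(is.na(y))) stop("y contains missing values; drop them first")
  one <- rep(1, length(y))
  Ki1 <- .solveSPD(K, one, R = Kchol)
  p <- sum(Ki1 * y) / sum(Ki1)
  min(max(p, 0), 1)
}

#' Pedigree-aware quasi-likelihood score test of association
#'
#' Case-control association test for a single biallelic variant among
#' related individuals. Genotypes are coded as half allele counts
#' `y` in `{0, 1/2, 1}`; phenotypes enter through the enriched weight
#' vector `A` (see [transformPhenotypes()] and [enrichPhenotypes()]); the
#' kinship structure enters through `K = 2 * Phi` which both corrects the
#' variance of the score for relatedness and weights the allele-frequency
#' estimate. The statistic is
#' \deqn{W = \frac{[A'(y - \hat p 1)]^2}{(\hat p(1-\hat p)/2)\,[A'KA - (A'1)^2/(1'K^{-1}1)]}}
#' referred to the upper tail of a 1-df chi-square distribution.
#' Monomorphic variants (estimated frequency 0 or 1) and degenerate
#' phenotype contrasts (zero variance term) are flagged untestable with
#' `p = 1` by convention.
#'
#' @param y half-count genotype vector (no missing values).
#' @param A enriched phenotype weight vector aligned with `y`.
#' @param K genotype correlation matrix aligned with `y`.
#' @param minMaf variants whose estimated minor allele frequency is below
#'   this are flagged untestable (default 0).
#' @param Kchol optional precomputed `chol(K)`, for scanning many
#'   variants against the same kinship structure.
#' @return list with `W`, `df` (1), `p`, `alleleFreq`, `nGenotyped` and
#'   `testable`.
#' @examples
#' # four unrelated individuals: genotype counts (2, 1, 0, 0)
#' y <- c(1, 0.5, 0, 0); A <- c(1, 1, -1/3, -1/3)
#' mqlsTest(y, A, diag(4))$W   # 4.8
#' @export
mqlsTest <- function(y, A, K, minMaf = 0, Kchol = NULL) {
  n <- length(y)
  if (length(A) != n || !all(dim(K) == n))
    stop("y, A and K must be aligned on the same genotyped set")
  if (is.null(Kchol)) Kchol <- .cholSPD(K)
  p <- blueAlleleFreq(y, K, Kchol = Kchol)
  out <- list(W = NA_real_, df = 1L, p = 1, alleleFreq = p,
              nGenotyped = n, testable = FALSE)
  maf <- min(p, 1 - p)
  if (maf <= 0 || maf < minMaf) return(out)
  one <- rep(1, n)
  Ki1 <- .solveSPD(K, one, R = Kchol)
  denom <- (p * (1 - p) / 2) * (drop(crossprod(A, K %*% A)) -
                                sum(A)^2 / sum(Ki1))
  if (!is.finite(denom) || denom <= 1e-14) return(out)
  W <- drop(crossprod(A, y - p))^2 / denom
  list(W = W, df = 1L, p = stats::pchisq(W, df = 1, lower.tail = FALSE),
       alleleFreq = p, nGenotyped = n, testable = TRUE)
}

#' Scan a set of variants for association in a pedigree
#'
#' Runs [mqlsTest()] for each variant of a genotype matrix against the
#' affection statuses of a pedigree. Per variant, individuals with
#' missing genotypes are dropped from `y`, `K` and `A`; phenotyped
#' individuals without a genotype for that variant contribute through the
#' enrichment term. X-linked variants are excluded with a warning unless
#' `includeX = TRUE` (the autosomal coding is then applied and flagged
#' approximate). A Bonferroni threshold `0.05 / n_variants` is reported;
#' no adjustment is applied to the statistics themselves.
#'
#' @param genotypes numeric matrix of allele counts (0, 1, 2, `NA`),
#'   rows = individuals (rownames = ids), columns = variants.
#' @param ped a [Pedigree-class] covering all genotyped individuals.
#' @param kMale,kFemale sex-specific prevalences (defaults 0.25, 0.27).
#' @param chrom optional character vector of chromosome names per variant
#'   (used for the X-linked exclusion).
#' @param includeX test X-linked variants with the autosomal coding
#'   (default `FALSE`).
#' @param minMaf passed to [mqlsTest()].
#' @return `data.frame` with one row per variant: `variant`, `W`, `df`,
#'   `p`, `alleleFreq`, `nGenotyped`, `testable`, `significant` (at the
#'   Bonferroni threshold), plus attributes `bonferroni` and `nTests`.
#' @export
associationScan <- function(genotypes, ped, kMale = 0.25, kFemale = 0.27,
                            chrom = NULL, includeX = FALSE, minMaf = 0) {
  if (is.null(rownames(genotypes)))
    stop("genotypes must have individual ids as rownames")
  vnames <- colnames(genotypes)
  if (is.null(vnames)) vnames <- paste0("v", seq_len(ncol(genotypes)))
  keepV <- rep(TRUE, ncol(genotypes))
  if (!is.null(chrom)) {
    isX <- chrom %in% c("X", "chrX", "23")
    if (any(isX) && !includeX) {
      warning("excluding ", sum(isX), " X-linked variant(s); ",
              "set includeX = TRUE to force the autosomal coding")
      keepV <- !isX
    } else if (any(isX)) {
      warning("testing X-linked variant(s) with the autosomal coding ",
              "(approximate)")
    }
  }
  km <- kinshipMatrix(ped)
  T <- transformPhenotypes(ped, kMale, kFemale)
  Kfull <- genotypeCorrelation(km)
  res <- lapply(which(keepV), function(j) {
    g <- genotypes[, j]
    N <- rownames(genotypes)[!is.na(g)]
    if (!length(N))
      return(data.frame(variant = vnames[j], W = NA, df = 1L, p = 1,
                        alleleFreq = NA, nGenotyped = 0L, testable = FALSE))
    y <- g[!is.na(g)] / 2
    M <- setdiff(names(T)[T != 0], N)
    A <- enrichPhenotypes(T, N, km, ungenotypedIds = M)
    r <- mqlsTest(y, A, Kfull[N, N, drop = FALSE], minMaf = minMaf)
    data.frame(variant = vnames[j], W = r$W, df = r$df, p = r$p,
               alleleFreq = r$alleleFreq, nGenotyped = r$nGenotyped,
               testable = r$testable)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  nTests <- sum(keepV)
  thr <- 0.05 / max(nTests, 1L)
  out$significant <- out$testable & out$p < thr
  attr(out, "bonferroni") <- thr
  attr(out, "nTests") <- nTests
  out
}
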