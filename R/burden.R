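#' Two-tailed Fisher's exact test for a 2x2 allele-count table
#'
#' Exact hypergeometric test comparing variant-allele counts between a
#' case cohort and reference-panel chromosomes. The two-sided p-value is
#' defined by the small-probability method: the sum of the probabilities
#' of all tables with the observed margins whose point probability does
#' not exceed that of the observed table (a relative slack of 1e-7
#' absorbs floating-point ties), capped at 1. A table of all zeros
#' returns `p = 1` with a warning.
#'
#' @param caseVariant,caseReference variant / reference allele counts on
#'   case chromosomes.
#' @param controlVariant,controlReference the same on control chromosomes.
#' @return two-sided p-value.
#' @examples
#' fisherExactTwoTailed(1, 233, 0, 9358)    # 0.0244
#' fisherExactTwoTailed(4, 230, 44, 9314)   # 0.029
#' @export
fisherExactTwoTailed <- function(caseVariant, caseReference,
                                 controlVariant, controlReference) {
  a <- .assertCount(caseVariant, "caseVariant")
  b <- .assertCount(caseReference, "caseReference")
  cc <- .assertCount(controlVariant, "controlVariant")
  d <- .assertCount(controlReference, "controlReference")
  if (a + b + cc + d == 0L) {
    warning("empty contingency table; p = 1")
    return(1)
  }
  m <- a + b          # case chromosomes
  n <- cc + d         # control chromosomes
  k <- a + cc         # total variant alleles
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- stats::dhyper(x, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  min(p, 1)
}

#' Aggregated (burden) comparison of variant categories
#'
#' Sums per-variant allele counts within a category for cases and
#' controls, forms the 2x2 allele-count table against the respective
#' chromosome totals, and computes frequencies and the two-tailed exact
#' p-value. Carrier counts are allele counts assuming heterozygosity
#' (each carrier contributes one of two chromosomes).
#'
#' @param caseVariantCounts per-variant variant-allele counts in cases.
#' @param caseChromosomes total case chromosomes sampled.
#' @param controlVariantCounts per-variant counts in the reference panels.
#' @param controlChromosomes total control chromosomes sampled.
#' @param category label (`"single_variant"`, `"combined_listed"`,
#'   `"private"`, `"rare_below_threshold"`, ...).
#' @return one-row `data.frame`: `category`, allele-count table columns
#'   `case_variant`, `case_reference`, `control_variant`,
#'   `control_reference`, `case_freq`, `control_freq`, `p`.
#' @examples
#' combinedBurden(c(1, 1, 2), 234, c(0, 0, 44), 9358, "combined_listed")
#' @export
combinedBurden <- function(caseVariantCounts, caseChromosomes,
                           controlVariantCounts, controlChromosomes,
                           category = "combined_listed") {
  a <- sum(caseVariantCounts)
  cc <- sum(controlVariantCounts)
  if (a > caseChromosomes)
    stop("summed case variant counts exceed case chromosome total")
  if (cc > controlChromosomes)
    stop("summed control variant counts exceed control chromosome total")
  b <- caseChromosomes - a
  d <- controlChromosomes - cc
  data.frame(category = category,
             case_variant = a, case_reference = b,
             control_variant = cc, control_reference = d,
             case_freq = a / caseChromosomes,
             control_freq = cc / controlChromosomes,
             p = fisherExactTwoTailed(a, b, cc, d))
}

#' Classify variants as private / rare / common
#'
#' A variant is *private* when it is observed in exactly one case
#' individual and is absent from all reference panels; *rare* when its
#' control frequency is below `rareThreshold` (private variants are by
#' construction rare); otherwise *common*. Labels are non-exclusive
#' logical columns.
#'
#' @param variants `data.frame` with columns `control_freq` (0 when the
#'   variant is absent from the panels) and `case_carriers` (number of
#'   case individuals carrying it).
#' @param rareThreshold control-frequency cut-off for rarity
#'   (default 0.01).
#' @return `variants` with added logical columns `private`, `rare`,
#'   `common`.
#' @export
classifyRarity <- function(variants, rareThreshold = 0.01) {
  variants$private <- variants$case_carriers == 1 & variants$control_freq == 0
  variants$rare <- variants$private | variants$control_freq < rareThreshold
  variants$common <- !variants$rare
  variants
}

#' Select variants for confirmatory verification
#'
#' In pooled sequencing, nonsynonymous variants and variants with an
#' estimated pooled allele frequency below 5% are re-sequenced
#' individually to confirm the call and derive accurate frequencies.
#' Returns the selected subset tagged with the selection reason.
#'
#' @param variants `data.frame` with columns `consequence` and
#'   `estimated_vaf` (pooled variant reads / total reads).
#' @param vafThreshold frequency below which even synonymous variants are
#'   verified (default 0.05).
#' @return subset of `variants` with an added `verification_reason`
#'   column (`"nonsynonymous"`, `"low frequency"` or both).
#' @export
selectForVerification <- function(variants, vafThreshold = 0.05) {
  nonsyn <- variants$consequence %in% .DELETERIOUS_CONSEQUENCES
  lowvaf <- variants$estimated_vaf < vafThreshold
  sel <- nonsyn | lowvaf
  out <- variants[sel, , drop = FALSE]
  out$verification_reason <- paste0(
    ifelse(nonsyn[sel], "nonsynonymous", ""),
    ifelse(nonsyn[sel] & lowvaf[sel], "+", ""),
    ifelse(lowvaf[sel], "low frequency", ""))
  out
}

#' Read reference-panel allele counts
#'
#' Tab-separated table with columns `panel`, `chrom`, `pos`, `ref`,
#' `alt`, `alt_count`, `total_chromosomes`; counts of several panels for
#' the same variant are summed by [panelTotals()].
#'
#' @param path TSV file path.
#' @return `data.frame` of panel counts.
#' @export
readPanelCounts <- function(path) {
  pc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("panel", "chrom", "pos", "ref", "alt", "alt_count",
            "total_chromosomes")
  miss <- setdiff(need, names(pc))
  if (length(miss)) stop("missing panel columns: ", paste(miss, collapse = ", "))
  pc
}

#' Sum reference-panel counts per variant
#'
#' @param panelCounts `data.frame` as returned by [readPanelCounts()].
#' @return `data.frame` with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, `alt_count`, `total_chromosomes`, `control_freq`.
#' @export
panelTotals <- function(panelCounts) {
  key <- paste(panelCounts$chrom, panelCounts$pos, panelCounts$ref,
               panelCounts$alt, sep = ":")
  sp <- split(panelCounts, key)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(chrom = g$chrom[1L], pos = g$pos[1L], ref = g$ref[1L],
               alt = g$alt[1L], alt_count = sum(g$alt_count),
               total_chromosomes = sum(g$total_chromosomes))))
  out$control_freq <- out$alt_count / out$total_chromosomes
  rownames(out) <- NULL
  out
}
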