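#' Genotype and allele frequency summaries by subgroup
#'
#' Tabulates, for each subgroup of individuals, the genotype frequencies
#' (homozygous reference, heterozygous, homozygous variant), the variant
#' allele frequency and the carrier count, as typically reported for a
#' validation cohort.
#'
#' @param genotypes named numeric vector of allele counts (0, 1, 2) per
#'   individual; `NA` for untyped individuals.
#' @param subgroups named list of id vectors; each individual may belong
#'   to any number of subgroups.
#' @return `data.frame` with one row per subgroup: `subgroup`, `n`,
#'   `freq_hom_ref`, `freq_het`, `freq_hom_var`, `allele_freq`,
#'   `carriers`. Empty subgroups get `n = 0` and `NA` frequencies.
#' @examples
#' g <- stats::setNames(c(rep(1, 25), rep(0, 86)), paste0("i", 1:111))
#' cohortFrequencySummary(g, list(all = names(g)))$allele_freq  # 0.1126
#' @export
cohortFrequencySummary <- function(genotypes, subgroups) {
  out <- lapply(names(subgroups), function(lab) {
    g <- genotypes[intersect(subgroups[[lab]], names(genotypes))]
    g <- g[!is.na(g)]
    n <- length(g)
    if (n == 0)
      return(data.frame(subgroup = lab, n = 0L, freq_hom_ref = NA,
                        freq_het = NA, freq_hom_var = NA,
                        allele_freq = NA, carriers = 0L))
    het <- sum(g == 1); hom <- sum(g == 2)
    data.frame(subgroup = lab, n = n,
               freq_hom_ref = sum(g == 0) / n,
               freq_het = het / n,
               freq_hom_var = hom / n,
               allele_freq = (het + 2 * hom) / (2 * n),
               carriers = het + hom)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Penetrance and phenocopy-rate summary
#'
#' Penetrance is the fraction of variant carriers who are affected; the
#' phenocopy rate is the fraction of affected individuals who do *not*
#' carry the variant. Only individuals with both genotype and affection
#' known are counted.
#'
#' @param carrier logical vector: carries at least one variant allele
#'   (`NA` = genotype unknown).
#' @param affected logical vector aligned with `carrier`
#'   (`NA` = phenotype unknown).
#' @return list with `penetrance`, `phenocopyRate` (either `NA` with a
#'   `flag` when undefined) and the underlying `counts` (carriers,
#'   affected carriers, affected, affected non-carriers).
#' @examples
#' # 25 carriers of whom 19 affected; 49 affected of whom 19 carriers
#' carrier <- c(rep(TRUE, 25), rep(FALSE, 86))
#' affected <- c(rep(TRUE, 19), rep(FALSE, 6), rep(TRUE, 30), rep(FALSE, 56))
#' penetrancePhenocopySummary(carrier, affected)
#' @export
penetrancePhenocopySummary <- function(carrier, affected) {
  ok <- !is.na(carrier) & !is.na(affected)
  carrier <- carrier[ok]; affected <- affected[ok]
  nCarrier <- sum(carrier)
  nAffected <- sum(affected)
  affCarrier <- sum(carrier & affected)
  affNonCarrier <- sum(!carrier & affected)
  flag <- character(0)
  if (nCarrier == 0) flag <- c(flag, "no carriers: penetrance undefined")
  if (nAffected == 0) flag <- c(flag, "no affected: phenocopy rate undefined")
  list(penetrance = if (nCarrier) affCarrier / nCarrier else NA_real_,
       phenocopyRate = if (nAffected) affNonCarrier / nAffected else NA_real_,
       counts = c(carriers = nCarrier, affected_carriers = affCarrier,
                  affected = nAffected, affected_non_carriers = affNonCarrier),
       flag = flag)
}

#' Sex-specific prevalence from cohort counts
#'
#' Convenience helper: prevalence of affection among males and females of
#' a phenotyped cohort (affected / assessed, per sex).
#'
#' @param affected logical vector of affection.
#' @param sex character vector, `"male"`/`"female"`, aligned with
#'   `affected`.
#' @return named numeric vector `c(male = ..., female = ...)`.
#' @export
prevalenceBySex <- function(affected, sex) {
  ok <- !is.na(affected) & sex %in% c("male", "female")
  c(male = mean(affected[ok & sex == "male"]),
    female = mean(affected[ok & sex == "female"]))
}
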