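#' Probability of detecting a heterozygous variant at a given read depth
#'
#' Under a binomial read model each read at a heterozygous position
#' carries the variant allele independently with probability
#' `perReadProb` (1/2 for an unbiased sequencer). The probability that at
#' least `minVariantReads` of `depth` reads carry the variant is the
#' upper tail of `Binomial(depth, perReadProb)`. At depth 10 with a
#' 2-read minimum this is 0.9893 — the "ten reads for 99% detection"
#' rule of thumb.
#'
#' @param depth total read depth (vectorised).
#' @param minVariantReads minimum variant-supporting reads required.
#' @param perReadProb per-read probability of sequencing the variant
#'   allele, strictly between 0 and 1 (default 0.5).
#' @return detection probability; 0 when `minVariantReads > depth`.
#' @examples
#' hetDetectionProbability(10, 2)      # 0.9892578
#' @export
hetDetectionProbability <- function(depth, minVariantReads, perReadProb = 0.5) {
  .assertProb(perReadProb, "perReadProb", open = TRUE)
  if (any(depth < 0) || any(minVariantReads < 0))
    stop("depth and minVariantReads must be non-negative")
  stats::pbinom(minVariantReads - 1, size = depth, prob = perReadProb,
                lower.tail = FALSE)
}

#' Minimum depth needed to reach a detection confidence
#'
#' Smallest depth `n` with
#' `hetDetectionProbability(n, minVariantReads, perReadProb) >= confidence`.
#'
#' @param minVariantReads minimum variant-supporting reads required.
#' @param confidence target detection probability, in (0, 1).
#' @param perReadProb per-read variant probability (default 0.5).
#' @return integer depth.
#' @examples
#' minDepthForConfidence(2, 0.985)   # 10
#' @export
minDepthForConfidence <- function(minVariantReads, confidence, perReadProb = 0.5) {
  .assertProb(confidence, "confidence", open = TRUE)
  n <- .assertCount(minVariantReads, "minVariantReads")
  while (hetDetectionProbability(n, minVariantReads, perReadProb) < confidence)
    n <- n + 1L
  n
}

# required columns of a variant record table
.VARIANT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                   "consequence", "known", "depth", "variant_reads",
                   "unique_start_sites")

#' Validate a variant record table
#'
#' Variant records are rows of a `data.frame` with columns `sample_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `consequence` (one of
#' missense, nonsense, frameshift, canonical_splice, synonymous,
#' intronic, nongenic, utr, other), `known` (logical) and the read
#' evidence `depth`, `variant_reads`, `unique_start_sites`. Read-evidence
#' sanity (`variant_reads <= depth`,
#' `unique_start_sites <= variant_reads`) and allele content are checked.
#'
#' @param records variant record `data.frame`.
#' @return `records`, invisibly, after validation.
#' @export
validateVariantRecords <- function(records) {
  miss <- setdiff(.VARIANT_COLS, names(records))
  if (length(miss)) stop("missing variant columns: ", paste(miss, collapse = ", "))
  if (any(records$pos < 1)) stop("pos must be >= 1")
  if (any(records$ref == records$alt)) stop("ref == alt in some record")
  if (!all(grepl("^[ACGT]+$", records$ref)) || !all(grepl("^[ACGT]+$", records$alt)))
    stop("alleles must be non-empty strings over A, C, G, T")
  if (any(records$variant_reads > records$depth))
    stop("variant_reads exceeds depth")
  if (any(records$unique_start_sites > records$variant_reads))
    stop("unique_start_sites exceeds variant_reads")
  invisible(records)
}

.filterResult <- function(records, keep, reason) {
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], removed = removed)
}

#' Read-evidence quality filter
#'
#' Keeps records with at least `minUniqueStarts` distinct alignment start
#' sites among the variant reads and a variant allele fraction
#' (`variant_reads / depth`) of at least `minVaf`. Both thresholds are
#' inclusive. Records with zero depth are removed with reason
#' `"no coverage"`.
#'
#' @param records variant record `data.frame` (see
#'   [validateVariantRecords()]).
#' @param minUniqueStarts minimum unique start sites (default 4).
#' @param minVaf minimum variant allele fraction (default 0.15).
#' @return list with elements `kept` and `removed` (the latter with a
#'   `reason` column).
#' @export
qualityFilter <- function(records, minUniqueStarts = 4, minVaf = 0.15) {
  validateVariantRecords(records)
  vaf <- ifelse(records$depth > 0, records$variant_reads / records$depth, NA)
  keep <- records$depth > 0 &
    records$unique_start_sites >= minUniqueStarts &
    !is.na(vaf) & vaf >= minVaf
  reason <- ifelse(records$depth == 0, "no coverage",
            ifelse(records$unique_start_sites < minUniqueStarts,
                   "unique start sites", "variant allele fraction"))
  .filterResult(records, keep, reason)
}

#' Consequence filter
#'
#' Keeps potentially deleterious consequences — missense, nonsense,
#' frameshift and canonical splice site (the 2 intronic bases at each
#' exon boundary) — and removes synonymous, intronic, nongenic, UTR and
#' other records.
#'
#' @param records variant record `data.frame`.
#' @return list with `kept` and `removed`.
#' @export
consequenceFilter <- function(records) {
  cons <- records$consequence
  bad <- is.na(cons) | !(cons %in% .CONSEQUENCE_LEVELS)
  if (any(bad))
    stop("missing or invalid consequence for record(s): ",
         paste(utils::head(.variantKey(records)[bad], 5), collapse = ", "))
  keep <- cons %in% .DELETERIOUS_CONSEQUENCES
  .filterResult(records, keep, rep("consequence class", nrow(records)))
}

#' Novelty filter against known-variant catalogues
#'
#' Removes records whose allele-aware identity `(chrom, pos, ref, alt)`
#' appears in the union of the supplied catalogues, and sets the `known`
#' flag accordingly on the kept and removed records. Matching is
#' allele-aware: a known site with a *different* alternate allele still
#' counts as novel.
#'
#' @param records variant record `data.frame`.
#' @param known a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (rows of several catalogues may be concatenated), or a list of such
#'   data frames.
#' @return list with `kept` (novel) and `removed` (known).
#' @export
noveltyFilter <- function(records, known) {
  if (is.data.frame(known)) known <- list(known)
  keys <- unique(unlist(lapply(known, function(k) {
    if (!nrow(k)) return(character(0))
    paste(k$chrom, k$pos, k$ref, k$alt, sep = ":")
  })))
  hit <- .variantKey(records) %in% keys
  records$known <- hit
  .filterResult(records, !hit, rep("known site", nrow(records)))
}

#' Affected-sharing filter
#'
#' Collapses per-sample records to distinct variants and keeps those
#' carried by at least `minShared` distinct samples.
#'
#' @param records variant record `data.frame` across samples.
#' @param minShared minimum number of distinct carrier samples (default 3).
#' @param nSamples total number of sequenced samples (default: number of
#'   distinct `sample_id` values present).
#' @return `data.frame` of shared variants: one row per variant with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#'   `n_carriers` and a comma-separated `carriers` column.
#' @export
sharingFilter <- function(records, minShared = 3, nSamples = NULL) {
  if (is.null(nSamples)) nSamples <- length(unique(records$sample_id))
  if (minShared > nSamples)
    stop("minShared (", minShared, ") exceeds number of samples (", nSamples, ")")
  if (!nrow(records))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      n_carriers = integer(0), carriers = character(0)))
  key <- .variantKey(records)
  sp <- split(records, key)
  out <- do.call(rbind, lapply(sp, function(g) {
    carr <- sort(unique(g$sample_id))
    data.frame(chrom = g$chrom[1L], pos = g$pos[1L], ref = g$ref[1L],
               alt = g$alt[1L], gene = g$gene[1L],
               consequence = g$consequence[1L],
               n_carriers = length(carr),
               carriers = paste(carr, collapse = ","))
  }))
  rownames(out) <- NULL
  out <- out[out$n_carriers >= minShared, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Annotate variants with linkage-region overlap
#'
#' Flags each record that falls inside one of the supplied regions
#' (1-based inclusive on both ends, same chromosome). Overlap is computed
#' with `GenomicRanges::findOverlaps`.
#'
#' @param records variant `data.frame` with `chrom` and `pos`.
#' @param regions a `GRanges`, or a `data.frame` with columns `chrom`,
#'   `start`, `end` in 1-based inclusive coordinates.
#' @return `records` with an added logical column `in_linkage_region`.
#' @seealso [readRegionsBed()]
#' @export
annotateLinkageRegions <- function(records, regions) {
  if (!nrow(records)) {
    records$in_linkage_region <- logical(0)
    return(records)
  }
  if (methods::is(regions, "GRanges"))
    regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                          start = GenomicRanges::start(regions),
                          end = GenomicRanges::end(regions))
  # shared chromosome universe avoids seqlevel mismatch noise
  lv <- unique(c(records$chrom, regions$chrom))
  gr <- GenomicRanges::GRanges(factor(regions$chrom, levels = lv),
                               IRanges::IRanges(regions$start, regions$end))
  q <- GenomicRanges::GRanges(factor(records$chrom, levels = lv),
                              IRanges::IRanges(records$pos, records$pos))
  records$in_linkage_region <- IRanges::overlapsAny(q, gr)
  records
}

#' Read a BED region file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path BED file (first three columns chrom, start, end).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
readRegionsBed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]) + 1L,
                    end = as.integer(bed[[3]]),
                    label = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA)
  if (any(out$start > out$end)) stop("malformed BED interval (start > end)")
  out
}

#' Run the full exome filter cascade
#'
#' Applies, in order: read-evidence quality, consequence, novelty against
#' known catalogues, and affected-sharing; survivors are annotated with
#' linkage-region overlap flags and a `validated` placeholder (external
#' confirmation, e.g. by Sanger sequencing, is recorded by the caller).
#' Per-record filters commute, so ordering only affects the attribution
#' of removals, not survival.
#'
#' @param records variant record `data.frame` across samples.
#' @param known known-variant catalogue(s) (see [noveltyFilter()]);
#'   `NULL` for none.
#' @param regions linkage regions (see [annotateLinkageRegions()]);
#'   `NULL` for none.
#' @param minUniqueStarts,minVaf quality thresholds (defaults 4 and 0.15).
#' @param minShared,nSamples sharing thresholds (defaults 3 and the
#'   number of distinct samples).
#' @return list with `shared` (surviving variant table with
#'   `in_linkage_region` and `validated` columns) and `report`
#'   (a [FilterReport-class]).
#' @examples
#' sim <- simulateExomeCohort(exomeSimConfig(nBackgroundVariants = 200, seed = 1))
#' res <- filterCascade(sim$records, known = sim$known)
#' res$report
#' @export
filterCascade <- function(records, known = NULL, regions = NULL,
                          minUniqueStarts = 4, minVaf = 0.15,
                          minShared = 3, nSamples = NULL) {
  validateVariantRecords(records)
  if (is.null(nSamples)) nSamples <- length(unique(records$sample_id))
  stages <- data.frame(stage = character(0), input = integer(0),
                       kept = integer(0), removed = integer(0))
  note <- function(stage, input, kept)
    rbind(stages, data.frame(stage = stage, input = input, kept = kept,
                             removed = input - kept))

  q <- qualityFilter(records, minUniqueStarts, minVaf)
  stages <- note("quality", nrow(records), nrow(q$kept))
  cns <- consequenceFilter(q$kept)
  stages <- note("consequence", nrow(q$kept), nrow(cns$kept))
  nov <- if (is.null(known)) list(kept = cns$kept) else noveltyFilter(cns$kept, known)
  stages <- note("novelty", nrow(cns$kept), nrow(nov$kept))
  shared <- sharingFilter(nov$kept, minShared = minShared, nSamples = nSamples)
  # sharing collapses per-sample records to variants; count surviving records
  keptRecords <- nov$kept[.variantKey(nov$kept) %in% .variantKey(shared), , drop = FALSE]
  stages <- note("sharing", nrow(nov$kept), nrow(keptRecords))

  if (!is.null(regions)) shared <- annotateLinkageRegions(shared, regions)
  else shared$in_linkage_region <- rep(FALSE, nrow(shared))
  shared$validated <- rep(NA, nrow(shared))
  report <- new("FilterReport", stages = stages,
                survivors = .variantKey(shared))
  list(shared = shared, report = report)
}

#' FilterReport accessors
#'
#' `stageCounts()` returns the per-stage bookkeeping table;
#' `survivors()` the keys of variants surviving the cascade.
#'
#' @param x a [FilterReport-class].
#' @name FilterReport-accessors
NULL

#' @rdname FilterReport-accessors
#' @export
setMethod("stageCounts", "FilterReport", function(x) x@stages)

#' @rdname FilterReport-accessors
#' @export
setMethod("survivors", "FilterReport", function(x) x@survivors)

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", length(object@survivors), "surviving variant(s)\n")
  print(object@stages, row.names = FALSE)
})
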