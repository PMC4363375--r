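#' Write a variant record table as TSV
#'
#' @param records variant record `data.frame`
#'   (see [validateVariantRecords()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(records, path) {
  utils::write.table(records[, .VARIANT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant record table from TSV
#'
#' Expects the 11 documented columns (`sample_id`, `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `consequence`, `known`, `depth`, `variant_reads`,
#' `unique_start_sites`).
#'
#' @param path TSV path.
#' @return validated variant record `data.frame`.
#' @export
readVariantTable <- function(path) {
  r <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        sample_id = "character",
                                        ref = "character",
                                        alt = "character",
                                        gene = "character"))
  validateVariantRecords(r)
  r
}

# VCF 4.2 emission for one sample's records. Minimal but standard:
# INFO carries gene, consequence, unique start sites and known flag;
# FORMAT carries GT:DP:AD.
.writeSampleVcf <- function(records, sample_id, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
           "##INFO=<ID=USS,Number=1,Type=Integer,Description=\"Unique variant-read start sites\">",
           "##INFO=<ID=KNOWN,Number=1,Type=Integer,Description=\"Present in known-variant catalogues (0/1)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  r <- records[order(records$chrom, records$pos), , drop = FALSE]
  info <- sprintf("GENE=%s;CSQ=%s;USS=%d;KNOWN=%d", r$gene,
                  r$consequence, r$unique_start_sites, as.integer(r$known))
  geno <- sprintf("0/1:%d:%d,%d", r$depth, r$depth - r$variant_reads,
                  r$variant_reads)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:DP:AD\t%s",
                  r$chrom, r$pos, r$ref, r$alt, info, geno)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read one sample's variant records from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) carrying per-genotype `DP` and
#' `AD` fields plus the `GENE`, `CSQ`, `USS` and `KNOWN` INFO keys used
#' by [writeFixtureBundle()], and reconstructs the variant record table.
#'
#' @param path VCF file path.
#' @param sample_id sample identifier to assign (default: the VCF's
#'   genotype column name).
#' @return validated variant record `data.frame`.
#' @export
readVariantVcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2L]
  dp <- as.integer(vcfR::extract.gt(v, "DP"))
  ad <- vcfR::extract.gt(v, "AD")
  vr <- as.integer(vapply(strsplit(ad, ","), `[`, "", 2L))
  uss <- as.integer(vcfR::extract.info(v, "USS"))
  gene <- vcfR::extract.info(v, "GENE")
  csq <- vcfR::extract.info(v, "CSQ")
  known <- vcfR::extract.info(v, "KNOWN") == "1"
  r <- data.frame(sample_id = sample_id,
                  chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  gene = gene, consequence = csq, known = known,
                  depth = dp, variant_reads = vr,
                  unique_start_sites = uss)
  rownames(r) <- NULL
  validateVariantRecords(r)
  r
}

#' Read a known-variant catalogue
#'
#' Accepts a VCF (sites-only or with genotypes) or a TSV with columns
#' `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path catalogue file path (`.vcf` or TSV).
#' @return `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
readKnownCatalogue <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = fix[, "ALT"])
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  }
}

.writeSitesVcf <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  s <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", s$chrom, s$pos, s$ref, s$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.writeBed <- function(regions, path) {
  # internal 1-based inclusive -> BED 0-based half-open
  lab <- if (!is.null(regions$label)) regions$label else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start - 1L,
                     regions$end, lab), path)
  invisible(path)
}

#' Write a self-describing fixture bundle
#'
#' Serialises simulated objects into the plain-text formats the pipeline
#' consumes: PED/FAM (cohort), one VCF per sample plus a known-catalogue
#' VCF and truth-label JSON (exome), BED linkage regions, reference-panel
#' count TSV, and a `manifest.json` recording the seeds and
#' configurations so the bundle is reproducible. Identical seeds produce
#' byte-identical bundles.
#'
#' @param dir output directory (created if needed).
#' @param cohort optional result of [simulateCohort()].
#' @param exome optional result of [simulateExomeCohort()].
#' @param regions optional region `data.frame` (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param panelCounts optional reference-panel count `data.frame`
#'   (see [readPanelCounts()]).
#' @return character vector of written file paths, invisibly.
#' @export
writeFixtureBundle <- function(dir, cohort = NULL, exome = NULL,
                               regions = NULL, panelCounts = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  written <- character(0)
  put <- function(f) written <<- c(written, f)
  if (!is.null(cohort)) {
    put(writePed(cohort$ped, file.path(dir, "cohort.ped")))
    g <- cohort$genotypes
    utils::write.table(
      data.frame(id = names(g), allele_count = unname(g)),
      file.path(dir, "cohort_genotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    put(file.path(dir, "cohort_genotypes.tsv"))
  }
  if (!is.null(exome)) {
    for (s in unique(exome$records$sample_id)) {
      f <- file.path(dir, paste0(s, ".vcf"))
      .writeSampleVcf(exome$records[exome$records$sample_id == s, ], s, f)
      put(f)
    }
    put(.writeSitesVcf(exome$known, file.path(dir, "known_catalogue.vcf")))
    jsonlite::write_json(exome$truth, file.path(dir, "truth_labels.json"),
                         dataframe = "columns", pretty = TRUE)
    put(file.path(dir, "truth_labels.json"))
  }
  if (!is.null(regions)) put(.writeBed(regions, file.path(dir, "regions.bed")))
  if (!is.null(panelCounts)) {
    utils::write.table(panelCounts, file.path(dir, "panel_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    put(file.path(dir, "panel_counts.tsv"))
  }
  manifest <- list(
    cohort = if (!is.null(cohort)) unclass(cohort$cfg),
    exome = if (!is.null(exome)) unclass(exome$cfg),
    files = basename(written))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  put(file.path(dir, "manifest.json"))
  invisible(written)
}

#' Read a fixture bundle back into memory
#'
#' Inverse of [writeFixtureBundle()] for the exome part: re-reads the
#' per-sample VCFs, the known catalogue and the truth labels.
#'
#' @param dir bundle directory.
#' @return list with `records`, `known`, `truth`, and `ped` /
#'   `genotypes` when a cohort was written.
#' @export
readFixtureBundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list(manifest = manifest)
  vcfs <- setdiff(list.files(dir, pattern = "\\.vcf$", full.names = TRUE),
                  file.path(dir, "known_catalogue.vcf"))
  if (length(vcfs))
    out$records <- do.call(rbind, lapply(vcfs, readVariantVcf))
  kc <- file.path(dir, "known_catalogue.vcf")
  if (file.exists(kc)) out$known <- readKnownCatalogue(kc)
  tl <- file.path(dir, "truth_labels.json")
  if (file.exists(tl))
    out$truth <- as.data.frame(jsonlite::read_json(tl, simplifyVector = TRUE))
  pd <- file.path(dir, "cohort.ped")
  if (file.exists(pd)) out$ped <- readPed(pd)
  gt <- file.path(dir, "cohort_genotypes.tsv")
  if (file.exists(gt)) {
    g <- utils::read.table(gt, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    out$genotypes <- stats::setNames(g$allele_count, g$id)
  }
  out
}
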