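#' Construct a Pedigree
#'
#' Builds and validates a [Pedigree-class] object from per-individual
#' vectors. Founders are individuals whose father *and* mother are `NA`;
#' half-specified parents are rejected. Parents whose sex is unknown are
#' assigned male/female according to their parental role, with a warning.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother identifiers of the parents, `NA` for founders.
#' @param sex `"male"`, `"female"` or `"unknown"` (default) per individual.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"` (default).
#' @param genotyped logical, whether a genotype is available (default `FALSE`).
#' @param familyId family label (default `"FAM1"`).
#'
#' @return A validated [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(id = c("dad", "mum", "kid"),
#'                  father = c(NA, NA, "dad"),
#'                  mother = c(NA, NA, "mum"),
#'                  sex = c("male", "female", "female"))
#' founders(trio)
#' @export
Pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     affection = "unknown", genotyped = FALSE,
                     familyId = "FAM1") {
  n <- length(id)
  d <- data.frame(id = as.character(id),
                  father = as.character(rep_len(father, n)),
                  mother = as.character(rep_len(mother, n)),
                  sex = as.character(rep_len(sex, n)),
                  affection = as.character(rep_len(affection, n)),
                  genotyped = as.logical(rep_len(genotyped, n)),
                  stringsAsFactors = FALSE)
  d$father[d$father %in% c("", "0")] <- NA_character_
  d$mother[d$mother %in% c("", "0")] <- NA_character_
  # assign sex by parental role where unknown (required for validity)
  is_father <- d$id %in% d$father
  is_mother <- d$id %in% d$mother
  fix_f <- is_father & d$sex == "unknown"
  fix_m <- is_mother & d$sex == "unknown"
  if (any(fix_f) || any(fix_m))
    warning("assigning sex by parental role for: ",
            paste(d$id[fix_f | fix_m], collapse = ", "))
  d$sex[fix_f] <- "male"
  d$sex[fix_m] <- "female"
  new("Pedigree", familyId = as.character(familyId)[1L], data = d)
}

#' Read a PED/FAM pedigree file
#'
#' Parses a whitespace-delimited PLINK-dialect PED/FAM file with the six
#' mandatory columns family, individual, father, mother, sex, phenotype;
#' any additional columns are ignored. `0` denotes a missing parent or
#' unknown sex; phenotype codes are mapped 1 = unaffected, 2 = affected
#' and 0 / -9 = unknown. Both tabs and spaces are accepted as delimiters.
#'
#' @param path path to the PED/FAM file.
#' @param genotyped optional character vector of ids with genotypes, or a
#'   logical vector aligned with the file rows; default marks none.
#' @return A validated [Pedigree-class].
#' @seealso [writePed()], [Pedigree()]
#' @export
readPed <- function(path, genotyped = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(raw) < 6) stop("PED file must have at least 6 columns")
  names(raw)[1:6] <- paste0("V", 1:6)  # extra columns beyond 6 are ignored
  id <- raw$V2
  if (anyDuplicated(id))
    stop("duplicate individual id(s) in PED file: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sex <- c("1" = "male", "2" = "female")[raw$V5]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[raw$V6]
  aff[is.na(aff)] <- "unknown"
  geno <- if (is.null(genotyped)) FALSE
          else if (is.character(genotyped)) id %in% genotyped
          else as.logical(genotyped)
  Pedigree(id = id, father = raw$V3, mother = raw$V4, sex = unname(sex),
           affection = unname(aff), genotyped = geno, familyId = raw$V1[1L])
}

#' Write a Pedigree as a PED/FAM file
#'
#' Emits the six mandatory PLINK columns, tab-delimited, with `0` for
#' missing parents/sex and 1/2/0 phenotype coding, so that
#' `readPed(writePed(p, f))` round-trips.
#'
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePed <- function(ped, path) {
  d <- ped@data
  out <- data.frame(
    fam = ped@familyId,
    id = d$id,
    father = ifelse(is.na(d$father), "0", d$father),
    mother = ifelse(is.na(d$mother), "0", d$mother),
    sex = c(male = "1", female = "2", unknown = "0")[d$sex],
    phe = c(affected = "2", unaffected = "1", unknown = "0")[d$affection])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pedigree accessors
#'
#' `individuals()` returns the per-individual table; `founders()` and
#' `nonFounders()` return the corresponding ids (a founder has no recorded
#' parents).
#'
#' @param x a [Pedigree-class].
#' @return `individuals()`: a `data.frame`; `founders()`/`nonFounders()`:
#'   character vectors of ids.
#' @name Pedigree-accessors
NULL

#' @rdname Pedigree-accessors
#' @export
setMethod("individuals", "Pedigree", function(x) x@data)

#' @rdname Pedigree-accessors
#' @export
setMethod("founders", "Pedigree",
          function(x) x@data$id[is.na(x@data$father)])

#' @rdname Pedigree-accessors
#' @export
setMethod("nonFounders", "Pedigree",
          function(x) x@data$id[!is.na(x@data$father)])

#' Pedigree complexity in bits
#'
#' The complexity of a pedigree for exact-likelihood computation, defined
#' as twice the number of non-founders minus the number of founders. A
#' trio scores `2*1 - 2 = 0`; large multi-generation founder pedigrees
#' (hundreds of bits) are beyond exact linkage computation and typically
#' have to be split.
#'
#' @param x a [Pedigree-class], or the number of non-founders.
#' @param founders number of founders (numeric method only).
#' @param ... unused.
#' @return integer number of bits.
#' @examples
#' pedigreeBits(203, 85)   # 321
#' @export
#' @rdname pedigreeBits
setMethod("pedigreeBits", "Pedigree", function(x, ...) {
  2L * length(nonFounders(x)) - length(founders(x))
})

#' @rdname pedigreeBits
#' @export
setMethod("pedigreeBits", "numeric", function(x, founders, ...) {
  nf <- .assertCount(x, "x")
  f <- .assertCount(founders, "founders")
  2L * nf - f
})

#' Generation depth of each individual
#'
#' Founders are generation 0; every other individual is one deeper than
#' its deepest parent.
#'
#' @param ped a [Pedigree-class].
#' @return named integer vector of depths.
#' @export
generationDepth <- function(ped) {
  d <- ped@data
  stats::setNames(.generationDepth(d), d$id)
}

#' Summary statistics of a pedigree
#'
#' @param ped a [Pedigree-class].
#' @return list with counts of individuals, founders, non-founders, males,
#'   females, affected, bits and number of generations.
#' @export
pedStats <- function(ped) {
  d <- ped@data
  list(n = nrow(d),
       founders = length(founders(ped)),
       nonFounders = length(nonFounders(ped)),
       males = sum(d$sex == "male"),
       females = sum(d$sex == "female"),
       affected = sum(d$affection == "affected"),
       bits = pedigreeBits(ped),
       generations = max(.generationDepth(d)) + 1L)
}

setMethod("show", "Pedigree", function(object) {
  s <- pedStats(object)
  cat("Pedigree '", object@familyId, "': ", s$n, " individuals (",
      s$founders, " founders, ", s$nonFounders, " non-founders), ",
      s$generations, " generations, ", s$bits, " bits\n", sep = "")
  cat("  affected: ", s$affected, ", genotyped: ",
      sum(object@data$genotyped), "\n", sep = "")
})
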