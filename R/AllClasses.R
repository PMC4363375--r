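#' @import methods
NULL

.SEX_LEVELS <- c("male", "female", "unknown")
.AFFECTION_LEVELS <- c("affected", "unaffected", "unknown")
.CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift", "canonical_splice",
                         "synonymous", "intronic", "nongenic", "utr", "other")
.DELETERIOUS_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "canonical_splice")

#' Pedigree of related individuals
#'
#' An S4 container for a validated pedigree: one row per individual with
#' parental links, sex, affection status and a genotyped flag. A *founder*
#' is exactly an individual with both parent fields missing (this covers
#' both original founders and married-in individuals). The parent relation
#' must be acyclic, referenced parents must exist, and fathers/mothers must
#' be male/female where sex is known.
#'
#' @slot familyId single character label for the family.
#' @slot data `data.frame` with character columns `id`, `father`, `mother`
#'   (`NA` for founders), `sex` (`"male"`, `"female"`, `"unknown"`),
#'   `affection` (`"affected"`, `"unaffected"`, `"unknown"`) and logical
#'   `genotyped`.
#'
#' @seealso [Pedigree()], [readPed()], [kinshipMatrix()], [pedigreeBits()]
#' @export
setClass("Pedigree",
         representation(familyId = "character", data = "data.frame"))

#' Pairwise kinship coefficients for a pedigree
#'
#' Stores the symmetric matrix of kinship coefficients phi[i,j] — the
#' probability that one allele sampled at random from i and one from j are
#' identical by descent — together with the inbreeding coefficients
#' h[i] = 2*phi[i,i] - 1. For a non-inbred individual phi[i,i] = 1/2 and
#' h[i] = 0; two distinct founders have phi = 0.
#'
#' @slot ids ordered individual identifiers (row/column order of `phi`).
#' @slot phi symmetric numeric matrix of kinship coefficients in `[0, 1]`.
#' @slot h numeric vector of inbreeding coefficients, `h = 2 * diag(phi) - 1`.
#'
#' @seealso [kinshipMatrix()], [kinship()], [inbreeding()]
#' @export
setClass("KinshipMatrix",
         representation(ids = "character", phi = "matrix", h = "numeric"))

#' Stage-by-stage report of the variant filter cascade
#'
#' Records, for every filtering stage, how many variant records entered,
#' how many were kept and how many removed, plus the keys of the variants
#' that survived the whole cascade. Counts are conserved: at every stage
#' kept + removed = input, and each stage's input equals the previous
#' stage's kept.
#'
#' @slot stages `data.frame` with columns `stage`, `input`, `kept`, `removed`.
#' @slot survivors character vector of surviving variant keys
#'   (`"chrom:pos:ref:alt"`).
#'
#' @seealso [filterCascade()]
#' @export
setClass("FilterReport",
         representation(stages = "data.frame", survivors = "character"))

#' Result of a gene-drop (allele-dropping) simulation
#'
#' Monte-Carlo distribution of a variant's allele frequency in a target set
#' of individuals, obtained by dropping founder alleles through the
#' pedigree under Mendelian transmission.
#'
#' @slot targetIds individuals whose allele frequency was recorded.
#' @slot freqs per-replicate variant-allele frequency in the target set.
#' @slot mode `"fixed_carriers"` or `"random_frequency"`.
#' @slot nReplicates number of replicates.
#' @slot seed integer seed used (NA if none supplied).
#'
#' @seealso [dropAlleles()], [enumerateExact()], [expectedFrequencySweep()]
#' @export
setClass("GeneDropResult",
         representation(targetIds = "character", freqs = "numeric",
                        mode = "character", nReplicates = "integer",
                        seed = "integer"))

setValidity("Pedigree", function(object) {
  d <- object@data
  need <- c("id", "father", "mother", "sex", "affection", "genotyped")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$id))
    return(paste("duplicate individual id(s):",
                 paste(unique(d$id[duplicated(d$id)]), collapse = ", ")))
  half <- xor(is.na(d$father), is.na(d$mother))
  if (any(half))
    return(paste("half-specified parents for:", paste(d$id[half], collapse = ", ")))
  refs <- c(d$father, d$mother)
  bad <- setdiff(refs[!is.na(refs)], d$id)
  if (length(bad))
    return(paste("unknown parent reference(s):", paste(unique(bad), collapse = ", ")))
  if (!all(d$sex %in% .SEX_LEVELS)) return("invalid sex value")
  if (!all(d$affection %in% .AFFECTION_LEVELS)) return("invalid affection value")
  fa <- d$sex[match(d$father[!is.na(d$father)], d$id)]
  mo <- d$sex[match(d$mother[!is.na(d$mother)], d$id)]
  if (any(fa == "female")) return("a father is recorded as female")
  if (any(mo == "male")) return("a mother is recorded as male")
  cyc <- .findCycle(d)
  if (!is.null(cyc))
    return(paste("parent relation is cyclic:", paste(cyc, collapse = " -> ")))
  TRUE
})

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  n <- length(object@ids)
  if (!all(dim(p) == c(n, n))) return("phi dimensions do not match ids")
  if (length(object@h) != n) return("h length does not match ids")
  if (any(p < 0 - 1e-12) || any(p > 1 + 1e-12)) return("phi outside [0, 1]")
  if (max(abs(p - t(p))) > 1e-12) return("phi is not symmetric")
  if (any(diag(p) < 0.5 - 1e-12)) return("diagonal phi below 1/2")
  if (max(abs(object@h - (2 * diag(p) - 1))) > 1e-12)
    return("h inconsistent with 2*diag(phi) - 1")
  TRUE
})

setValidity("FilterReport", function(object) {
  s <- object@stages
  if (!all(c("stage", "input", "kept", "removed") %in% names(s)))
    return("stages must have columns stage, input, kept, removed")
  if (any(s$kept + s$removed != s$input))
    return("kept + removed != input at some stage")
  if (nrow(s) > 1 && any(s$input[-1] != s$kept[-nrow(s)]))
    return("stage input does not chain from previous kept")
  TRUE
})

setValidity("GeneDropResult", function(object) {
  if (any(object@freqs < -1e-12 | object@freqs > 1 + 1e-12))
    return("replicate frequencies outside [0, 1]")
  if (length(object@freqs) != object@nReplicates)
    return("freqs length != nReplicates")
  TRUE
})
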