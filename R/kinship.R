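#' Recursive kinship and inbreeding coefficients
#'
#' Computes the full matrix of pairwise kinship coefficients by the
#' classical recursion over individuals in ancestor-before-descendant
#' order: founders have `phi[i,i] = 1/2` and `phi[i,j] = 0` with other
#' founders; an individual `i` with parents `(f, m)` has
#' `phi[i,i] = (1 + phi[f,m]) / 2` and, for any previously processed
#' `j`, `phi[i,j] = (phi[f,j] + phi[m,j]) / 2`. Inbreeding coefficients
#' are `h = 2 * diag(phi) - 1` (the kinship of the parents).
#'
#' Classical identities fall out of the recursion: parent-offspring and
#' full sibs 1/4, half sibs 1/8, first cousins 1/16; the child of
#' first-cousin parents has `h = 1/16`.
#'
#' @param x a [Pedigree-class].
#' @param ... unused.
#' @return A [KinshipMatrix-class].
#' @examples
#' trio <- Pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"), sex = c("male", "female", "unknown"))
#' kinship(kinshipMatrix(trio))["f", "c"]   # 0.25
#' @export
#' @rdname kinshipMatrix
setMethod("kinshipMatrix", "Pedigree", function(x, ...) {
  d <- x@data
  ord <- .topoOrder(d)
  ids <- d$id[ord]
  fi <- match(d$father[ord], ids)   # indices into the reordered vector
  mi <- match(d$mother[ord], ids)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]; m <- mi[i]
      phi[i, i] <- (1 + phi[f, m]) / 2
      if (i > 1L) {
        j <- seq_len(i - 1L)
        v <- (phi[f, j] + phi[m, j]) / 2
        phi[i, j] <- v
        phi[j, i] <- v
      }
    }
  }
  # return in the pedigree's own individual order
  back <- match(d$id, ids)
  phi <- phi[back, back, drop = FALSE]
  new("KinshipMatrix", ids = d$id, phi = phi, h = 2 * diag(phi) - 1)
})

#' KinshipMatrix accessors
#'
#' `kinship()` returns the symmetric matrix of kinship coefficients
#' (optionally restricted to a subset of ids); `inbreeding()` the named
#' vector of inbreeding coefficients.
#'
#' @param x a [KinshipMatrix-class].
#' @param ids optional ids to subset rows/columns (order preserved).
#' @param ... unused.
#' @name KinshipMatrix-accessors
NULL

#' @rdname KinshipMatrix-accessors
#' @export
setMethod("kinship", "KinshipMatrix", function(x, ids = NULL, ...) {
  if (is.null(ids)) return(x@phi)
  miss <- setdiff(ids, x@ids)
  if (length(miss)) stop("ids not in kinship matrix: ", paste(miss, collapse = ", "))
  x@phi[ids, ids, drop = FALSE]
})

#' @rdname KinshipMatrix-accessors
#' @export
setMethod("inbreeding", "KinshipMatrix",
          function(x) stats::setNames(x@h, x@ids))

#' Genotype correlation matrix used by the quasi-likelihood score test
#'
#' For the half-count genotype coding the covariance structure of the
#' genotype vector is proportional to `K` with `K[i,i] = 1 + h[i]` and
#' `K[i,j] = 2 * phi[i,j]`; since `1 + h = 2 * diag(phi)` this is exactly
#' `2 * phi`.
#'
#' @param km a [KinshipMatrix-class].
#' @param ids optional subset of ids.
#' @return numeric matrix `K`.
#' @seealso [mqlsTest()], [blueAlleleFreq()]
#' @export
genotypeCorrelation <- function(km, ids = NULL) {
  2 * kinship(km, ids)
}

setMethod("show", "KinshipMatrix", function(object) {
  n <- length(object@ids)
  cat("KinshipMatrix over ", n, " individuals; ",
      sum(object@h > 1e-12), " inbred (max h = ",
      format(max(c(0, object@h)), digits = 3), ")\n", sep = "")
})
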