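#' @rdname Pedigree-accessors
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname Pedigree-accessors
#' @export
setGeneric("nonFounders", function(x) standardGeneric("nonFounders"))

#' @rdname Pedigree-accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname pedigreeBits
#' @export
setGeneric("pedigreeBits", function(x, ...) standardGeneric("pedigreeBits"))

#' @rdname kinshipMatrix
#' @export
setGeneric("kinshipMatrix", function(x, ...) standardGeneric("kinshipMatrix"))

#' @rdname KinshipMatrix-accessors
#' @export
setGeneric("kinship", function(x, ...) standardGeneric("kinship"))

#' @rdname KinshipMatrix-accessors
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))

#' @rdname GeneDropResult-accessors
#' @export
setGeneric("dropFreqs", function(x) standardGeneric("dropFreqs"))

#' @rdname FilterReport-accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname FilterReport-accessors
#' @export
setGeneric("survivors", function(x) standardGeneric("survivors"))
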