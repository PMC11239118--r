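#' @rdname TraitTable
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname TraitTable
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @rdname TraitTable
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TraitTable
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname FilterSet-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname FilterSet-class
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))

#' @rdname FilterSet-class
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))

#' @rdname MultipleImputationResult-class
#' @export
setGeneric("imputationDraws", function(x) standardGeneric("imputationDraws"))
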