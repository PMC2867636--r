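#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("rateSE", function(x) standardGeneric("rateSE"))

#' @rdname accessors
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' @rdname accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname accessors
#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))

#' @rdname accessors
#' @export
setGeneric("periodGrid", function(x) standardGeneric("periodGrid"))

#' @rdname accessors
#' @export
setGeneric("cohortLayout", function(x) standardGeneric("cohortLayout"))

#' @rdname accessors
#' @export
setGeneric("periodEffects", function(x) standardGeneric("periodEffects"))

#' @rdname accessors
#' @export
setGeneric("cohortEffects", function(x) standardGeneric("cohortEffects"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("hazardTable", function(x) standardGeneric("hazardTable"))

#' @rdname accessors
#' @export
setGeneric("seriesTable", function(x) standardGeneric("seriesTable"))
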