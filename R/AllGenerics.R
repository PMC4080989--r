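#' @rdname indexSum
#' @export
setGeneric("indexSum", function(x, ...) standardGeneric("indexSum"))

#' @rdname estimateICF
#' @export
setGeneric("estimateICF", function(x, effect = 0.5, ...)
  standardGeneric("estimateICF"))

#' @rdname fitHill
#' @export
setGeneric("fitHill", function(x, ...) standardGeneric("fitHill"))

#' @rdname inhibition
#' @export
setGeneric("inhibition", function(x, clipped = FALSE)
  standardGeneric("inhibition"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("drugId", function(x) standardGeneric("drugId"))

#' @rdname accessors
#' @export
setGeneric("tdc", function(x) standardGeneric("tdc"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("replicateCV", function(x) standardGeneric("replicateCV"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("ic90", function(x) standardGeneric("ic90"))

#' @rdname accessors
#' @export
setGeneric("isActive", function(x) standardGeneric("isActive"))

#' @rdname accessors
#' @export
setGeneric("isEstimable", function(x) standardGeneric("isEstimable"))

#' @rdname accessors
#' @export
setGeneric("ciValue", function(x) standardGeneric("ciValue"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
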