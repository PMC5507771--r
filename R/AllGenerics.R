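#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 containers.
#'
#' @param x,object An object.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterInfo", function(x) standardGeneric("clusterInfo"))

#' @rdname accessors
#' @export
setGeneric("q2", function(x) standardGeneric("q2"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))

#' @rdname accessors
#' @export
setGeneric("alignedSpectra", function(x) standardGeneric("alignedSpectra"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' @rdname accessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname accessors
#' @export
setGeneric("associationRho", function(x) standardGeneric("associationRho"))

#' @rdname accessors
#' @export
setGeneric("associationP", function(x) standardGeneric("associationP"))

#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' Re-threshold an association matrix
#'
#' Recomputes the significance mask at a new alpha without recomputing the
#' permutation p-values.
#'
#' @param x An \code{AssociationMatrix}.
#' @param alpha New significance threshold in (0, 1].
#' @return An \code{AssociationMatrix} with an updated mask.
#' @export
setGeneric("setAlpha", function(x, alpha) standardGeneric("setAlpha"))
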