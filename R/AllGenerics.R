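#' Accessors for memdyn classes
#'
#' Small accessor generics: \code{atoms} returns the atom table of a
#' \linkS4class{StructureModel}; \code{models}, \code{modelIds} and
#' \code{nModels} access the members of a \linkS4class{ModelEnsemble};
#' \code{bursts} returns the burst data.frame of a \linkS4class{BurstTable};
#' \code{cloudPoints} the point matrix of a \linkS4class{DyeCloud};
#' \code{gridMean}, \code{gridSD} and \code{gridMask} the statistic matrices
#' of a \linkS4class{ThicknessGrid}.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases atoms models modelIds nModels bursts cloudPoints gridMean gridSD
#'   gridMask
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))
#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("gridMean", function(x) standardGeneric("gridMean"))
#' @rdname accessors
#' @export
setGeneric("gridSD", function(x) standardGeneric("gridSD"))
#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname accessors
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("models", "ModelEnsemble", function(x) x@models)
#' @rdname accessors
setMethod("modelIds", "ModelEnsemble", function(x)
  vapply(x@models, function(m) m@modelId, character(1)))
#' @rdname accessors
setMethod("nModels", "ModelEnsemble", function(x) length(x@models))
#' @rdname accessors
setMethod("bursts", "BurstTable", function(x) x@bursts)
#' @rdname accessors
setMethod("cloudPoints", "DyeCloud", function(x) x@points)
#' @rdname accessors
setMethod("gridMean", "ThicknessGrid", function(x) x@mean)
#' @rdname accessors
setMethod("gridSD", "ThicknessGrid", function(x) x@sd)
#' @rdname accessors
setMethod("gridMask", "ThicknessGrid", function(x) x@mask)
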