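#' @rdname VectorField2D-class
#' @param object a sparseTFM S4 object.
#' @export
setGeneric("xComp", function(object) standardGeneric("xComp"))
#' @rdname VectorField2D-class
#' @export
setGeneric("yComp", function(object) standardGeneric("yComp"))
#' @rdname VectorField2D-class
#' @export
setGeneric("fieldMagnitude",
           function(object) standardGeneric("fieldMagnitude"))
#' @rdname VectorField2D-class
#' @export
setGeneric("fieldSpacing", function(object) standardGeneric("fieldSpacing"))
#' @rdname VectorField2D-class
#' @export
setGeneric("fieldUnits", function(object) standardGeneric("fieldUnits"))

#' @rdname VectorField2D-class
#' @export
setMethod("xComp", "VectorField2D", function(object) object@x)
#' @rdname VectorField2D-class
#' @export
setMethod("yComp", "VectorField2D", function(object) object@y)
#' @rdname VectorField2D-class
#' @export
setMethod("fieldMagnitude", "VectorField2D",
          function(object) sqrt(object@x^2 + object@y^2))
#' @rdname VectorField2D-class
#' @export
setMethod("fieldSpacing", "VectorField2D", function(object) object@spacing)
#' @rdname VectorField2D-class
#' @export
setMethod("fieldUnits", "VectorField2D", function(object) object@units)

#' @rdname StiffnessMatrix-class
#' @param object a sparseTFM S4 object.
#' @export
setGeneric("stiffness", function(object) standardGeneric("stiffness"))
#' @rdname StiffnessMatrix-class
#' @export
setMethod("stiffness", "StiffnessMatrix", function(object) object@matrix)

#' @rdname SolveResult-class
#' @param object a sparseTFM S4 object.
#' @export
setGeneric("tractions", function(object) standardGeneric("tractions"))
#' @rdname SolveResult-class
#' @export
setMethod("tractions", "SolveResult", function(object) object@tractions)
#' @rdname SolveResult-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname SolveResult-class
#' @export
setMethod("converged", "SolveResult", function(object) object@converged)
#' @rdname SolveResult-class
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))
#' @rdname SolveResult-class
#' @export
setMethod("iterations", "SolveResult", function(object) object@iterations)

#' @rdname RegionSet-class
#' @param object a sparseTFM S4 object.
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname RegionSet-class
#' @export
setMethod("regionLabels", "RegionSet", function(object) object@labelImage)
#' @rdname RegionSet-class
#' @export
setGeneric("regionCount", function(object) standardGeneric("regionCount"))
#' @rdname RegionSet-class
#' @export
setMethod("regionCount", "RegionSet", function(object) object@regionCount)
#' @rdname RegionSet-class
#' @export
setGeneric("regionPixels", function(object) standardGeneric("regionPixels"))
#' @rdname RegionSet-class
#' @export
setMethod("regionPixels", "RegionSet", function(object) object@pixels)

#' @rdname FootprintSet-class
#' @param object a sparseTFM S4 object.
#' @export
setGeneric("footprintTable",
           function(object) standardGeneric("footprintTable"))
#' @rdname FootprintSet-class
#' @export
setMethod("footprintTable", "FootprintSet", function(object) object@table)
#' @rdname FootprintSet-class
#' @export
setGeneric("footprintPixels",
           function(object) standardGeneric("footprintPixels"))
#' @rdname FootprintSet-class
#' @export
setMethod("footprintPixels", "FootprintSet", function(object) object@pixels)
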