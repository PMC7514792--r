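#' @describeIn FovMask-class circle center as c(row, col)
#' @param object a retiqa S4 object
#' @export
setGeneric("fovCenter", function(object) standardGeneric("fovCenter"))
#' @describeIn FovMask-class circle radius in pixels
#' @export
setGeneric("fovRadius", function(object) standardGeneric("fovRadius"))
#' @describeIn FovMask-class logical matrix of FOV membership
#' @export
setGeneric("fovInside", function(object) standardGeneric("fovInside"))

#' @describeIn NSSModel-class mean vector of the MVG model
#' @param object a retiqa S4 object
#' @export
setGeneric("nssMean", function(object) standardGeneric("nssMean"))
#' @describeIn NSSModel-class covariance matrix of the MVG model
#' @export
setGeneric("nssCov", function(object) standardGeneric("nssCov"))

#' @describeIn SelectionResult-class names of the selected features
#' @param object a retiqa S4 object
#' @export
setGeneric("selectedFeatures",
           function(object) standardGeneric("selectedFeatures"))
#' @describeIn SelectionResult-class per-feature bootstrap selection counts
#' @export
setGeneric("selectionCounts",
           function(object) standardGeneric("selectionCounts"))

setMethod("fovCenter", "FovMask", function(object)
  c(row = object@centerRow, col = object@centerCol))
setMethod("fovRadius", "FovMask", function(object) object@radius)
setMethod("fovInside", "FovMask", function(object) object@inside)
setMethod("fovCenter", "PreprocessedImage", function(object)
  fovCenter(object@fov))
setMethod("fovRadius", "PreprocessedImage", function(object)
  fovRadius(object@fov))
setMethod("fovInside", "PreprocessedImage", function(object)
  fovInside(object@fov))

setMethod("nssMean", "NSSModel", function(object) object@nu)
setMethod("nssCov", "NSSModel", function(object) object@sigma)

setMethod("selectedFeatures", "SelectionResult",
          function(object) object@selected)
setMethod("selectionCounts", "SelectionResult", function(object)
  setNames(object@counts, object@featureNames))
setMethod("selectedFeatures", "TrainedQualityModel",
          function(object) object@selectedFeatures)

#' Pixel array of a preprocessed image
#'
#' @param object a [PreprocessedImage-class]
#' @return numeric H x W x 3 array on the 0-255 scale.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
setMethod("imagePixels", "PreprocessedImage", function(object) object@pixels)
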