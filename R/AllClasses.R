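#' Circular field-of-view mask
#'
#' Boolean grid plus circle geometry locating the retinal aperture inside the
#' image canvas. The mask is true exactly on the disk of the stated
#' center/radius, clipped to the grid.
#'
#' @slot inside logical matrix, TRUE on FOV pixels.
#' @slot centerRow,centerCol numeric, circle center in pixel coordinates
#'   (1-based, pixel centers at integers).
#' @slot radius numeric, circle radius in pixels.
#' @export
setClass("FovMask",
  representation(inside = "matrix", centerRow = "numeric",
                 centerCol = "numeric", radius = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!is.logical(object@inside)) msg <- c(msg, "'inside' must be logical")
    if (length(object@radius) != 1 || object@radius <= 0)
      msg <- c(msg, "radius must be a single positive number")
    if (!any(object@inside)) msg <- c(msg, "mask has no interior pixel")
    if (is.logical(object@inside) && length(object@radius) == 1 &&
        object@radius > 0) {
      d <- dim(object@inside)
      disk <- outer((seq_len(d[1]) - object@centerRow)^2,
                    (seq_len(d[2]) - object@centerCol)^2, "+") <=
        object@radius^2
      if (!identical(unname(disk), unname(object@inside)))
        msg <- c(msg, "'inside' does not match the stated circle geometry")
    }
    if (length(msg)) msg else TRUE
  })

#' Border-free preprocessed fundus image
#'
#' RGB pixel grid whose FOV border has been removed by iterative FOV
#' extension; pixels inside the original aperture are identical to the source
#' image.
#'
#' @slot pixels numeric H x W x 3 array, values on the 0-255 scale (stored as
#'   doubles; extension averages are not re-quantized).
#' @slot fov [FovMask-class] of the original aperture.
#' @slot extension list with elements `iterations` (dilation steps until the
#'   mask covered the canvas) and `added` (pixels gained per step).
#' @export
setClass("PreprocessedImage",
  representation(pixels = "array", fov = "FovMask", extension = "list"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[3] != 3)
      return("pixels must be an H x W x 3 array")
    if (!identical(d[1:2], dim(object@fov@inside)))
      return("pixels and fov mask differ in spatial shape")
    TRUE
  })

#' Multivariate Gaussian natural-scene statistics model
#'
#' Mean vector and covariance of the 36 per-block NSS parameters (GGD shape
#' and spread of normalized luminance plus AGGD parameters of four neighbor
#' products, at two scales).
#'
#' @slot nu numeric mean vector.
#' @slot sigma covariance matrix (symmetric, positive semi-definite).
#' @slot blockCount integer, number of blocks pooled into the fit.
#' @slot P,T block size (pixels) and sharpness threshold used for block
#'   selection.
#' @export
setClass("NSSModel",
  representation(nu = "numeric", sigma = "matrix", blockCount = "integer",
                 P = "numeric", T = "numeric"),
  validity = function(object) {
    k <- length(object@nu)
    if (!all(dim(object@sigma) == c(k, k)))
      return("sigma dimensions do not match nu")
    if (k > 0) {
      if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
        return("sigma is not symmetric")
      ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1))
        return("sigma is not positive semi-definite")
    }
    TRUE
  })

#' Bootstrap-stabilised FCBF selection result
#'
#' @slot featureNames ordered names of the candidate features.
#' @slot counts integer, number of bootstrap replicates selecting each
#'   feature.
#' @slot selected names with counts >= threshold.
#' @slot B number of replicates; @slot threshold selection count cutoff;
#' @slot seed master seed.
#' @export
setClass("SelectionResult",
  representation(featureNames = "character", counts = "integer",
                 selected = "character", B = "integer", threshold = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@counts) != length(object@featureNames))
      return("counts and featureNames differ in length")
    if (any(object@counts < 0L) || any(object@counts > object@B))
      return("counts must lie in [0, B]")
    if (!all(object@selected %in% object@featureNames))
      return("selected must be a subset of featureNames")
    TRUE
  })

#' Trained quality classifier
#'
#' Selected feature names, training-set standardization, MLP weights
#' (tanh hidden layer, logistic output), convex-blend weight-decay
#' regularization weight, ROC-selected decision threshold and the reference
#' NSS model the `niqe_q` feature was computed against.
#'
#' @slot selectedFeatures ordered feature names the network consumes.
#' @slot center,scale per-feature standardization.
#' @slot W1 input-to-hidden weights (p x nHidden); @slot b1 hidden biases;
#' @slot w2 hidden-to-output weights; @slot b2 output bias.
#' @slot nHidden hidden layer width; @slot eta regularization weight in
#'   \[0, 1); @slot threshold decision threshold in (0, 1).
#' @slot referenceModel [NSSModel-class] (may have length-0 nu when the model
#'   was trained on precomputed features).
#' @slot seed integer training seed; @slot lossTrace recorded loss
#'   checkpoints.
#' @export
setClass("TrainedQualityModel",
  representation(selectedFeatures = "character", center = "numeric",
                 scale = "numeric", W1 = "matrix", b1 = "numeric",
                 w2 = "numeric", b2 = "numeric", nHidden = "integer",
                 eta = "numeric", threshold = "numeric",
                 referenceModel = "NSSModel", seed = "integer",
                 lossTrace = "numeric"),
  validity = function(object) {
    p <- length(object@selectedFeatures)
    if (object@nHidden < 1L) return("nHidden must be >= 1")
    if (!(object@threshold > 0 && object@threshold < 1))
      return("threshold must lie in (0, 1)")
    if (!(object@eta >= 0 && object@eta < 1))
      return("eta must lie in [0, 1)")
    if (!all(dim(object@W1) == c(p, object@nHidden)))
      return("W1 dimensions inconsistent with features/nHidden")
    if (length(object@b1) != object@nHidden ||
        length(object@w2) != object@nHidden || length(object@b2) != 1)
      return("bias/output weight dimensions inconsistent")
    TRUE
  })

setMethod("show", "FovMask", function(object) {
  d <- dim(object@inside)
  cat(sprintf(
    "FovMask: %d x %d grid, center (%.1f, %.1f), radius %.1f px, %d FOV pixels\n",
    d[1], d[2], object@centerRow, object@centerCol, object@radius,
    sum(object@inside)))
})

setMethod("show", "PreprocessedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "PreprocessedImage: %d x %d x 3, FOV radius %.1f px, border removed in %d iterations\n",
    d[1], d[2], object@fov@radius, object@extension$iterations))
})

setMethod("show", "NSSModel", function(object) {
  cat(sprintf(
    "NSSModel: %d-D multivariate Gaussian fitted on %d blocks (P = %g, T = %g)\n",
    length(object@nu), object@blockCount, object@P, object@T))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d/%d features selected on >= %d of %d bootstrap FCBF runs\n",
    length(object@selected), length(object@featureNames), object@threshold,
    object@B))
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "TrainedQualityModel", function(object) {
  cat(sprintf(
    "TrainedQualityModel: %d features -> %d tanh hidden units -> logistic output\n",
    length(object@selectedFeatures), object@nHidden))
  cat(sprintf("  eta = %g, decision threshold = %.4f\n", object@eta,
              object@threshold))
})
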