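#' @include persal-package.R
NULL

## ---- gaze logs ------------------------------------------------------------

.gazeCols <- c("timestamp", "left_x", "left_y", "right_x", "right_y",
               "left_pupil", "right_pupil")

#' GazeLog: one subject viewing one image
#'
#' Ordered binocular eye-tracker samples for a single (subject, image)
#' presentation. Coordinates are 0-based pixels with the origin at the top
#' left (x rightward, y downward); pupil diameters are in millimetres.
#' Missing cells are `NA`, never sentinel zeros, because (0,0) is a valid
#' coordinate.
#'
#' @slot subjectId subject identifier.
#' @slot imageId image identifier.
#' @slot day session-day index (integer >= 1).
#' @slot records `data.frame` with columns `timestamp`, `left_x`, `left_y`,
#'   `right_x`, `right_y`, `left_pupil`, `right_pupil`, sorted by timestamp.
#' @exportClass GazeLog
setClass("GazeLog",
         representation(subjectId = "character", imageId = "character",
                        day = "integer", records = "data.frame"))

setValidity("GazeLog", function(object) {
  r <- object@records
  if (!all(.gazeCols %in% names(r)))
    return(paste("records must have columns:", paste(.gazeCols, collapse = ", ")))
  if (length(object@day) != 1L || is.na(object@day) || object@day < 1L)
    return("day must be a single integer >= 1")
  if (nrow(r) == 0L) return(TRUE)
  ts <- r$timestamp
  if (anyNA(ts) || any(ts < 0)) return("timestamps must be non-missing and >= 0")
  if (is.unsorted(ts)) return("records must be sorted by timestamp")
  for (cc in c("left_pupil", "right_pupil")) {
    v <- r[[cc]]
    if (any(!is.na(v) & v <= 0)) return(sprintf("%s must be > 0 when present", cc))
  }
  for (cc in c("left_x", "left_y", "right_x", "right_y")) {
    v <- r[[cc]]
    if (any(!is.na(v) & !is.finite(v)))
      return(sprintf("%s must be finite when present", cc))
  }
  TRUE
})

#' Construct a GazeLog
#'
#' @param subjectId,imageId identifiers.
#' @param records data.frame of samples (see [GazeLog-class]).
#' @param day session-day index.
#' @return A [GazeLog-class] object.
#' @examples
#' rec <- data.frame(timestamp = c(0, 0.02),
#'                   left_x = c(100, NA), left_y = c(200, NA),
#'                   right_x = c(110, NA), right_y = c(210, NA),
#'                   left_pupil = c(3.1, NA), right_pupil = c(3.3, NA))
#' GazeLog("s1", "img1", rec)
#' @export
GazeLog <- function(subjectId, imageId, records, day = 1L) {
  records <- as.data.frame(records)[, .gazeCols]
  for (cc in .gazeCols) records[[cc]] <- as.numeric(records[[cc]])
  new("GazeLog", subjectId = as.character(subjectId),
      imageId = as.character(imageId), day = as.integer(day),
      records = records)
}

## ---- fixation grids and saliency maps -------------------------------------

#' CountGrid: per-cell fixation counts
#'
#' Integer counts of gaze samples landing in each pixel cell. Rows index y
#' (top to bottom), columns index x. Samples that were missing or fell out of
#' bounds are dropped from the grid but tallied in `nMissing` /
#' `nOutOfBounds`, so `sum(counts) + nMissing + nOutOfBounds` equals the
#' number of input samples.
#'
#' @slot counts integer matrix (height x width).
#' @slot nMissing number of dropped missing samples.
#' @slot nOutOfBounds number of dropped out-of-bounds samples.
#' @exportClass CountGrid
setClass("CountGrid",
         representation(counts = "matrix", nMissing = "integer",
                        nOutOfBounds = "integer"))

setValidity("CountGrid", function(object) {
  ct <- object@counts
  if (!is.numeric(ct)) return("counts must be numeric")
  if (any(ct < 0) || any(ct != round(ct))) return("counts must be non-negative integers")
  TRUE
})

#' SaliencyMap: normalized gaze-density grid
#'
#' A heat map over image pixels. Measured maps (`kind` "PSM" or "USM") lie
#' in [0,1]; under the default max normalization the peak is exactly 1
#' whenever any gaze was recorded, while sum normalization gives total mass
#' 1 instead. Model outputs (`kind` "predicted") are only constrained to be
#' non-negative, since the network's final ReLU does not bound them above.
#'
#' @slot values numeric matrix (height x width).
#' @slot kind one of "PSM", "USM", "predicted".
#' @exportClass SaliencyMap
setClass("SaliencyMap",
         representation(values = "matrix", kind = "character"))

setValidity("SaliencyMap", function(object) {
  v <- object@values
  if (!object@kind %in% c("PSM", "USM", "predicted"))
    return("kind must be PSM, USM or predicted")
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be >= 0")
  if (object@kind != "predicted" && any(v > 1 + 1e-12))
    return("measured map values must be <= 1")
  TRUE
})

#' Construct a SaliencyMap
#' @param values numeric matrix, rows = y, columns = x.
#' @param kind "PSM", "USM" or "predicted".
#' @return A [SaliencyMap-class] object.
#' @export
SaliencyMap <- function(values, kind = c("PSM", "USM", "predicted")) {
  kind <- match.arg(kind)
  new("SaliencyMap", values = as.matrix(values), kind = kind)
}

#' FixationSet: binary fixation locations for one image
#'
#' Deduplicated in-bounds gaze cells used as the ground-truth side of the
#' AUC-type metrics. Coordinates are 0-based pixel cells.
#'
#' @slot imageId image identifier.
#' @slot points integer matrix with columns x, y.
#' @slot width,height grid dimensions in pixels.
#' @exportClass FixationSet
setClass("FixationSet",
         representation(imageId = "character", points = "matrix",
                        width = "integer", height = "integer"))

setValidity("FixationSet", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (x, y)")
  if (nrow(p) > 0L) {
    if (any(p[, 1] < 0 | p[, 1] >= object@width |
            p[, 2] < 0 | p[, 2] >= object@height))
      return("points must be in bounds")
    if (anyDuplicated(p)) return("points must be deduplicated per cell")
  }
  TRUE
})

## ---- interest -------------------------------------------------------------

#' AnomalyThreshold: chi-squared cutoff for pupil anomalies
#'
#' Two-sided anomaly region of total mass `alpha` for a standardized
#' (univariate Mahalanobis) pupil diameter: the squared distance cutoff is
#' the chi-squared(df = 1) quantile at 1 - alpha, and `zUpper = sqrt(aSq)`
#' is the dilation-side threshold actually used for interest labels.
#'
#' @slot alpha significance level in (0,1).
#' @slot aSq squared-distance cutoff.
#' @slot zUpper,zLower +/- sqrt(aSq).
#' @exportClass AnomalyThreshold
setClass("AnomalyThreshold",
         representation(alpha = "numeric", aSq = "numeric",
                        zUpper = "numeric", zLower = "numeric"))

setValidity("AnomalyThreshold", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@aSq < 0) return("aSq must be >= 0")
  if (abs(object@zUpper + object@zLower) > 1e-12)
    return("zUpper must equal -zLower")
  TRUE
})

#' InterestVector: binary per-image interest labels for one subject
#'
#' Entry m is 1 when the subject's pupil dilated anomalously while viewing
#' image m. The image order is fixed and shared across subjects so vectors
#' are comparable.
#'
#' @slot subjectId subject identifier.
#' @slot entries integer vector of 0/1, one per image.
#' @slot imageIds image identifiers, parallel to `entries`.
#' @slot flagged ids of images with no usable pupil data (entry forced to 0).
#' @exportClass InterestVector
setClass("InterestVector",
         representation(subjectId = "character", entries = "integer",
                        imageIds = "character", flagged = "character"))

setValidity("InterestVector", function(object) {
  if (length(object@entries) != length(object@imageIds))
    return("entries and imageIds must have equal length")
  if (!all(object@entries %in% c(0L, 1L))) return("entries must be 0/1")
  TRUE
})

## ---- model ----------------------------------------------------------------

#' PsmModelConfig: architecture hyperparameters
#'
#' Shared configuration of the universal (USM) and personalized (PSM)
#' saliency models. `channelScale` scales every convolutional depth so tiny
#' desk-scale instances and the full-width instance (final channel count
#' C = 512) run the identical graph.
#'
#' @slot inputSize integer c(width, height) of the model input, divisible
#'   by 16 (four 2x2 poolings).
#' @slot channelScale fraction of the reference depths; C = round(512 * scale).
#' @slot M length of the user interest vector.
#' @slot encLayers Transformer-encoder depth of the user-encoding mechanism
#'   (0 = identity).
#' @slot decLayers Transformer-decoder depth fusing image and user features.
#' @slot heads attention head count; C must be divisible by it.
#' @slot seed integer seed for weight initialization.
#' @slot logitScale "sqrt_dk" (default) or "dk" attention logit scaling.
#' @slot positional add learned positional embeddings to the feature tokens.
#' @slot decoderSelfAttn include self-attention among feature tokens in each
#'   Transformer-decoder layer.
#' @slot ffMult feed-forward expansion factor.
#' @exportClass PsmModelConfig
setClass("PsmModelConfig",
         representation(inputSize = "integer", channelScale = "numeric",
                        M = "integer", encLayers = "integer",
                        decLayers = "integer", heads = "integer",
                        seed = "integer", logitScale = "character",
                        positional = "logical", decoderSelfAttn = "logical",
                        ffMult = "numeric"))

setValidity("PsmModelConfig", function(object) {
  if (length(object@inputSize) != 2L || any(object@inputSize %% 16L != 0L))
    return("inputSize must be c(width, height), each divisible by 16; pad the input to the next multiple of 16")
  C <- max(1L, as.integer(round(512 * object@channelScale)))
  if (C %% object@heads != 0L)
    return(sprintf("channel count C = %d must be divisible by heads = %d", C, object@heads))
  if (C %/% object@heads < 1L) return("per-head dimension d_k must be >= 1")
  if (object@encLayers < 0L) return("encLayers must be >= 0")
  if (object@decLayers < 1L) return("decLayers must be >= 1")
  if (object@M < 1L) return("M must be >= 1")
  if (!object@logitScale %in% c("sqrt_dk", "dk"))
    return("logitScale must be 'sqrt_dk' or 'dk'")
  TRUE
})

#' Build a model configuration
#'
#' Defaults are the full-scale reference architecture: final channel depth
#' C = 512, user vector length M = 800, four Transformer-encoder layers,
#' nine Transformer-decoder layers and 256 heads.
#'
#' @param inputSize c(width, height), divisible by 16.
#' @param channelScale depth multiplier (1 = full width, C = 512).
#' @param M user-vector length.
#' @param encLayers,decLayers,heads Transformer shape.
#' @param seed initialization seed.
#' @param logitScale attention logit scaling, "sqrt_dk" or "dk".
#' @param positional learned positional embeddings for feature tokens.
#' @param decoderSelfAttn include token self-attention in decoder layers.
#' @param ffMult feed-forward expansion factor.
#' @return A [PsmModelConfig-class] object.
#' @examples
#' cfg <- psmConfig(c(32, 32), channelScale = 1 / 16, encLayers = 1,
#'                  decLayers = 1, heads = 4, M = 16)
#' headDim(cfg)
#' @export
psmConfig <- function(inputSize = c(480L, 272L), channelScale = 1,
                      M = 800L, encLayers = 4L, decLayers = 9L,
                      heads = 256L, seed = 1L, logitScale = "sqrt_dk",
                      positional = FALSE, decoderSelfAttn = TRUE,
                      ffMult = 4) {
  new("PsmModelConfig", inputSize = as.integer(inputSize),
      channelScale = channelScale, M = as.integer(M),
      encLayers = as.integer(encLayers), decLayers = as.integer(decLayers),
      heads = as.integer(heads), seed = as.integer(seed),
      logitScale = logitScale, positional = positional,
      decoderSelfAttn = decoderSelfAttn, ffMult = ffMult)
}

#' FeatureTensor: encoder output
#'
#' Convolutional features of shape (height/16, width/16, C), viewable
#' losslessly as a (W*H) x C matrix whose row i is the pixel with 0-based
#' x = (i-1) %% W, y = (i-1) %/% W (x fastest).
#'
#' @slot values numeric array (h, w, C).
#' @exportClass FeatureTensor
setClass("FeatureTensor", representation(values = "array"))

#' UserToken: encoded user characteristics
#'
#' The 1 x C output of the user-encoding mechanism (Linear embedding plus
#' Transformer encoder), consumed as Key/Value by the cross-attention.
#'
#' @slot values 1 x C numeric matrix.
#' @exportClass UserToken
setClass("UserToken", representation(values = "matrix"))

setValidity("UserToken", function(object) {
  if (nrow(object@values) != 1L) return("a user token has exactly one row")
  TRUE
})

#' SaliencyModel: USM or PSM network
#'
#' Container for the network weights (a flat named list of arrays), the
#' configuration, and the stage: "USM" models run encoder -> decoder only;
#' "PSM" models insert the Transformer fusion conditioned on a user token.
#'
#' @slot params named list of weight arrays.
#' @slot config a [PsmModelConfig-class].
#' @slot stage "USM" or "PSM".
#' @slot arch derived layer plan (internal).
#' @exportClass SaliencyModel
setClass("SaliencyModel",
         representation(params = "list", config = "PsmModelConfig",
                        stage = "character", arch = "list"))

## ---- synthetic world ------------------------------------------------------

#' SyntheticWorld: planted ground truth for the simulator
#'
#' Defines the study conditions the simulator draws from: procedural stimuli
#' with center-concentrated objects, a per-subject interest matrix over
#' object categories, central-bias gaze, Gaussian baseline pupil diameter
#' with interest-driven dilation, and optional per-day baseline shifts.
#'
#' @slot nSubjects,nImages corpus dimensions.
#' @slot imageSize c(width, height) of the stimuli in pixels.
#' @slot objects data.frame of object layouts (image, x, y, size, category,
#'   salience).
#' @slot interestMatrix nSubjects x nCategories non-negative weights.
#' @slot centralBiasSigma SD (pixels) of the central gaze component.
#' @slot centralWeight mixture weight of the central component.
#' @slot interestGain gaze-weight gain per unit interest.
#' @slot samplesPerImage gaze samples per presentation.
#' @slot presentationSeconds presentation duration.
#' @slot pupilBaseMean,pupilBaseSd per-subject baseline pupil diameter (mm).
#' @slot dilationDelta dilation amplitude in baseline-SD units.
#' @slot dilationWindow fraction of samples covered by the dilation window.
#' @slot interestThreshold minimum category weight that makes a subject
#'   interested in an image containing that category.
#' @slot dayAssignment list, per subject, of the day index of each image.
#' @slot dayShift baseline shift per additional day, in SD units.
#' @slot eyeJitterSd per-eye coordinate jitter SD (pixels).
#' @slot missingRate probability a sample is lost (both eyes missing).
#' @slot seed master seed.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
         representation(nSubjects = "integer", nImages = "integer",
                        imageSize = "integer", objects = "data.frame",
                        interestMatrix = "matrix",
                        centralBiasSigma = "numeric", centralWeight = "numeric",
                        interestGain = "numeric", samplesPerImage = "integer",
                        presentationSeconds = "numeric",
                        pupilBaseMean = "numeric", pupilBaseSd = "numeric",
                        dilationDelta = "numeric", dilationWindow = "numeric",
                        interestThreshold = "numeric", dayAssignment = "list",
                        dayShift = "numeric", eyeJitterSd = "numeric",
                        missingRate = "numeric", seed = "integer"))

setValidity("SyntheticWorld", function(object) {
  if (any(object@pupilBaseSd <= 0)) return("pupil baseline SDs must be > 0")
  if (object@samplesPerImage < 1L) return("samplesPerImage must be >= 1")
  if (any(object@interestMatrix < 0)) return("interest weights must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0,1)")
  TRUE
})
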