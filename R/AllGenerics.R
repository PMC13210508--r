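#' @include AllClasses.R
NULL

#' Accessors for persal classes
#'
#' Small accessor generics so slots are never reached into directly:
#' `subjectId`, `imageId`, `sessionDay`, `gazeRecords` and `nRecords` for
#' [GazeLog-class]; `gridCounts` for [CountGrid-class]; `mapValues` and
#' `mapKind` for [SaliencyMap-class]; `interestEntries` and
#' `interestImageIds` for [InterestVector-class]; `fixationPoints` for
#' [FixationSet-class]; `modelConfig`, `modelStage` and `modelParams` for
#' [SaliencyModel-class]; `featureValues` for [FeatureTensor-class] and
#' `tokenValues` for [UserToken-class].
#'
#' @param x an object of the documented class.
#' @return The slot content (see above).
#' @name accessors
#' @examples
#' m <- SaliencyMap(matrix(c(0, 1, 0.5, 0.25), 2), "PSM")
#' mapKind(m)
#' dim(mapValues(m))
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("sessionDay", function(x) standardGeneric("sessionDay"))
#' @rdname accessors
#' @export
setGeneric("gazeRecords", function(x) standardGeneric("gazeRecords"))
#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname accessors
#' @export
setGeneric("gridCounts", function(x) standardGeneric("gridCounts"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))
#' @rdname accessors
#' @export
setGeneric("interestEntries", function(x) standardGeneric("interestEntries"))
#' @rdname accessors
#' @export
setGeneric("interestImageIds", function(x) standardGeneric("interestImageIds"))
#' @rdname accessors
#' @export
setGeneric("fixationPoints", function(x) standardGeneric("fixationPoints"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("modelStage", function(x) standardGeneric("modelStage"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("tokenValues", function(x) standardGeneric("tokenValues"))

#' Merge binocular samples into cyclopean gaze points
#'
#' Collapses the two eyes of each record into one gaze point and one pupil
#' diameter: when both eyes are present the per-field arithmetic mean is
#' taken; when only one eye is valid its values pass through; when neither
#' is, the sample is missing. An eye's coordinate counts as present only if
#' both its x and y are present. The merged coordinate is missing iff both
#' eyes are missing, and likewise for the pupil (the two conditions are
#' independent).
#'
#' @param x a [GazeLog-class] or a data.frame of gaze records.
#' @return A data.frame with columns `timestamp`, `x`, `y`, `pupil` (one row
#'   per input record, `NA` where missing).
#' @examples
#' rec <- data.frame(timestamp = 0, left_x = 100, left_y = 200,
#'                   right_x = 110, right_y = 210,
#'                   left_pupil = 3.0, right_pupil = 3.4)
#' mergeBinocular(rec)   # xy (105, 205), pupil 3.2
#' @export
setGeneric("mergeBinocular", function(x) standardGeneric("mergeBinocular"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
setMethod("subjectId", "GazeLog", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "InterestVector", function(x) x@subjectId)
#' @rdname accessors
setMethod("imageId", "GazeLog", function(x) x@imageId)
#' @rdname accessors
setMethod("imageId", "FixationSet", function(x) x@imageId)
#' @rdname accessors
setMethod("sessionDay", "GazeLog", function(x) x@day)
#' @rdname accessors
setMethod("gazeRecords", "GazeLog", function(x) x@records)
#' @rdname accessors
setMethod("nRecords", "GazeLog", function(x) nrow(x@records))
#' @rdname accessors
setMethod("gridCounts", "CountGrid", function(x) x@counts)
#' @rdname accessors
setMethod("mapValues", "SaliencyMap", function(x) x@values)
#' @rdname accessors
setMethod("mapKind", "SaliencyMap", function(x) x@kind)
#' @rdname accessors
setMethod("interestEntries", "InterestVector", function(x) x@entries)
#' @rdname accessors
setMethod("interestImageIds", "InterestVector", function(x) x@imageIds)
#' @rdname accessors
setMethod("fixationPoints", "FixationSet", function(x) x@points)
#' @rdname accessors
setMethod("modelConfig", "SaliencyModel", function(x) x@config)
#' @rdname accessors
setMethod("modelStage", "SaliencyModel", function(x) x@stage)
#' @rdname accessors
setMethod("modelParams", "SaliencyModel", function(x) x@params)
#' @rdname accessors
setMethod("featureValues", "FeatureTensor", function(x) x@values)
#' @rdname accessors
setMethod("tokenValues", "UserToken", function(x) x@values)

## ---- show methods ---------------------------------------------------------

setMethod("show", "GazeLog", function(object) {
  r <- object@records
  ok <- sum(!is.na(r$left_x) | !is.na(r$right_x))
  cat(sprintf("GazeLog: subject %s, image %s, day %d\n", object@subjectId,
              object@imageId, object@day))
  cat(sprintf("  %d records (%d with at least one valid eye)", nrow(r), ok))
  if (nrow(r) > 0L && ok == 0L) cat("  [entirely missing]")
  cat("\n")
})

setMethod("show", "CountGrid", function(object) {
  cat(sprintf("CountGrid %dx%d: %d fixations (%d missing, %d out of bounds dropped)\n",
              ncol(object@counts), nrow(object@counts), sum(object@counts),
              object@nMissing, object@nOutOfBounds))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap [%s] %dx%d, values in [%.3g, %.3g]\n", object@kind,
              ncol(object@values), nrow(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "AnomalyThreshold", function(object) {
  cat(sprintf("AnomalyThreshold: alpha = %g, a^2 = %.4f, z in [%.4f, %.4f]\n",
              object@alpha, object@aSq, object@zLower, object@zUpper))
})

setMethod("show", "InterestVector", function(object) {
  cat(sprintf("InterestVector: subject %s, %d images, %d labelled interesting",
              object@subjectId, length(object@entries), sum(object@entries)))
  if (length(object@flagged)) cat(sprintf(" (%d flagged missing)", length(object@flagged)))
  cat("\n")
})

setMethod("show", "FixationSet", function(object) {
  cat(sprintf("FixationSet: image %s, %d cells on %dx%d\n", object@imageId,
              nrow(object@points), object@width, object@height))
})

setMethod("show", "PsmModelConfig", function(object) {
  C <- max(1L, as.integer(round(512 * object@channelScale)))
  cat(sprintf("PsmModelConfig: input %dx%d, C = %d (scale %.4g), M = %d\n",
              object@inputSize[1], object@inputSize[2], C,
              object@channelScale, object@M))
  cat(sprintf("  Transformer: %d encoder / %d decoder layers, %d heads (d_k = %d)\n",
              object@encLayers, object@decLayers, object@heads,
              C %/% object@heads))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld: %d subjects x %d images (%dx%d px), %d samples / %.3g s\n",
              object@nSubjects, object@nImages, object@imageSize[1],
              object@imageSize[2], object@samplesPerImage,
              object@presentationSeconds))
  cat(sprintf("  %d object categories, dilation %.3g SD over %.0f%% window, seed %d\n",
              ncol(object@interestMatrix), object@dilationDelta,
              100 * object@dilationWindow, object@seed))
})
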