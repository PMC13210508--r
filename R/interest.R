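#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Chi-squared anomaly threshold for standardized pupil diameters
#'
#' The Mahalanobis distance of a univariate standardized value z is |z|, so
#' its square follows a chi-squared distribution with one degree of freedom
#' under normality. The two-sided anomaly region of total mass `alpha` is
#' `z^2 >= aSq` with `aSq` the chi-squared(1) quantile at `1 - alpha`;
#' interest labels use only the upper (dilation) side `z >= sqrt(aSq)`.
#'
#' @param alpha significance level in (0,1); the study compares 0.01 and
#'   0.10 and adopts 0.10.
#' @return An [AnomalyThreshold-class].
#' @examples
#' anomalyThreshold(0.10)  # aSq ~ 2.7055, zUpper ~ 1.6449
#' anomalyThreshold(0.01)  # aSq ~ 6.6349
#' @export
anomalyThreshold <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  aSq <- qchisq(1 - alpha, df = 1)
  new("AnomalyThreshold", alpha = alpha, aSq = aSq,
      zUpper = sqrt(aSq), zLower = -sqrt(aSq))
}

#' Standardize pupil diameters per subject (optionally per day)
#'
#' Pools every sample a subject produced over all images in a group (the
#' whole session, or one session day when `perDay = TRUE`) and transforms
#' each diameter to `z = (d - mean) / SD` with the population SD. Per-day
#' grouping removes session-to-session baseline shifts that otherwise make
#' the pooled distribution bimodal; it is switched on explicitly rather
#' than auto-detected.
#'
#' @param samples data.frame with columns `subject_id`, `image_id`, `day`,
#'   `pupil` (one row per merged sample; `NA` pupils are dropped).
#' @param perDay standardize within subject-day groups instead of subjects.
#' @return The input rows with non-missing pupils, plus a `z` column.
#' @examples
#' d <- data.frame(subject_id = "s", image_id = c("a", "b"), day = 1,
#'                 pupil = c(2, 4))
#' standardizePupil(d)$z  # -1, +1 (population SD)
#' @export
standardizePupil <- function(samples, perDay = FALSE) {
  need <- c("subject_id", "image_id", "day", "pupil")
  stopifnot(all(need %in% names(samples)))
  samples <- samples[!is.na(samples$pupil), , drop = FALSE]
  grp <- if (perDay) paste(samples$subject_id, samples$day, sep = "\r")
         else as.character(samples$subject_id)
  z <- numeric(nrow(samples))
  for (g in unique(grp)) {
    sel <- grp == g
    v <- samples$pupil[sel]
    if (length(v) < 2L)
      stop("group ", gsub("\r", " day ", g), " has fewer than 2 pupil samples")
    s <- popSd(v)
    if (s == 0)
      stop("group ", gsub("\r", " day ", g), " has zero pupil variance; cannot standardize")
    z[sel] <- (v - mean(v)) / s
  }
  samples$z <- z
  samples
}

#' Label one image from its standardized pupil series
#'
#' Dilation-only rule: constriction is detected by the two-sided test but
#' never labels an image interesting. `mode = "any"` flags the image when
#' any standardized sample reaches the upper threshold; `"fraction"` when
#' at least a fraction `fraction` of samples do. Image-level mean testing
#' (the package default for whole corpora) lives in
#' [buildInterestVector()], which needs all of a subject's images at once.
#'
#' @param z numeric vector of standardized samples for one image.
#' @param threshold an [AnomalyThreshold-class].
#' @param mode "any" or "fraction".
#' @param fraction minimum exceedance fraction for `mode = "fraction"`.
#' @return 0L or 1L (empty series: 0L with a warning).
#' @examples
#' thr <- anomalyThreshold(0.10)
#' labelImage(c(0, 0.5, 3.0), thr)   # 1
#' labelImage(c(-3, -3, -3), thr)    # 0: enlargement only
#' @export
labelImage <- function(z, threshold, mode = c("any", "fraction"),
                       fraction = 0.15) {
  mode <- match.arg(mode)
  if (length(z) == 0L) {
    warning("empty pupil series; labelling 0")
    return(0L)
  }
  hits <- z >= threshold@zUpper
  switch(mode, any = as.integer(any(hits)),
         fraction = as.integer(mean(hits) >= fraction))
}

#' Build a subject's binary interest vector
#'
#' Applies the pupil anomaly test over a fixed, shared image order and
#' emits one 0/1 entry per image for each subject present in `samples`.
#'
#' Aggregation over time within an image is configurable:
#' \describe{
#'   \item{"mean" (default)}{each image is summarized by its mean pupil
#'     diameter; the per-image means are standardized across the subject's
#'     images (within days when `perDay`) and an image is labelled 1 when
#'     its mean is anomalously large. This rule is calibrated at the image
#'     level: under the null, each image is flagged with probability
#'     alpha/2 regardless of how many samples a presentation contains.}
#'   \item{"any"}{per-sample standardization, flag if any sample exceeds
#'     the threshold. With hundreds of samples per image the family-wise
#'     null exceedance probability approaches 1, so this reading is only
#'     useful for strongly autocorrelated series or very short windows.}
#'   \item{"fraction"}{per-sample standardization, flag if at least
#'     `fraction` of samples exceed the threshold.}
#' }
#'
#' @param samples data.frame with columns `subject_id`, `image_id`, `day`,
#'   `pupil` (one row per merged sample).
#' @param imageIds fixed image order; defaults to order of first appearance
#'   in `samples`.
#' @param alpha significance level of the anomaly test.
#' @param mode "mean", "any" or "fraction" (see Details).
#' @param perDay standardize within subject-day groups.
#' @param fraction exceedance fraction for `mode = "fraction"`.
#' @return A list of [InterestVector-class], one per subject (in order of
#'   first appearance). Images with no usable samples get entry 0 and are
#'   recorded in the vector's `flagged` slot.
#' @export
buildInterestVector <- function(samples, imageIds = NULL, alpha = 0.10,
                                mode = c("mean", "any", "fraction"),
                                perDay = FALSE, fraction = 0.15) {
  mode <- match.arg(mode)
  thr <- anomalyThreshold(alpha)
  if (is.null(imageIds)) imageIds <- unique(as.character(samples$image_id))
  imageIds <- as.character(imageIds)
  subjects <- unique(as.character(samples$subject_id))
  lapply(subjects, function(s) {
    sub <- samples[samples$subject_id == s & !is.na(samples$pupil), , drop = FALSE]
    entries <- integer(length(imageIds))
    flagged <- character(0)
    if (mode == "mean") {
      mu <- tapply(sub$pupil, as.character(sub$image_id), mean)
      dayOf <- tapply(sub$day, as.character(sub$image_id), function(d) d[1L])
      present <- imageIds %in% names(mu)
      flagged <- imageIds[!present]
      ids <- imageIds[present]
      m <- as.numeric(mu[ids])
      grp <- if (perDay) as.numeric(dayOf[ids]) else rep(1, length(ids))
      zi <- numeric(length(m))
      for (g in unique(grp)) {
        sel <- grp == g
        if (sum(sel) < 2L || popSd(m[sel]) == 0)
          stop("subject ", s, ": need >= 2 images with distinct mean pupil per group")
        zi[sel] <- (m[sel] - mean(m[sel])) / popSd(m[sel])
      }
      entries[present] <- as.integer(zi >= thr@zUpper)
    } else {
      std <- standardizePupil(sub, perDay = perDay)
      zByImage <- split(std$z, as.character(std$image_id))
      for (i in seq_along(imageIds)) {
        z <- zByImage[[imageIds[i]]]
        if (is.null(z)) {
          flagged <- c(flagged, imageIds[i])
          entries[i] <- 0L
        } else {
          entries[i] <- labelImage(z, thr, mode = mode, fraction = fraction)
        }
      }
    }
    new("InterestVector", subjectId = s, entries = entries,
        imageIds = imageIds, flagged = flagged)
  })
}

#' Write / read interest vectors as CSV
#'
#' Long format `subject_id,image_id,label`, one row per subject-image.
#'
#' @param vectors list of [InterestVector-class].
#' @param path CSV path.
#' @return `writeInterestVectors()`: `path` invisibly;
#'   `readInterestVectors()`: a list of [InterestVector-class].
#' @export
writeInterestVectors <- function(vectors, path) {
  rows <- do.call(rbind, lapply(vectors, function(v) {
    data.frame(subject_id = subjectId(v), image_id = interestImageIds(v),
               label = interestEntries(v))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeInterestVectors
#' @export
readInterestVectors <- function(path) {
  rows <- read.csv(path, colClasses = c(subject_id = "character",
                                        image_id = "character",
                                        label = "integer"))
  lapply(unique(rows$subject_id), function(s) {
    sub <- rows[rows$subject_id == s, , drop = FALSE]
    new("InterestVector", subjectId = s, entries = sub$label,
        imageIds = sub$image_id, flagged = character(0))
  })
}
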