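#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Build a fixation set from merged gaze samples
#'
#' Takes the raw in-bounds gaze cells (0-based pixels) and deduplicates
#' them per cell; this binary set — not the smoothed map — is the ground
#' truth for the AUC-type metrics.
#'
#' @param samples data.frame with `x`, `y` columns, or a 2-column matrix.
#' @param width,height grid size in pixels.
#' @param imageId identifier carried along.
#' @return A [FixationSet-class].
#' @export
fixationSet <- function(samples, width, height, imageId = "") {
  p <- if (is.matrix(samples)) samples else cbind(samples$x, samples$y)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  p <- floor(p)
  inb <- p[, 1] >= 0 & p[, 1] < width & p[, 2] >= 0 & p[, 2] < height
  p <- unique(p[inb, , drop = FALSE])
  storage.mode(p) <- "integer"
  colnames(p) <- c("x", "y")
  new("FixationSet", imageId = as.character(imageId), points = p,
      width = as.integer(width), height = as.integer(height))
}

.mapAt <- function(values, points) {
  values[cbind(points[, 2] + 1L, points[, 1] + 1L)]
}

.asValues <- function(map) if (is(map, "SaliencyMap")) mapValues(map) else as.matrix(map)

#' Normalized scanpath saliency
#'
#' Standardizes the map to mean 0 and population SD 1 over all cells and
#' returns the mean standardized value at the fixation cells; large
#' positive values mean fixations land on salient peaks. A constant map
#' has zero SD and NSS is defined as 0; NSS is invariant to affine
#' rescaling `a * map + b` (a > 0).
#'
#' @param map a [SaliencyMap-class] or matrix.
#' @param fix a [FixationSet-class].
#' @return NSS value (NA if the fixation set is empty, with a warning).
#' @export
nss <- function(map, fix) {
  v <- .asValues(map)
  p <- fixationPoints(fix)
  if (nrow(p) == 0L) {
    warning("empty fixation set")
    return(NA_real_)
  }
  s <- popSd(v)
  if (s == 0) return(0)
  z <- (v - mean(v)) / s
  mean(.mapAt(z, p))
}

#' Pearson correlation between two saliency maps
#'
#' @param mapA,mapB same-size maps (or matrices); both must be
#'   non-constant, otherwise NA is returned with a warning.
#' @return Correlation in [-1, 1].
#' @export
cc <- function(mapA, mapB) {
  a <- .asValues(mapA); b <- .asValues(mapB)
  if (!all(dim(a) == dim(b))) stop("maps must have the same dimensions")
  if (popSd(a) == 0 || popSd(b) == 0) {
    warning("correlation undefined for a constant map")
    return(NA_real_)
  }
  cor(as.vector(a), as.vector(b))
}

## Mann-Whitney AUC with ties counted 1/2, via midranks.
.aucMW <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' AUC-Borji: fixations vs uniform random locations
#'
#' Ranks the map values at fixated cells against values at uniformly
#' random cells; ties count 1/2 (Mann-Whitney). Averaged over `nSplits`
#' random negative draws. Monotone under any strictly increasing
#' transform of the map.
#'
#' @param map a [SaliencyMap-class] or matrix.
#' @param fix a [FixationSet-class].
#' @param nRand negatives per split (default: number of fixations).
#' @param nSplits number of random splits.
#' @param seed RNG seed.
#' @return AUC in [0, 1].
#' @export
aucBorji <- function(map, fix, nRand = NULL, nSplits = 100, seed = 1) {
  v <- .asValues(map)
  p <- fixationPoints(fix)
  if (nrow(p) == 0L) stop("fixation set is empty")
  pos <- .mapAt(v, p)
  if (is.null(nRand)) nRand <- length(pos)
  withSeed(seed, {
    mean(vapply(seq_len(nSplits), function(i) {
      neg <- v[sample.int(length(v), nRand, replace = TRUE)]
      .aucMW(pos, neg)
    }, numeric(1)))
  })
}

#' Shuffled AUC: fixations vs other-image fixations
#'
#' As [aucBorji()], but negatives are sampled from fixation locations of
#' other images (the shuffled null). Because human fixations and photo
#' composition are both center-biased, a pure central-bias map scores near
#' chance here, while it can score high against uniform negatives; sAUC
#' therefore discounts the central bias.
#'
#' @param map a [SaliencyMap-class] or matrix.
#' @param fix a [FixationSet-class] for the evaluated image.
#' @param otherFix a [FixationSet-class], list of them, or 2-column matrix
#'   of pooled fixation cells from other images.
#' @param nRand negatives per split (default: number of fixations).
#' @param nSplits number of random splits.
#' @param seed RNG seed.
#' @return AUC in [0, 1].
#' @export
shuffledAuc <- function(map, fix, otherFix, nRand = NULL, nSplits = 100,
                        seed = 1) {
  v <- .asValues(map)
  p <- fixationPoints(fix)
  if (nrow(p) == 0L) stop("fixation set is empty")
  pool <- if (is(otherFix, "FixationSet")) fixationPoints(otherFix)
          else if (is.list(otherFix)) do.call(rbind, lapply(otherFix, fixationPoints))
          else as.matrix(otherFix)
  if (is.null(pool) || nrow(pool) == 0L) stop("other-image fixation pool is empty")
  pos <- .mapAt(v, p)
  if (is.null(nRand)) nRand <- length(pos)
  withSeed(seed, {
    mean(vapply(seq_len(nSplits), function(i) {
      neg <- .mapAt(v, pool[sample.int(nrow(pool), nRand, replace = TRUE), , drop = FALSE])
      .aucMW(pos, neg)
    }, numeric(1)))
  })
}

#' Cosine similarity between two saliency maps
#'
#' Cosine of the flattened maps; in [0, 1] for non-negative maps. Used for
#' the subject-by-subject PSM comparisons.
#'
#' @param mapA,mapB same-size maps (or matrices).
#' @return Similarity in [0, 1], NA (with warning) if a map is all zero.
#' @export
mapCosine <- function(mapA, mapB) {
  a <- .asValues(mapA); b <- .asValues(mapB)
  if (!all(dim(a) == dim(b))) stop("maps must have the same dimensions")
  cosineSimilarity(as.vector(a), as.vector(b))
}

#' Metric table over a set of predictions
#'
#' Convenience wrapper producing one row per evaluated image (or
#' subject-image) with sAUC, AUC-B, NSS and CC columns plus a mean row,
#' mirroring the usual saliency-benchmark layout.
#'
#' @param preds named list of predicted maps.
#' @param fixes named list of [FixationSet-class], same names.
#' @param truths optional named list of ground-truth maps (for CC).
#' @param nSplits,seed passed to the AUC metrics.
#' @return data.frame with columns id, sAUC, AUC_B, NSS, CC.
#' @export
evalMetrics <- function(preds, fixes, truths = NULL, nSplits = 25, seed = 1) {
  ids <- names(preds)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[[i]]
    others <- do.call(rbind, lapply(fixes[setdiff(ids, id)], fixationPoints))
    data.frame(id = id,
               sAUC = shuffledAuc(preds[[id]], fixes[[id]], others,
                                  nSplits = nSplits, seed = mixSeed(seed, i, 1)),
               AUC_B = aucBorji(preds[[id]], fixes[[id]],
                                nSplits = nSplits, seed = mixSeed(seed, i, 2)),
               NSS = nss(preds[[id]], fixes[[id]]),
               CC = if (is.null(truths)) NA_real_ else cc(preds[[id]], truths[[id]]))
  })
  out <- do.call(rbind, rows)
  means <- data.frame(id = "mean", sAUC = mean(out$sAUC), AUC_B = mean(out$AUC_B),
                      NSS = mean(out$NSS), CC = mean(out$CC))
  rbind(out, means)
}
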