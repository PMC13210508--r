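#' @include AllClasses.R AllGenerics.R saliency.R interest.R train.R
NULL

#' Generate a synthetic study world
#'
#' Builds the planted ground truth the simulator draws from. Defaults are
#' the reference study conditions: 8 subjects viewing 1000 images on a
#' 1920x1080 display, 300 gaze/pupil samples per 5 s presentation, pupil
#' dilation of 2.5 baseline-SD during a contiguous 40% window on images
#' the subject is interested in, and two subjects (2 and 8) whose session
#' spans two days with a 3 SD baseline shift on day 2.
#'
#' Objects are placed with a center-concentrated distribution (photo
#' composition), carry a category and a base salience, and each subject's
#' row of the interest matrix holds one primary category at weight 1 plus
#' a shared secondary at 0.4 and small background weights; with 16
#' categories and 2 objects per image a subject's primary category appears
#' in roughly 12% of images. A subject is "interested" in an image when
#' their maximum category weight among its objects exceeds
#' `interestThreshold`.
#'
#' @param nSubjects,nImages corpus dimensions.
#' @param imageSize c(width, height) in pixels.
#' @param nCategories number of object categories.
#' @param objectsPerImage objects per stimulus.
#' @param samplesPerImage gaze samples per presentation.
#' @param presentationSeconds presentation duration (s).
#' @param centralBiasSigma SD of the central gaze component (pixels;
#'   default 18% of the smaller image side).
#' @param centralWeight mixture weight of the central component.
#' @param interestGain gaze-weight gain per unit of category interest.
#' @param dilationDelta pupil dilation amplitude in baseline-SD units.
#' @param dilationWindow fraction of samples covered by the dilation.
#' @param interestThreshold category weight above which dilation is
#'   planted.
#' @param twoDaySubjects indices of subjects measured over two days.
#' @param dayShift baseline pupil shift on day 2, in SD units.
#' @param eyeJitterSd per-eye coordinate jitter SD (pixels).
#' @param missingRate probability a sample is lost (blink/track loss).
#' @param interestMatrix optional explicit nSubjects x nCategories matrix
#'   overriding the planted one.
#' @param seed master seed; the same seed reproduces the world and every
#'   log bit-for-bit.
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- generateWorld(nSubjects = 2, nImages = 4, imageSize = c(64, 64),
#'                    seed = 7)
#' nRecords(sampleGaze(w, 1, 1))
#' @export
generateWorld <- function(nSubjects = 8, nImages = 1000,
                          imageSize = c(1920, 1080), nCategories = 16,
                          objectsPerImage = 2, samplesPerImage = 300,
                          presentationSeconds = 5,
                          centralBiasSigma = 0.18 * min(imageSize),
                          centralWeight = 1.2, interestGain = 1.0,
                          dilationDelta = 2.5, dilationWindow = 0.4,
                          interestThreshold = 0.5,
                          twoDaySubjects = intersect(c(2, 8), seq_len(nSubjects)),
                          dayShift = 3, eyeJitterSd = 2, missingRate = 0.02,
                          interestMatrix = NULL, seed = 1) {
  withSeed(mixSeed(seed, 0, 0), {
    W <- imageSize[1]; H <- imageSize[2]
    nObj <- nImages * objectsPerImage
    objects <- data.frame(
      image = rep(seq_len(nImages), each = objectsPerImage),
      x = pmin(pmax(rnorm(nObj, W / 2, 0.22 * W), 0.08 * W), 0.92 * W),
      y = pmin(pmax(rnorm(nObj, H / 2, 0.22 * H), 0.08 * H), 0.92 * H),
      size = runif(nObj, 0.08, 0.15) * min(W, H),
      category = sample.int(nCategories, nObj, replace = TRUE),
      salience = runif(nObj, 0.2, 0.6))
    if (is.null(interestMatrix)) {
      interestMatrix <- matrix(runif(nSubjects * nCategories, 0, 0.15),
                               nSubjects, nCategories)
      primary <- ((seq_len(nSubjects) - 1) %% nCategories) + 1
      secondary <- (primary %% nCategories) + 1
      for (s in seq_len(nSubjects)) {
        interestMatrix[s, primary[s]] <- 1
        interestMatrix[s, secondary[s]] <- 0.4
      }
    }
    dayAssignment <- lapply(seq_len(nSubjects), function(s) {
      d <- rep(1L, nImages)
      if (s %in% twoDaySubjects) d[seq_len(nImages) > nImages / 2] <- 2L
      d
    })
    new("SyntheticWorld", nSubjects = as.integer(nSubjects),
        nImages = as.integer(nImages), imageSize = as.integer(imageSize),
        objects = objects, interestMatrix = interestMatrix,
        centralBiasSigma = centralBiasSigma, centralWeight = centralWeight,
        interestGain = interestGain,
        samplesPerImage = as.integer(samplesPerImage),
        presentationSeconds = presentationSeconds,
        pupilBaseMean = runif(nSubjects, 3.0, 4.0),
        pupilBaseSd = rep(0.2, nSubjects),
        dilationDelta = dilationDelta, dilationWindow = dilationWindow,
        interestThreshold = interestThreshold,
        dayAssignment = dayAssignment, dayShift = dayShift,
        eyeJitterSd = eyeJitterSd, missingRate = missingRate,
        seed = as.integer(seed))
  })
}

#' Planted ground truth: which images interest a subject
#'
#' TRUE for images containing at least one object whose category weight
#' for the subject exceeds the world's interest threshold — the truth the
#' pupil pipeline should recover.
#'
#' @param world a [SyntheticWorld-class].
#' @param subject subject index.
#' @return Logical vector of length `nImages`.
#' @export
interestedImages <- function(world, subject) {
  w <- world@interestMatrix[subject, world@objects$category]
  best <- tapply(w, world@objects$image, max)
  out <- rep(FALSE, world@nImages)
  out[as.integer(names(best))] <- best > world@interestThreshold
  out
}

#' Simulate the pupil-diameter series for one presentation
#'
#' Baseline diameters are Gaussian around the subject's mean (shifted on
#' later session days); when the subject is interested in the image, a
#' dilation of `dilationDelta` baseline-SD is added over a contiguous
#' window covering `dilationWindow` of the samples (interest is phasic,
#' not sustained — this also makes any-exceedance and mean-based labeling
#' distinguishable).
#'
#' @param world a [SyntheticWorld-class].
#' @param subject,image indices.
#' @return Numeric vector of `samplesPerImage` diameters (mm).
#' @export
samplePupil <- function(world, subject, image) {
  n <- world@samplesPerImage
  day <- world@dayAssignment[[subject]][image]
  withSeed(mixSeed(world@seed, subject, image), {
    mu <- world@pupilBaseMean[subject] +
      (day - 1) * world@dayShift * world@pupilBaseSd[subject]
    p <- rnorm(n, mu, world@pupilBaseSd[subject])
    if (interestedImages(world, subject)[image]) {
      len <- max(1L, round(world@dilationWindow * n))
      start <- sample.int(n - len + 1L, 1L)
      p[start:(start + len - 1L)] <- p[start:(start + len - 1L)] +
        world@dilationDelta * world@pupilBaseSd[subject]
    }
    p
  })
}

#' Simulate a gaze log for one presentation
#'
#' Gaze points are drawn from a mixture of a central Gaussian (central
#' bias) and one Gaussian per object, weighted by base salience plus the
#' subject's interest in the object's category; each eye adds independent
#' jitter, and a small fraction of samples is lost entirely (both eyes
#' missing). Pupil columns come from [samplePupil()] plus tiny per-eye
#' measurement noise, so the log carries everything downstream modules
#' need.
#'
#' @param world a [SyntheticWorld-class].
#' @param subject,image indices.
#' @return A [GazeLog-class] with `samplesPerImage` records.
#' @export
sampleGaze <- function(world, subject, image) {
  n <- world@samplesPerImage
  W <- world@imageSize[1]; H <- world@imageSize[2]
  obj <- world@objects[world@objects$image == image, , drop = FALSE]
  pupil <- samplePupil(world, subject, image)
  withSeed(mixSeed(world@seed, subject + 10000L, image), {
    wts <- c(world@centralWeight,
             obj$salience + world@interestGain *
               world@interestMatrix[subject, obj$category])
    comp <- sample.int(length(wts), n, replace = TRUE, prob = wts)
    cx <- c(W / 2, obj$x)[comp]
    cy <- c(H / 2, obj$y)[comp]
    sdv <- c(world@centralBiasSigma, obj$size / 2)[comp]
    gx <- rnorm(n, cx, sdv)
    gy <- rnorm(n, cy, sdv)
    jit <- function() rnorm(n, 0, world@eyeJitterSd)
    rec <- data.frame(timestamp = seq(0, world@presentationSeconds, length.out = n),
                      left_x = gx + jit(), left_y = gy + jit(),
                      right_x = gx + jit(), right_y = gy + jit(),
                      left_pupil = pmax(pupil + rnorm(n, 0, 0.02), 0.1),
                      right_pupil = pmax(pupil + rnorm(n, 0, 0.02), 0.1))
    lost <- runif(n) < world@missingRate
    rec[lost, c("left_x", "left_y", "right_x", "right_y",
                "left_pupil", "right_pupil")] <- NA_real_
    GazeLog(sprintf("s%d", subject), sprintf("img%04d", image), rec,
            day = world@dayAssignment[[subject]][image])
  })
}

#' Render a procedural stimulus
#'
#' Stimuli are procedural rather than photographic: a textured mid-grey
#' background with one filled disc per object, colored by category. The
#' model consumes only pixel arrays, and procedural objects give exact
#' ground-truth object masks for free.
#'
#' @param world a [SyntheticWorld-class].
#' @param image image index.
#' @param size optional c(width, height) to render at (default the world's
#'   image size); object geometry scales along.
#' @return (height, width, 3) array in [0, 1].
#' @export
renderStimulus <- function(world, image, size = NULL) {
  if (is.null(size)) size <- world@imageSize
  W <- size[1]; H <- size[2]
  fx <- W / world@imageSize[1]; fy <- H / world@imageSize[2]
  nCat <- ncol(world@interestMatrix)
  withSeed(mixSeed(world@seed, 20000L, image), {
    img <- array(0.5 + 0.04 * rnorm(H * W), c(H, W, 3))
    pal <- cbind(0.5 + 0.5 * cos(2 * pi * seq_len(nCat) / nCat),
                 0.5 + 0.5 * cos(2 * pi * seq_len(nCat) / nCat + 2),
                 0.5 + 0.5 * cos(2 * pi * seq_len(nCat) / nCat + 4))
    obj <- world@objects[world@objects$image == image, , drop = FALSE]
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 0.5, W), H, W)
    for (i in seq_len(nrow(obj))) {
      r <- obj$size[i] / 2 * sqrt(fx * fy)
      mask <- (xs - obj$x[i] * fx)^2 + (ys - obj$y[i] * fy)^2 <= r^2
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask] <- pal[obj$category[i], ch]
        img[, , ch] <- pl
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Enumerate the corpus without materializing it
#'
#' One row per (subject, image) presentation with the session day and the
#' planted interest label — the full reference world yields 8 x 1000 =
#' 8000 rows, the size of the PSM training corpus.
#'
#' @param world a [SyntheticWorld-class].
#' @return data.frame with subject_id, image_id, day, label.
#' @export
corpusManifest <- function(world) {
  rows <- expand.grid(image = seq_len(world@nImages),
                      subject = seq_len(world@nSubjects))
  data.frame(subject_id = sprintf("s%d", rows$subject),
             image_id = sprintf("img%04d", rows$image),
             day = vapply(seq_len(nrow(rows)), function(i)
               world@dayAssignment[[rows$subject[i]]][rows$image[i]], integer(1)),
             label = vapply(seq_len(nrow(rows)), function(i)
               as.integer(interestedImages(world, rows$subject[i])[rows$image[i]]),
               integer(1)))
}

#' Build a full synthetic corpus
#'
#' Runs the whole pipeline on a (sub)world: simulates gaze logs, builds
#' per-subject PSMs and the aggregated USM for every image, extracts
#' interest vectors from the pupil series (per-day standardization, since
#' the world contains two-day subjects), renders stimuli at map
#' resolution, and assembles the (image, interest vector, PSM) training
#' triples with a stratified split.
#'
#' @param world a [SyntheticWorld-class].
#' @param subjects,images optional index subsets (defaults: all).
#' @param mapSize c(width, height) of stimuli and maps (default the world
#'   image size); must be divisible by 16 to feed the model.
#' @param kernelSize,sigma smoothing parameters at map resolution;
#'   defaults scale the reference smoothing (sigma 24 at 1080p, i.e. 2.2%
#'   of the short side, floor 3) with a kernel truncated at 3.5 sigma.
#' @param alpha significance level for interest extraction.
#' @param trainFrac,seed split parameters.
#' @return list with `stimuli`, `logs` (logs[[s]][[m]]), `psm`
#'   (psm[[s]][[m]]), `usm` (per image), `interest` (list of
#'   [InterestVector-class]), `labels`, `split`, `samples` — the list of
#'   PSM training samples (image, target, iVec, subject_id, image_id)
#'   aligned with `labels` — plus the `mapSize` / `imageSize` used, so
#'   downstream consumers can rescale gaze coordinates.
#' @export
buildCorpus <- function(world, subjects = NULL, images = NULL, mapSize = NULL,
                        kernelSize = NULL, sigma = NULL, alpha = 0.10,
                        trainFrac = 0.8, seed = 1) {
  if (is.null(subjects)) subjects <- seq_len(world@nSubjects)
  if (is.null(images)) images <- seq_len(world@nImages)
  if (is.null(mapSize)) mapSize <- world@imageSize
  if (is.null(sigma)) sigma <- max(3, round(0.022 * min(mapSize)))
  if (is.null(kernelSize)) kernelSize <- 2 * ceiling(3.5 * sigma) + 1
  sx <- mapSize[1] / world@imageSize[1]
  sy <- mapSize[2] / world@imageSize[2]

  logs <- lapply(subjects, function(s) lapply(images, function(m) sampleGaze(world, s, m)))
  stimuli <- lapply(images, function(m) renderStimulus(world, m, size = mapSize))

  grids <- lapply(seq_along(subjects), function(si) lapply(seq_along(images), function(mi) {
    sm <- mergeBinocular(logs[[si]][[mi]])
    sm$x <- sm$x * sx; sm$y <- sm$y * sy
    countFixations(sm, mapSize[1], mapSize[2])
  }))
  psm <- lapply(grids, function(gs) lapply(gs, smoothToMap,
                                           kernelSize = kernelSize, sigma = sigma))
  usm <- lapply(seq_along(images), function(mi)
    aggregateUsm(lapply(grids, `[[`, mi), kernelSize = kernelSize, sigma = sigma))

  pupilRows <- do.call(rbind, lapply(seq_along(subjects), function(si)
    do.call(rbind, lapply(seq_along(images), function(mi) {
      lg <- logs[[si]][[mi]]
      data.frame(subject_id = subjectId(lg), image_id = imageId(lg),
                 day = sessionDay(lg), pupil = mergeBinocular(lg)$pupil)
    }))))
  imageIds <- sprintf("img%04d", images)
  interest <- buildInterestVector(pupilRows, imageIds = imageIds, alpha = alpha,
                                  perDay = TRUE)

  labels <- do.call(rbind, lapply(seq_along(subjects), function(si)
    data.frame(subject_id = sprintf("s%d", subjects[si]), image_id = imageIds,
               label = interestEntries(interest[[si]]))))
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    si <- match(labels$subject_id[i], sprintf("s%d", subjects))
    mi <- match(labels$image_id[i], imageIds)
    list(image = stimuli[[mi]], target = mapValues(psm[[si]][[mi]]),
         iVec = as.numeric(interestEntries(interest[[si]])),
         subject_id = labels$subject_id[i], image_id = labels$image_id[i])
  })
  split <- splitDataset(cbind(labels, idx = seq_len(nrow(labels))),
                        trainFrac = trainFrac, seed = seed)
  list(stimuli = stimuli, logs = logs, psm = psm, usm = usm,
       interest = interest, labels = labels, samples = samples, split = split,
       mapSize = as.integer(mapSize), imageSize = world@imageSize)
}
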