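test_that("the default world matches the reference study structure", {
  w <- generateWorld()
  expect_equal(w@nSubjects, 8L)
  expect_equal(w@nImages, 1000L)
  expect_equal(w@samplesPerImage, 300L)
  expect_equal(w@presentationSeconds, 5)
  expect_equal(w@imageSize, c(1920L, 1080L))
  man <- corpusManifest(w)
  expect_equal(nrow(man), 8000L)
  # two-day subjects mirror the study; others are single-day
  expect_setequal(unique(man$day[man$subject_id == "s2"]), c(1L, 2L))
  expect_equal(unique(man$day[man$subject_id == "s3"]), 1L)
})

test_that("worlds and logs are bit-identical under the same seed", {
  w1 <- generateWorld(nSubjects = 3, nImages = 5, imageSize = c(64, 64), seed = 33)
  w2 <- generateWorld(nSubjects = 3, nImages = 5, imageSize = c(64, 64), seed = 33)
  expect_identical(w1@objects, w2@objects)
  expect_identical(w1@interestMatrix, w2@interestMatrix)
  expect_identical(gazeRecords(sampleGaze(w1, 2, 4)), gazeRecords(sampleGaze(w2, 2, 4)))
  expect_identical(samplePupil(w1, 1, 3), samplePupil(w2, 1, 3))
  w3 <- generateWorld(nSubjects = 3, nImages = 5, imageSize = c(64, 64), seed = 34)
  expect_false(identical(w1@objects, w3@objects))
})

test_that("a zero-object world is pure central bias", {
  w <- generateWorld(nSubjects = 1, nImages = 2, imageSize = c(200, 200),
                     objectsPerImage = 0, missingRate = 0, seed = 35)
  expect_equal(nrow(w@objects), 0L)
  m <- mergeBinocular(sampleGaze(w, 1, 1))
  se <- w@centralBiasSigma / sqrt(nrow(m))
  expect_lt(abs(mean(m$x) - 100), 3 * se)
  expect_lt(abs(mean(m$y) - 100), 3 * se)
})

test_that("interest pulls gaze toward the preferred object", {
  # one left-placed object of category 1; subject 1 loves it, subject 2 neutral
  im <- matrix(c(1, 0.05), 2, 1)
  w <- generateWorld(nSubjects = 2, nImages = 1, imageSize = c(200, 100),
                     objectsPerImage = 1, nCategories = 1, missingRate = 0,
                     interestMatrix = im, seed = 36)
  w@objects$x <- 40; w@objects$y <- 50; w@objects$category <- 1L
  mA <- mergeBinocular(sampleGaze(w, 1, 1))
  mB <- mergeBinocular(sampleGaze(w, 2, 1))
  expect_gt(mean(mA$x < 100), mean(mB$x < 100))
})

test_that("gaze frequencies follow the specified mixture density", {
  # one subject, one image, many samples; coarse 6x6 binning chi-squared GOF
  w <- generateWorld(nSubjects = 1, nImages = 1, imageSize = c(120, 120),
                     objectsPerImage = 2, samplesPerImage = 100000,
                     missingRate = 0, eyeJitterSd = 0, seed = 37)
  m <- mergeBinocular(sampleGaze(w, 1, 1))
  obj <- w@objects
  wts <- c(w@centralWeight, obj$salience + w@interestGain *
             w@interestMatrix[1, obj$category])
  wts <- wts / sum(wts)
  mus <- rbind(c(60, 60), cbind(obj$x, obj$y))
  sds <- c(w@centralBiasSigma, obj$size / 2)
  breaks <- seq(0, 120, by = 20)
  cellP <- function(mu, sd) {
    px <- diff(pnorm(breaks, mu[1], sd))
    py <- diff(pnorm(breaks, mu[2], sd))
    outer(py, px)
  }
  expP <- Reduce(`+`, lapply(seq_along(wts), function(k) wts[k] * cellP(mus[k, ], sds[k])))
  keep <- !is.na(m$x) & m$x >= 0 & m$x < 120 & m$y >= 0 & m$y < 120
  obs <- table(factor(findInterval(m$y[keep], breaks, rightmost.closed = TRUE), 1:6),
               factor(findInterval(m$x[keep], breaks, rightmost.closed = TRUE), 1:6))
  expCounts <- expP / sum(expP) * sum(obs)
  stat <- sum((obs - expCounts)^2 / expCounts)
  # 35 df; not rejected at the 0.1% level
  expect_lt(stat, qchisq(0.999, 35))
})

test_that("baseline pupils are Gaussian and dilation is planted where intended", {
  w0 <- generateWorld(nSubjects = 1, nImages = 1000, imageSize = c(64, 64),
                      dilationDelta = 0, seed = 38)
  p <- unlist(lapply(1:1000, function(m) samplePupil(w0, 1, m)))
  z <- (p - mean(p)) / sd(p)
  expect_equal(length(p), 3e5)
  expect_lt(abs(mean(z^3)), 0.1)        # skew
  expect_lt(abs(excessKurtosis(z)), 0.2)
  # with dilation on, only interested images shift their means
  w1 <- generateWorld(nSubjects = 2, nImages = 50, imageSize = c(64, 64), seed = 39)
  truth <- interestedImages(w1, 1)
  mus <- vapply(1:50, function(m) mean(samplePupil(w1, 1, m)), numeric(1))
  if (any(truth) && any(!truth)) {
    gap <- mean(mus[truth]) - mean(mus[!truth])
    expect_equal(gap, w1@dilationDelta * w1@dilationWindow * w1@pupilBaseSd[1],
                 tolerance = 0.25)
  }
})

test_that("interest-vector similarity is higher for subjects sharing planted categories", {
  # planted rate must stay moderate (one object, 8 categories: ~12%) or the
  # cross-image standardization saturates and nothing is flagged
  im <- matrix(0.05, 3, 8)
  im[1, 1] <- 1; im[2, 1] <- 1; im[3, 5] <- 1  # subjects 1,2 share; 3 differs
  w <- generateWorld(nSubjects = 3, nImages = 150, imageSize = c(64, 64),
                     nCategories = 8, objectsPerImage = 1, interestMatrix = im,
                     twoDaySubjects = integer(0), seed = 40)
  rows <- do.call(rbind, lapply(1:3, function(s) do.call(rbind, lapply(1:150, function(m)
    data.frame(subject_id = sprintf("s%d", s), image_id = sprintf("i%03d", m),
               day = 1, pupil = samplePupil(w, s, m))))))
  vs <- buildInterestVector(rows, sprintf("i%03d", 1:150), alpha = 0.10)
  sim <- similarityMatrix(vs)
  expect_gt(sim["s1", "s2"], sim["s1", "s3"])
  expect_gt(sim["s1", "s2"], sim["s2", "s3"])
})

test_that("PSM similarity falls as interest matrices diverge", {
  mkSim <- function(im, seed) {
    w <- generateWorld(nSubjects = 2, nImages = 6, imageSize = c(64, 64),
                       nCategories = 2, objectsPerImage = 2, interestMatrix = im,
                       centralWeight = 0.4, twoDaySubjects = integer(0), seed = seed)
    mean(vapply(1:6, function(m) {
      maps <- lapply(1:2, function(s) {
        sm <- mergeBinocular(sampleGaze(w, s, m))
        mapValues(smoothToMap(countFixations(sm, 64, 64), 15, 3))
      })
      mapCosine(maps[[1]], maps[[2]])
    }, numeric(1)))
  }
  same <- matrix(c(1, 1, 0, 0), 2, 2)        # identical interests
  mild <- matrix(c(1, 0.5, 0, 0.5), 2, 2)    # partial overlap
  opp <- matrix(c(1, 0, 0, 1), 2, 2)         # disjoint interests
  sims <- c(mkSim(same, 41), mkSim(mild, 41), mkSim(opp, 41))
  expect_gt(sims[1], sims[2])
  expect_gt(sims[2], sims[3])
})

test_that("a tiny corpus assembles every artifact consistently and reproducibly", {
  t0 <- Sys.time()
  # the 4x8 corpus has subjects with no positive labels, so the stratified
  # split legitimately warns about its best effort
  corpus <- suppressWarnings(
    buildCorpus(generateWorld(nSubjects = 4, nImages = 8,
                              imageSize = c(64, 64), seed = 42),
                mapSize = c(32, 32), seed = 1))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
  expect_length(corpus$samples, 32L)          # subjects x images triples
  expect_length(corpus$usm, 8L)
  expect_equal(dim(corpus$stimuli[[1]]), c(32, 32, 3))
  expect_equal(dim(mapValues(corpus$psm[[2]][[3]])), c(32, 32))
  expect_equal(nrow(corpus$split$train) + nrow(corpus$split$val), 32L)
  # PSM targets align with the labels table
  expect_equal(corpus$samples[[5]]$subject_id, corpus$labels$subject_id[5])
  expect_equal(length(corpus$samples[[1]]$iVec), 8L)
  # regeneration under the same seed is bit-identical
  corpus2 <- suppressWarnings(
    buildCorpus(generateWorld(nSubjects = 4, nImages = 8,
                              imageSize = c(64, 64), seed = 42),
                mapSize = c(32, 32), seed = 1))
  expect_identical(mapValues(corpus$psm[[1]][[2]]), mapValues(corpus2$psm[[1]][[2]]))
  expect_identical(corpus$labels, corpus2$labels)
  expect_identical(corpus$stimuli[[4]], corpus2$stimuli[[4]])
})
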