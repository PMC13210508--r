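test_that("standardization matches the two-point case and its definition", {
  d <- data.frame(subject_id = "s", image_id = c("a", "b"), day = 1,
                  pupil = c(2, 4))
  expect_equal(standardizePupil(d)$z, c(-1, 1))
  set.seed(8)
  big <- data.frame(subject_id = "s", image_id = sample(letters, 500, TRUE),
                    day = 1, pupil = rnorm(500, 3.5, 0.3))
  z <- standardizePupil(big)$z
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
})

test_that("degenerate pupil groups are rejected with a diagnostic", {
  flat <- data.frame(subject_id = "s", image_id = "a", day = 1, pupil = rep(3, 5))
  expect_error(standardizePupil(flat), "variance")
  single <- data.frame(subject_id = "s", image_id = "a", day = 1, pupil = 3)
  expect_error(standardizePupil(single), "fewer than 2")
})

test_that("chi-squared thresholds match the df = 1 inverse CDF", {
  t10 <- anomalyThreshold(0.10)
  expect_equal(t10@aSq, 2.7055, tolerance = 1e-4)
  expect_equal(t10@zUpper, qnorm(0.95), tolerance = 1e-10)
  expect_equal(anomalyThreshold(0.01)@aSq, 6.6349, tolerance = 1e-4)
  expect_lt(anomalyThreshold(0.999)@aSq, 2e-6)  # alpha -> 1 shrinks to 0
  expect_equal(t10@zLower, -t10@zUpper)
})

test_that("image labels follow the dilation-only rule", {
  thr <- anomalyThreshold(0.10)
  expect_identical(labelImage(rep(0, 10), thr), 0L)
  expect_identical(labelImage(c(0, 0.2, 3.0), thr), 1L)
  expect_identical(labelImage(rep(-3, 10), thr), 0L)  # constriction never labels
  expect_warning(out <- labelImage(numeric(0), thr), "empty")
  expect_identical(out, 0L)
  expect_identical(labelImage(c(rep(0, 9), 2), thr, mode = "fraction", fraction = 0.5), 0L)
  expect_identical(labelImage(c(rep(2, 6), rep(0, 4)), thr, mode = "fraction", fraction = 0.5), 1L)
})

test_that("the two-sided per-sample anomaly rate converges to alpha", {
  set.seed(101)
  z <- rnorm(1e5)
  for (alpha in c(0.10, 0.01)) {
    thr <- anomalyThreshold(alpha)
    # binomial consistency at a strict level so a legitimate draw never fails
    expect_gt(binom.test(sum(z^2 >= thr@aSq), 1e5, alpha)$p.value, 1e-4)
    expect_gt(binom.test(sum(z >= thr@zUpper), 1e5, alpha / 2)$p.value, 1e-4)
  }
})

test_that("mean-mode interest vectors recover a planted shift", {
  # independent of the simulator: plant a mean shift on known images
  set.seed(21)
  nImg <- 200; n <- 100
  planted <- sort(sample(nImg, 20))
  rows <- do.call(rbind, lapply(seq_len(nImg), function(m) {
    mu <- 3.2 + if (m %in% planted) 0.2 else 0   # 1 SD shift in the mean
    data.frame(subject_id = "s1", image_id = sprintf("i%03d", m), day = 1,
               pupil = rnorm(n, mu, 0.2))
  }))
  iv <- buildInterestVector(rows, imageIds = sprintf("i%03d", seq_len(nImg)),
                            alpha = 0.10, mode = "mean")[[1]]
  hits <- which(interestEntries(iv) == 1)
  expect_gte(length(intersect(hits, planted)) / max(1, length(hits)), 0.9)
  expect_gte(length(intersect(hits, planted)) / length(planted), 0.9)
})

test_that("raising alpha never turns a 1-label into a 0-label", {
  set.seed(22)
  rows <- do.call(rbind, lapply(1:60, function(m)
    data.frame(subject_id = "s1", image_id = sprintf("i%02d", m), day = 1,
               pupil = rnorm(50, 3.2 + 0.15 * (m %% 5 == 0), 0.2))))
  ids <- sprintf("i%02d", 1:60)
  for (mode in c("mean", "any")) {
    v01 <- interestEntries(buildInterestVector(rows, ids, alpha = 0.01, mode = mode)[[1]])
    v10 <- interestEntries(buildInterestVector(rows, ids, alpha = 0.10, mode = mode)[[1]])
    expect_true(all(v10 >= v01))
  }
})

test_that("interest vectors are invariant to constant baseline offsets", {
  set.seed(23)
  rows <- do.call(rbind, lapply(1:40, function(m)
    data.frame(subject_id = "s1", image_id = sprintf("i%02d", m), day = 1,
               pupil = rnorm(60, 3 + 0.25 * (m <= 6), 0.2))))
  shifted <- rows
  shifted$pupil <- shifted$pupil + 1.7
  ids <- sprintf("i%02d", 1:40)
  for (mode in c("mean", "any", "fraction")) {
    expect_identical(
      interestEntries(buildInterestVector(rows, ids, mode = mode)[[1]]),
      interestEntries(buildInterestVector(shifted, ids, mode = mode)[[1]]))
  }
})

test_that("identical pupil records give identical vectors; absent images are flagged 0", {
  set.seed(24)
  base <- do.call(rbind, lapply(1:20, function(m)
    data.frame(image_id = sprintf("i%02d", m), day = 1,
               pupil = rnorm(40, 3 + 0.3 * (m <= 3), 0.2))))
  rows <- rbind(cbind(subject_id = "sA", base), cbind(subject_id = "sB", base))
  ids <- sprintf("i%02d", 1:21)  # i21 never observed
  vs <- buildInterestVector(rows, ids)
  expect_identical(interestEntries(vs[[1]]), interestEntries(vs[[2]]))
  expect_equal(vs[[1]]@flagged, "i21")
  expect_identical(interestEntries(vs[[1]])[21], 0L)
})

test_that("per-day standardization removes a planted day-two baseline shift", {
  set.seed(25)
  rows <- do.call(rbind, lapply(1:80, function(m)
    data.frame(subject_id = "s1", image_id = sprintf("i%02d", m),
               day = ifelse(m <= 40, 1, 2),
               pupil = rnorm(100, ifelse(m <= 40, 3, 3.6), 0.2))))
  zGlobal <- standardizePupil(rows, perDay = FALSE)$z
  zPerDay <- standardizePupil(rows, perDay = TRUE)$z
  # global pooling is bimodal (strongly platykurtic); per-day is Gaussian
  expect_lt(abs(excessKurtosis(zPerDay)), 0.2)
  expect_lt(excessKurtosis(zGlobal), -0.5)
  # under per-sample labelling the day shift floods day-2 labels unless
  # standardization is per day
  ids <- sprintf("i%02d", 1:80)
  vGlobal <- buildInterestVector(rows, ids, perDay = FALSE, mode = "any")[[1]]
  expect_gt(sum(interestEntries(vGlobal)[41:80]), 20)
  # the calibrated mean rule stays near its nominal alpha/2 rate per day
  vPerDay <- buildInterestVector(rows, ids, perDay = TRUE, mode = "mean")[[1]]
  expect_lt(sum(interestEntries(vPerDay)), 12)
})

test_that("cosine similarity matches closed forms and flags zero vectors", {
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_warning(s <- cosineSimilarity(c(0, 0), c(1, 1)), "zero")
  expect_true(is.na(s))
})

test_that("interest similarity matrices are symmetric with unit diagonal", {
  vs <- list(new("InterestVector", subjectId = "a", entries = c(1L, 1L, 0L),
                 imageIds = c("1", "2", "3"), flagged = character(0)),
             new("InterestVector", subjectId = "b", entries = c(1L, 0L, 1L),
                 imageIds = c("1", "2", "3"), flagged = character(0)))
  m <- similarityMatrix(vs)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m["a", "b"], 0.5)
  f <- tempfile(fileext = ".csv")
  writeInterestVectors(vs, f)
  back <- readInterestVectors(f)
  expect_identical(interestEntries(back[[2]]), interestEntries(vs[[2]]))
})
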