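## Shared fixtures (memoized per test run) and independent oracles.

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## 4 subjects x 12 images, 64x64 stimuli; enough structure for end-to-end runs.
tinyWorld <- function() fixture("tinyWorld", function()
  generateWorld(nSubjects = 4, nImages = 12, imageSize = c(64, 64), seed = 11))

tinyCorpus <- function() fixture("tinyCorpus", function()
  buildCorpus(tinyWorld(), mapSize = c(16, 16), seed = 11))

tinyConfig <- function(seed = 1, ...)
  do.call(psmConfig, utils::modifyList(
    list(inputSize = c(16, 16), channelScale = 1 / 16, encLayers = 1,
         decLayers = 1, heads = 4, M = 12, seed = seed),
    list(...)))

randomRecords <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(timestamp = sort(runif(n, 0, 5)),
             left_x = runif(n, 0, 64), left_y = runif(n, 0, 64),
             right_x = runif(n, 0, 64), right_y = runif(n, 0, 64),
             left_pupil = runif(n, 2, 5), right_pupil = runif(n, 2, 5))
}

## Brute-force truncated-Gaussian convolution (zero padding), double loop.
bruteSmooth <- function(counts, kernelSize, sigma, normalize = "max") {
  if (kernelSize %% 2 == 0) kernelSize <- kernelSize + 1
  k1 <- dnorm(seq(-(kernelSize - 1) / 2, (kernelSize - 1) / 2), sd = sigma)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- (kernelSize - 1) / 2
  H <- nrow(counts); W <- ncol(counts)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + counts[ii, jj] * k2[di + h + 1, dj + h + 1]
    }
    out[i, j] <- acc
  }
  tot <- if (normalize == "max") max(out) else sum(out)
  if (tot > 0) out / tot else out
}

## Exhaustive Mann-Whitney AUC: pairwise comparisons, ties counted 1/2.
bruteAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

excessKurtosis <- function(x) mean((x - mean(x))^4) / (mean((x - mean(x))^2)^2) - 3
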