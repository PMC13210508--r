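test_that("configuration validity enforces the dimension algebra", {
  expect_error(psmConfig(c(30, 32), channelScale = 1 / 16, heads = 4),
               "divisible by 16")
  expect_error(psmConfig(c(32, 32), channelScale = 1 / 16, heads = 5),
               "divisible by heads")
  # full width with 512 heads: one-dimensional queries/keys/values
  expect_equal(headDim(psmConfig(c(32, 32), channelScale = 1, heads = 512L)), 1L)
  expect_equal(headDim(psmConfig(c(32, 32), channelScale = 1, heads = 256L)), 2L)
})

test_that("the encoder halves spatial dims four times and the decoder undoes it", {
  cfg <- psmConfig(c(64, 48), channelScale = 1 / 8, encLayers = 1, decLayers = 1,
                   heads = 4, M = 6, seed = 2)
  um <- usmModel(cfg)
  img <- array(runif(48 * 64 * 3), c(48, 64, 3))
  ft <- encodeImage(um, img)
  expect_equal(dim(featureValues(ft)), c(3, 4, 64))  # (h/16, w/16, C)
  out <- decodeFeatures(um, ft)
  expect_equal(dim(mapValues(out)), c(48, 64))
  expect_true(all(mapValues(out) >= 0))  # final ReLU
  cfg2 <- tinyConfig()
  ft2 <- encodeImage(usmModel(cfg2), array(0.3, c(16, 16, 3)))
  expect_equal(dim(featureValues(ft2)), c(1, 1, 32))
})

test_that("zero input with zeroed biases propagates to zero features and maps", {
  cfg <- tinyConfig(seed = 4)
  um <- usmModel(cfg)
  for (k in grep("\\.b$", names(um@params), value = TRUE))
    um@params[[k]] <- um@params[[k]] * 0
  ft <- encodeImage(um, array(0, c(16, 16, 3)))
  expect_true(all(featureValues(ft) == 0))
  expect_true(all(mapValues(decodeFeatures(um, ft)) == 0))
})

test_that("feature tensor and matrix views are lossless with documented order", {
  set.seed(5)
  v <- array(rnorm(3 * 4 * 6), c(3, 4, 6))  # h=3, w=4, C=6
  ft <- new("FeatureTensor", values = v)
  m <- featureMatrix(ft)
  expect_equal(dim(m), c(12, 6))
  # row i is pixel x=(i-1)%%w, y=(i-1)%/%w
  for (i in c(1, 5, 12)) {
    x <- (i - 1) %% 4; y <- (i - 1) %/% 4
    expect_equal(m[i, ], v[y + 1, x + 1, ])
  }
  expect_equal(featureValues(featureTensor(m, 3, 4)), v)
})

test_that("the user encoder maps M-dim interest vectors to 1 x C tokens deterministically", {
  cfg <- tinyConfig(seed = 6)
  pm <- psmModel(cfg, parts = "user")
  iv <- c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  tok <- encodeUser(pm, iv)
  expect_s4_class(tok, "UserToken")
  expect_equal(dim(tokenValues(tok)), c(1L, 32L))
  expect_equal(tokenValues(encodeUser(pm, iv)), tokenValues(tok))
  expect_false(isTRUE(all.equal(tokenValues(encodeUser(pm, rev(iv))),
                                tokenValues(tok))))
  expect_error(encodeUser(pm, c(1, 0)), "length")
})

test_that("probes expose the embedding and encoded token; identity encoder collapses them", {
  cfg0 <- tinyConfig(seed = 7, encLayers = 0)
  pm0 <- psmModel(cfg0, parts = "user")
  iv <- rep(c(1, 0), 6)
  pr0 <- probeUserCharacteristics(pm0, iv)
  expect_equal(pr0$emb, pr0$enc)
  pm1 <- psmModel(tinyConfig(seed = 7), parts = "user")
  pr1 <- probeUserCharacteristics(pm1, iv)
  expect_false(isTRUE(all.equal(pr1$emb, pr1$enc)))
  expect_equal(cosineSimilarity(pr1$enc, pr1$enc), 1)
})

test_that("single-key cross-attention equals broadcast-of-V", {
  set.seed(8)
  C <- 12; heads <- 3; wh <- 10
  X <- matrix(rnorm(wh * C), wh, C)
  U <- matrix(rnorm(C), 1, C)
  w <- list(Wq = matrix(rnorm(C * C), C, C), bq = rnorm(C),
            Wk = matrix(rnorm(C * C), C, C), bk = rnorm(C),
            Wv = matrix(rnorm(C * C), C, C), bv = rnorm(C),
            Wo = matrix(rnorm(C * C), C, C), bo = rnorm(C))
  out <- crossAttend(X, U, w, heads)
  # oracle: with one key the softmax weight is 1, so every row is
  # V = (U Wv + bv) pushed through the output projection
  V <- U %*% w$Wv + matrix(w$bv, 1)
  expected <- matrix(rep(V %*% w$Wo + matrix(w$bo, 1), each = wh), wh, C)
  expect_lt(max(abs(out - expected)), 1e-6)
  # identical for both logit scalings (the softmax is saturated either way)
  expect_equal(crossAttend(X, U, w, heads, logitScale = "dk"), out)
  # FeatureTensor in, FeatureTensor out
  ft <- featureTensor(X, 2, 5)
  out2 <- crossAttend(ft, new("UserToken", values = U), w, heads)
  expect_equal(featureMatrix(out2), out)
})

test_that("attention internals satisfy the per-head shape algebra", {
  set.seed(9)
  C <- 8; heads <- 4; wh <- 6
  w <- list(Wq = matrix(rnorm(C * C), C, C), bq = rnorm(C),
            Wk = matrix(rnorm(C * C), C, C), bk = rnorm(C),
            Wv = matrix(rnorm(C * C), C, C), bv = rnorm(C),
            Wo = matrix(rnorm(C * C), C, C), bo = rnorm(C))
  fw <- persal:::mhaForward(matrix(rnorm(wh * C), wh, C),
                            matrix(rnorm(2 * C), 2, C), w, heads, 1 / sqrt(2))
  expect_equal(dim(fw$out), c(wh, C))
  expect_equal(fw$cache$dk, 2L)
  for (A in fw$cache$A) {
    expect_equal(dim(A), c(wh, 2L))
    expect_equal(rowSums(A), rep(1, wh), tolerance = 1e-12)  # softmax rows
  }
})

test_that("PSM prediction is deterministic, user-sensitive, and fast at desk scale", {
  cfg <- tinyConfig(seed = 10)
  pm <- psmModel(cfg)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  ivA <- c(1, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0)
  ivB <- c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1)
  t0 <- Sys.time()
  mA <- predictPsm(pm, img, ivA)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_true(all(mapValues(mA) >= 0))
  expect_equal(dim(mapValues(mA)), c(16, 16))
  expect_equal(mapValues(predictPsm(pm, img, ivA)), mapValues(mA))
  expect_false(isTRUE(all.equal(mapValues(predictPsm(pm, img, ivB)),
                                mapValues(mA))))
})

test_that("the encoder-output tap bypasses the user mechanism", {
  cfg <- tinyConfig(seed = 11)
  pm <- psmModel(cfg)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tap <- encOutputTap(pm, img)
  expect_equal(mapValues(tap),
               mapValues(decodeFeatures(pm, encodeImage(pm, img))))
  # and is invariant to the interest vector by construction
  expect_equal(mapValues(encOutputTap(pm, img)), mapValues(tap))
})

test_that("analytic gradients match finite differences on a tiny config", {
  # 32x32 input -> 2x2 = 4 feature tokens, so token self-attention has
  # real softmax structure
  cfg <- psmConfig(c(32, 32), channelScale = 1 / 32, encLayers = 1,
                   decLayers = 1, heads = 2, M = 6, seed = 12, positional = TRUE)
  pm <- psmModel(cfg)
  set.seed(12)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  iv <- c(1, 0, 1, 1, 0, 0)
  tgt <- matrix(runif(1024), 32, 32)
  fw <- persal:::.forwardNet(pm, img, iv, "psm")
  g <- persal:::.backwardNet(pm, fw$cache, 2 * (fw$pred - tgt) / 1024)
  expect_setequal(names(g), names(pm@params))
  lossAt <- function(p) {
    m2 <- pm; m2@params <- p
    mean((persal:::.forwardNet(m2, img, iv, "psm")$pred - tgt)^2)
  }
  # user branch, conv stacks, fusion and positional parts all flow gradient
  mustCover <- c("user.lin.W", "enc.c01.W", "dec.c14.b", "tdec1.cross.Wv",
                 "tdec1.self.Wq", "tenc1.ff.W1", "tdec.pos", "tdec.lnf.g")
  eps <- 1e-6
  for (nm in union(mustCover, sample(names(g), 12))) {
    if (sum(g[[nm]]^2) == 0) next  # single-key query/key projections (below)
    i <- which.max(abs(g[[nm]]))
    p <- pm@params
    p[[nm]][i] <- p[[nm]][i] + eps; lp <- lossAt(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps; lm <- lossAt(p)
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
  for (nm in mustCover)
    expect_gt(sum(g[[nm]]^2), 0, label = paste("gradient reaches", nm))
})

test_that("a saturated single-key softmax blocks gradient to its Q/K projections", {
  # with one key every attention weight is exactly 1 whatever the logits,
  # so the cross-attention (and the one-token user self-attention) cannot
  # train its query/key projections -- only V and the output projection
  cfg <- psmConfig(c(16, 16), channelScale = 1 / 32, encLayers = 1,
                   decLayers = 1, heads = 2, M = 6, seed = 12)
  pm <- psmModel(cfg)
  set.seed(13)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tgt <- matrix(runif(256), 16, 16)
  fw <- persal:::.forwardNet(pm, img, c(1, 0, 1, 1, 0, 0), "psm")
  g <- persal:::.backwardNet(pm, fw$cache, 2 * (fw$pred - tgt) / 256)
  for (nm in c("tdec1.cross.Wq", "tdec1.cross.Wk", "tenc1.attn.Wq"))
    expect_equal(sum(g[[nm]]^2), 0)
  for (nm in c("tdec1.cross.Wv", "tdec1.cross.Wo", "tenc1.attn.Wv"))
    expect_gt(sum(g[[nm]]^2), 0)
})

test_that("checkpoints round-trip weights, config and predictions", {
  cfg <- tinyConfig(seed = 13)
  pm <- psmModel(cfg)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(pm, f)
  back <- loadCheckpoint(f)
  expect_equal(modelStage(back), "PSM")
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  iv <- rep(c(1, 0), 6)
  expect_identical(mapValues(predictPsm(back, img, iv)),
                   mapValues(predictPsm(pm, img, iv)))
})

test_that("the layer table lists the reference stack", {
  tab <- describeModel(usmModel(tinyConfig(seed = 14)))
  expect_equal(sum(tab$part == "encoder" & tab$layer == "Conv2D"), 13L)
  expect_equal(sum(tab$part == "encoder" & tab$layer == "MaxPool2D"), 4L)
  expect_equal(sum(tab$part == "decoder" & tab$layer == "Conv2D"), 14L)
  expect_equal(sum(tab$part == "decoder" & tab$layer == "UpSample"), 4L)
  expect_equal(tab$depth[nrow(tab)], 1L)  # single-channel output conv
})
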