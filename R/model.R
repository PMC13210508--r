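#' @include AllClasses.R AllGenerics.R nn-layers.R nn-transformer.R
NULL

## ---- architecture plans ---------------------------------------------------

## Reference depths of the convolutional encoder (13 convs, 4 poolings) and
## decoder (14 convs, 4 upsamplings, final 1x1 conv to one channel). All
## convs are 3x3 stride 1 pad 1 with ReLU; channelScale shrinks every depth
## so tiny instances run the identical graph.
.encBase <- c(64, 64, 0, 128, 128, 0, 256, 256, 256, 0, 512, 512, 512, 0,
              512, 512, 512)
.decBase <- c(512, 512, 512, -1, 512, 512, 512, -1, 256, 256, 256, -1,
              128, 128, -1, 64, 64)

.scaleDepth <- function(d, channelScale) max(1L, as.integer(round(d * channelScale)))

.convPlan <- function(base, channelScale, final = FALSE) {
  plan <- lapply(base, function(d) {
    if (d == 0) list(type = "pool")
    else if (d == -1) list(type = "up")
    else list(type = "conv", out = .scaleDepth(d, channelScale), k = 3L)
  })
  if (final) plan <- c(plan, list(list(type = "conv", out = 1L, k = 1L)))
  plan
}

.channels <- function(config) .scaleDepth(512, config@channelScale)

#' Per-head attention dimension
#'
#' `d_k = C / heads`; at full width (C = 512) and 512 heads the queries,
#' keys and values become one-dimensional.
#'
#' @param config a [PsmModelConfig-class].
#' @return Integer d_k.
#' @export
headDim <- function(config) .channels(config) %/% config@heads

.logitScaleValue <- function(config) {
  dk <- headDim(config)
  if (config@logitScale == "sqrt_dk") 1 / sqrt(dk) else 1 / dk
}

.buildArch <- function(config) {
  C <- .channels(config)
  list(C = C, dk = headDim(config), scale = .logitScaleValue(config),
       fw = config@inputSize[1] %/% 16L, fh = config@inputSize[2] %/% 16L,
       encPlan = .convPlan(.encBase, config@channelScale),
       decPlan = .convPlan(.decBase, config@channelScale, final = TRUE))
}

## ---- initialization -------------------------------------------------------

.tn <- function(n, sd = 0.02) pmin(pmax(rnorm(n, 0, sd), -2 * sd), 2 * sd)

.initConvStack <- function(prefix, plan, cin, finalBias = 0) {
  p <- list()
  i <- 0L
  for (op in plan) {
    if (op$type != "conv") next
    i <- i + 1L
    fanIn <- op$k * op$k * cin
    p[[sprintf("%sc%02d.W", prefix, i)]] <-
      matrix(rnorm(fanIn * op$out, 0, sqrt(2 / fanIn)), fanIn, op$out)
    # fan-based uniform bias; zero bias parks dead-patch cells exactly on
    # the ReLU kink, where the loss is not differentiable
    p[[sprintf("%sc%02d.b", prefix, i)]] <- runif(op$out, -1, 1) / sqrt(fanIn)
    cin <- op$out
  }
  # the output conv feeds a ReLU; damped weights plus a positive bias keep
  # the unit active at initialization so gradients flow from the first step
  if (finalBias != 0 && i > 0L) {
    nm <- sprintf("%sc%02d", prefix, i)
    p[[paste0(nm, ".W")]] <- p[[paste0(nm, ".W")]] * 0.1
    p[[paste0(nm, ".b")]] <- rep(finalBias, cin)
  }
  p
}

.initAttn <- function(pre, C) {
  p <- list()
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- matrix(.tn(C * C), C, C)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(C)
  p
}

.initLn <- function(pre, C) setNames(list(rep(1, C), numeric(C)),
                                     paste0(pre, c("g", "b")))

.initFF <- function(pre, C, ffMult) {
  Ch <- max(1L, as.integer(round(C * ffMult)))
  setNames(list(matrix(.tn(C * Ch), C, Ch), numeric(Ch),
                matrix(.tn(Ch * C), Ch, C), numeric(C)),
           paste0(pre, c("W1", "b1", "W2", "b2")))
}

.initUserParams <- function(config, arch) {
  C <- arch$C
  p <- list(user.lin.W = matrix(.tn(config@M * C), config@M, C),
            user.lin.b = numeric(C))
  for (l in seq_len(config@encLayers)) {
    pre <- sprintf("tenc%d.", l)
    p <- c(p, .initLn(paste0(pre, "ln1."), C), .initAttn(paste0(pre, "attn."), C),
           .initLn(paste0(pre, "ln2."), C), .initFF(paste0(pre, "ff."), C, config@ffMult))
  }
  if (config@encLayers > 0L) p <- c(p, .initLn("user.lnf.", C))
  p
}

.initFusionParams <- function(config, arch) {
  C <- arch$C
  p <- list()
  for (l in seq_len(config@decLayers)) {
    pre <- sprintf("tdec%d.", l)
    if (config@decoderSelfAttn)
      p <- c(p, .initLn(paste0(pre, "ln1."), C), .initAttn(paste0(pre, "self."), C))
    p <- c(p, .initLn(paste0(pre, "ln2."), C), .initAttn(paste0(pre, "cross."), C),
           .initLn(paste0(pre, "ln3."), C), .initFF(paste0(pre, "ff."), C, config@ffMult))
  }
  p <- c(p, .initLn("tdec.lnf.", C))
  if (config@positional)
    p$tdec.pos <- matrix(.tn(arch$fw * arch$fh * C), arch$fw * arch$fh, C)
  p
}

#' Construct saliency models
#'
#' `usmModel()` builds the universal model: convolutional encoder plus
#' decoder. `psmModel()` builds the personalized model, which inserts the
#' user-encoding mechanism (Linear embedding + Transformer encoder) and a
#' stack of Transformer-decoder layers whose cross-attention takes the
#' image features as queries and the single user token as key/value.
#' Weight initialization is seeded from the config: fan-based normal for
#' convolutions, truncated normal (sd 0.02) for Transformer parts.
#'
#' `parts = "user"` instantiates only the user-encoding branch, enough for
#' [encodeUser()] / [probeUserCharacteristics()] without allocating the
#' convolutional weights — useful for probing wide configurations.
#'
#' @param config a [PsmModelConfig-class].
#' @param parts "full" or "user" (PSM only).
#' @return A [SaliencyModel-class].
#' @examples
#' cfg <- psmConfig(c(32, 32), channelScale = 1 / 16, encLayers = 1,
#'                  decLayers = 1, heads = 4, M = 16)
#' m <- psmModel(cfg)
#' @export
usmModel <- function(config) {
  arch <- .buildArch(config)
  params <- withSeed(config@seed,
                     c(.initConvStack("enc.", arch$encPlan, 3L),
                       .initConvStack("dec.", arch$decPlan, arch$C, finalBias = 0.1)))
  new("SaliencyModel", params = params, config = config, stage = "USM",
      arch = arch)
}

#' @rdname usmModel
#' @export
psmModel <- function(config, parts = c("full", "user")) {
  parts <- match.arg(parts)
  arch <- .buildArch(config)
  params <- withSeed(config@seed, {
    p <- .initUserParams(config, arch)
    if (parts == "full")
      p <- c(.initConvStack("enc.", arch$encPlan, 3L),
             .initConvStack("dec.", arch$decPlan, arch$C, finalBias = 0.1),
             p, .initFusionParams(config, arch))
    p
  })
  new("SaliencyModel", params = params, config = config, stage = "PSM",
      arch = arch)
}

setMethod("show", "SaliencyModel", function(object) {
  cat(sprintf("SaliencyModel [%s]\n", object@stage))
  show(object@config)
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("  %d parameter arrays, %.3g parameters total\n",
              length(object@params), np))
})

## ---- feature reshaping ----------------------------------------------------

#' Reshape encoder features between tensor and matrix views
#'
#' `featureMatrix()` views an (h, w, C) feature tensor as the (w*h) x C
#' matrix consumed by attention: row i is the pixel with 0-based
#' x = (i-1) %% w (fastest) and y = (i-1) %/% w. `featureTensor()` is its
#' exact inverse, so the round trip is lossless.
#'
#' @param ft a [FeatureTensor-class] (or (h, w, C) array).
#' @param mat a (w*h) x C matrix.
#' @param h,w feature-grid height and width.
#' @return A matrix, or a [FeatureTensor-class].
#' @export
featureMatrix <- function(ft) {
  v <- if (is(ft, "FeatureTensor")) featureValues(ft) else ft
  .featToMat(v)
}

#' @rdname featureMatrix
#' @export
featureTensor <- function(mat, h, w) new("FeatureTensor", values = .matToFeat(mat, h, w))

.featToMat <- function(v) {
  d <- dim(v)
  m <- aperm(v, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

.matToFeat <- function(m, h, w) {
  a <- m
  dim(a) <- c(w, h, ncol(m))
  aperm(a, c(2, 1, 3))
}

## ---- conv stacks ----------------------------------------------------------

.convStackForward <- function(x, params, prefix, plan) {
  caches <- vector("list", length(plan))
  i <- 0L
  for (s in seq_along(plan)) {
    op <- plan[[s]]
    if (op$type == "conv") {
      i <- i + 1L
      cf <- convForward(x, params[[sprintf("%sc%02d.W", prefix, i)]],
                        params[[sprintf("%sc%02d.b", prefix, i)]], op$k)
      rf <- reluForward(cf$out)
      caches[[s]] <- list(conv = cf$cache, relu = rf$cache, idx = i)
      x <- rf$out
    } else if (op$type == "pool") {
      pf <- poolForward(x)
      caches[[s]] <- pf$cache
      x <- pf$out
    } else {
      uf <- upForward(x)
      caches[[s]] <- uf$cache
      x <- uf$out
    }
  }
  list(out = x, caches = caches)
}

.convStackBackward <- function(dy, params, prefix, plan, caches) {
  g <- list()
  for (s in rev(seq_along(plan))) {
    op <- plan[[s]]
    if (op$type == "conv") {
      cch <- caches[[s]]
      dy <- reluBackward(dy, cch$relu)
      nm <- sprintf("%sc%02d", prefix, cch$idx)
      cb <- convBackward(dy, params[[paste0(nm, ".W")]], cch$conv)
      g[[paste0(nm, ".W")]] <- cb$dW
      g[[paste0(nm, ".b")]] <- cb$db
      dy <- cb$dx
    } else if (op$type == "pool") {
      dy <- poolBackward(dy, caches[[s]])
    } else {
      dy <- upBackward(dy, caches[[s]])
    }
  }
  list(dx = dy, grads = g)
}

## ---- full network ---------------------------------------------------------

.asImageArray <- function(image, config) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  d <- dim(image)
  W <- config@inputSize[1]; H <- config@inputSize[2]
  if (d[1] != H || d[2] != W || d[3] != 3L)
    stop(sprintf("image must be %d x %d x 3 (rows = height), got %s",
                 H, W, paste(d, collapse = " x ")))
  image
}

## mode: "usm" (encoder -> decoder) or "psm" (with user-conditioned fusion).
.forwardNet <- function(model, image, iVec = NULL, mode) {
  cfg <- model@config; arch <- model@arch; params <- model@params
  x <- .asImageArray(image, cfg)
  enc <- .convStackForward(x, params, "enc.", arch$encPlan)
  cache <- list(enc = enc$caches, mode = mode)
  feat <- enc$out
  if (mode == "psm") {
    if (is.null(iVec)) stop("a PSM forward pass needs a user interest vector")
    if (length(iVec) != cfg@M)
      stop(sprintf("interest vector has length %d; config M = %d", length(iVec), cfg@M))
    u <- userForward(iVec, params, cfg@encLayers, cfg@heads, arch$scale)
    X <- .featToMat(feat)
    if (cfg@positional) X <- X + params$tdec.pos
    layers <- vector("list", cfg@decLayers)
    for (l in seq_len(cfg@decLayers)) {
      fw <- tdecForward(X, u$out, params, sprintf("tdec%d.", l), cfg@heads,
                        arch$scale, cfg@decoderSelfAttn)
      layers[[l]] <- fw$cache
      X <- fw$out
    }
    lnf <- layernormForward(X, params[["tdec.lnf.g"]], params[["tdec.lnf.b"]])
    feat <- .matToFeat(lnf$out, arch$fh, arch$fw)
    cache$user <- u; cache$layers <- layers; cache$lnf <- lnf
  }
  dec <- .convStackForward(feat, params, "dec.", arch$decPlan)
  cache$dec <- dec$caches
  list(pred = dec$out[, , 1], cache = cache)
}

.backwardNet <- function(model, cache, dpred) {
  cfg <- model@config; arch <- model@arch; params <- model@params
  dy <- array(dpred, c(dim(dpred), 1L))
  db <- .convStackBackward(dy, params, "dec.", arch$decPlan, cache$dec)
  g <- db$grads
  dfeat <- db$dx
  if (cache$mode == "psm") {
    dX <- .featToMat(dfeat)
    lb <- layernormBackward(dX, params[["tdec.lnf.g"]], cache$lnf$cache)
    g[["tdec.lnf.g"]] <- lb$dg; g[["tdec.lnf.b"]] <- lb$db
    dX <- lb$dx
    du <- matrix(0, 1, arch$C)
    for (l in rev(seq_len(cfg@decLayers))) {
      bk <- tdecBackward(dX, params, sprintf("tdec%d.", l), cache$layers[[l]])
      g <- c(g, bk$grads)
      du <- du + bk$du
      dX <- bk$dx
    }
    if (cfg@positional) g[["tdec.pos"]] <- dX
    g <- c(g, userBackward(du, params, cfg@encLayers, cache$user$cache))
    dfeat <- .matToFeat(dX, arch$fh, arch$fw)
  }
  eb <- .convStackBackward(dfeat, params, "enc.", arch$encPlan, cache$enc)
  c(g, eb$grads)
}

## ---- public operations ----------------------------------------------------

#' Encode an image into convolutional features
#'
#' Runs the 13-conv / 4-pool encoder; a (H, W, 3) input in [0,1] yields an
#' (H/16, W/16, C) [FeatureTensor-class]. Inputs must be divisible by 16.
#'
#' @param model a [SaliencyModel-class] with convolutional parts.
#' @param image (H, W, 3) array (a matrix is replicated to 3 channels).
#' @return A [FeatureTensor-class].
#' @export
encodeImage <- function(model, image) {
  x <- .asImageArray(image, model@config)
  out <- .convStackForward(x, model@params, "enc.", model@arch$encPlan)$out
  new("FeatureTensor", values = out)
}

#' Decode features into a predicted saliency map
#'
#' Runs the decoder stack (convs with four 2x upsamplings and a final
#' 1-channel 1x1 conv with ReLU), so the output is elementwise
#' non-negative and 16x the feature grid in each dimension.
#'
#' @param model a [SaliencyModel-class].
#' @param features a [FeatureTensor-class] (or (h, w, C) array).
#' @return A [SaliencyMap-class] of kind "predicted".
#' @export
decodeFeatures <- function(model, features) {
  v <- if (is(features, "FeatureTensor")) featureValues(features) else features
  out <- .convStackForward(v, model@params, "dec.", model@arch$decPlan)$out
  SaliencyMap(out[, , 1], "predicted")
}

#' Encode a user interest vector into a 1 x C token
#'
#' The user-encoding mechanism: a Linear layer maps the M-dimensional
#' binary interest vector to the channel width C of the image features,
#' then `encLayers` Transformer-encoder blocks self-attend over the single
#' token (softmax over one key is identically 1, but the value/output
#' projections and feed-forwards still transform it).
#'
#' @param model a PSM [SaliencyModel-class].
#' @param iVec numeric vector of length `M`.
#' @return A [UserToken-class] (1 x C).
#' @export
encodeUser <- function(model, iVec) {
  cfg <- model@config
  if (length(iVec) != cfg@M)
    stop(sprintf("interest vector has length %d; config M = %d", length(iVec), cfg@M))
  u <- userForward(iVec, model@params, cfg@encLayers, cfg@heads, model@arch$scale)
  new("UserToken", values = u$out)
}

#' Probe the user-encoding mechanism
#'
#' Returns the intermediate user representations used for similarity
#' analyses: the post-Linear embedding and the post-Transformer-encoder
#' token (identical when `encLayers = 0`).
#'
#' @param model a PSM [SaliencyModel-class].
#' @param iVec numeric vector of length `M`.
#' @return list with 1 x C matrices `emb` and `enc`.
#' @export
probeUserCharacteristics <- function(model, iVec) {
  cfg <- model@config
  u <- userForward(iVec, model@params, cfg@encLayers, cfg@heads, model@arch$scale)
  list(emb = u$emb, enc = u$out)
}

#' Single-block cross-attention between image features and a user token
#'
#' Queries come from the (w*h) x C feature matrix, keys and values from
#' the 1 x C user token. With exactly one key every softmax weight is 1,
#' so each head's attention output equals its value row broadcast to all
#' w*h queries; heads concatenate back to C channels and pass through the
#' output projection.
#'
#' @param features a [FeatureTensor-class] or (w*h) x C matrix.
#' @param user a [UserToken-class] or 1 x C matrix.
#' @param weights list with `Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`, `Wo`, `bo`
#'   (C x C projections, length-C biases).
#' @param heads number of attention heads (C divisible by heads).
#' @param logitScale "sqrt_dk" or "dk".
#' @return Object of the same shape class as `features`.
#' @export
crossAttend <- function(features, user, weights, heads,
                        logitScale = c("sqrt_dk", "dk")) {
  logitScale <- match.arg(logitScale)
  isFT <- is(features, "FeatureTensor")
  X <- if (isFT) featureMatrix(features) else features
  U <- if (is(user, "UserToken")) tokenValues(user) else user
  C <- ncol(X)
  if (C %% heads != 0) stop("C must be divisible by heads")
  dk <- C %/% heads
  scale <- if (logitScale == "sqrt_dk") 1 / sqrt(dk) else 1 / dk
  out <- mhaForward(X, U, weights, heads, scale)$out
  if (isFT) {
    d <- dim(featureValues(features))
    featureTensor(out, d[1], d[2])
  } else out
}

#' Predict a personalized saliency map
#'
#' Full PSM forward pass: encode the image, encode the user, fuse with
#' `decLayers` Transformer-decoder blocks (cross-attending to the user
#' token), and decode to a non-negative map the same size as the input.
#' Identical interest vectors give identical maps.
#'
#' @param model a PSM [SaliencyModel-class] (full parts).
#' @param image (H, W, 3) array.
#' @param iVec interest vector of length M.
#' @return A [SaliencyMap-class] of kind "predicted".
#' @export
predictPsm <- function(model, image, iVec) {
  if (model@stage != "PSM") stop("predictPsm needs a PSM model")
  SaliencyMap(.forwardNet(model, image, iVec, "psm")$pred, "predicted")
}

#' Encoder-output diagnostic map
#'
#' Decodes the encoder features directly, bypassing the user-encoding
#' mechanism and the Transformer fusion, with the model's current weights.
#' On a freshly transfer-initialized PSM model this equals the source USM
#' model's prediction exactly; after PSM training it shows what the
#' encoder/decoder pair alone has learned. Independent of any interest
#' vector by construction.
#'
#' @param model a [SaliencyModel-class].
#' @param image (H, W, 3) array.
#' @return A [SaliencyMap-class] of kind "predicted".
#' @export
encOutputTap <- function(model, image) {
  SaliencyMap(.forwardNet(model, image, iVec = NULL, "usm")$pred, "predicted")
}

#' Describe the layer stack
#'
#' Prints the convolutional layer table (depths, kernels, activations) and
#' the Transformer shape for comparison against the reference
#' architecture.
#'
#' @param model a [SaliencyModel-class].
#' @return Invisibly, a data.frame of layers.
#' @export
describeModel <- function(model) {
  rows <- list()
  add <- function(part, op) {
    rows[[length(rows) + 1L]] <<- switch(op$type,
      conv = data.frame(part = part, layer = "Conv2D", depth = op$out,
                        kernel = sprintf("%dx%d", op$k, op$k), activation = "ReLU"),
      pool = data.frame(part = part, layer = "MaxPool2D", depth = NA,
                        kernel = "2x2", activation = ""),
      up = data.frame(part = part, layer = "UpSample", depth = NA,
                      kernel = "2x2", activation = ""))
  }
  for (op in model@arch$encPlan) add("encoder", op)
  for (op in model@arch$decPlan) add("decoder", op)
  out <- do.call(rbind, rows)
  print(out, row.names = FALSE)
  if (model@stage == "PSM") {
    cfg <- model@config
    cat(sprintf("user encoding: Linear %d -> %d, %d enc layer(s); fusion: %d dec layer(s), %d heads (d_k = %d)\n",
                cfg@M, model@arch$C, cfg@encLayers, cfg@decLayers, cfg@heads,
                model@arch$dk))
  }
  invisible(out)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry the full weight set, configuration and stage, so a
#' reloaded model is bit-identical in its predictions.
#'
#' @param model a [SaliencyModel-class].
#' @param path file path (RDS).
#' @return `saveCheckpoint()`: `path` invisibly; `loadCheckpoint()`: the
#'   model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params,
               config = list(inputSize = model@config@inputSize,
                             channelScale = model@config@channelScale,
                             M = model@config@M, encLayers = model@config@encLayers,
                             decLayers = model@config@decLayers,
                             heads = model@config@heads, seed = model@config@seed,
                             logitScale = model@config@logitScale,
                             positional = model@config@positional,
                             decoderSelfAttn = model@config@decoderSelfAttn,
                             ffMult = model@config@ffMult),
               stage = model@stage), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  config <- do.call(psmConfig, ck$config)
  new("SaliencyModel", params = ck$params, config = config, stage = ck$stage,
      arch = .buildArch(config))
}
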