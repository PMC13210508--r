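#' @include AllClasses.R AllGenerics.R model.R
NULL

#' Mean squared error between two maps
#'
#' The training loss: because the model output is non-negative (final
#' ReLU), plain MSE against the [0,1] target is meaningful and directly
#' interpretable, with no sigmoid/BCE pairing needed.
#'
#' @param pred,target same-size [SaliencyMap-class]s or matrices.
#' @return Mean of squared cellwise differences (>= 0).
#' @examples
#' mseLoss(matrix(c(0, 1), 1), matrix(c(1, 1), 1))  # 0.5
#' @export
mseLoss <- function(pred, target) {
  a <- .asValues(pred); b <- .asValues(target)
  if (!all(dim(a) == dim(b))) stop("maps must have the same dimensions")
  mean((a - b)^2)
}

#' Stratified train/validation split
#'
#' Splits subject-image samples so that the number of positive-labelled
#' images in the training set is uniform across subjects whenever
#' feasible (a common positive count is targeted; subjects that cannot
#' reach it fall back to their maximum with a warning). Deterministic
#' under `seed`.
#'
#' @param labels data.frame with columns `subject_id` and `label` (0/1);
#'   any other columns are carried along.
#' @param trainFrac fraction of each subject's samples used for training.
#' @param seed RNG seed.
#' @return list with data.frames `train` and `val`.
#' @export
splitDataset <- function(labels, trainFrac = 0.8, seed = 1) {
  stopifnot(all(c("subject_id", "label") %in% names(labels)),
            trainFrac > 0, trainFrac < 1)
  subs <- unique(labels$subject_id)
  nTrain <- vapply(subs, function(s) round(trainFrac * sum(labels$subject_id == s)), numeric(1))
  npos <- vapply(subs, function(s) sum(labels$subject_id == s & labels$label == 1), numeric(1))
  target <- round(trainFrac * mean(npos))
  withSeed(seed, {
    take <- lapply(seq_along(subs), function(i) {
      s <- subs[[i]]
      rows <- which(labels$subject_id == s)
      pos <- rows[labels$label[rows] == 1]
      neg <- rows[labels$label[rows] == 0]
      tp <- min(target, length(pos), nTrain[i])
      tn <- nTrain[i] - tp
      if (tn > length(neg)) {  # too few negatives: take extra positives
        tp <- min(nTrain[i] - length(neg), length(pos))
        tn <- nTrain[i] - tp
      }
      if (tp != target)
        warning(sprintf("subject %s: %d training positives (target %d); best effort",
                        s, tp, target))
      c(if (tp > 0) pos[sample.int(length(pos), tp)],
        if (tn > 0) neg[sample.int(length(neg), tn)])
    })
  })
  trainIdx <- sort(unlist(take))
  list(train = labels[trainIdx, , drop = FALSE],
       val = labels[setdiff(seq_len(nrow(labels)), trainIdx), , drop = FALSE])
}

#' Early-stopping bookkeeping
#'
#' Training halts when the validation loss has not improved for `patience`
#' consecutive evaluations (one per epoch). An improvement resets the
#' counter, so alternating improve/worsen sequences never stop.
#'
#' @param state list from `earlyStopState()` or a previous update.
#' @param valLoss validation loss of the current epoch.
#' @param patience consecutive non-improving evaluations tolerated.
#' @return `earlyStopUpdate()`: list with the updated `state` and logical
#'   `stop`.
#' @examples
#' st <- earlyStopState()
#' for (v in c(1.0, 0.9, 0.8)) st <- earlyStopUpdate(st, v, 5)$state
#' st$since  # 0: every step improved
#' @export
earlyStopState <- function() list(bestVal = Inf, since = 0L)

#' @rdname earlyStopState
#' @export
earlyStopUpdate <- function(state, valLoss, patience = 5) {
  stopifnot(patience >= 1)
  if (valLoss < state$bestVal) {
    state$bestVal <- valLoss
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
  }
  list(state = state, stop = state$since >= patience)
}

#' Transfer-initialize a PSM model from a trained USM model
#'
#' Copies the convolutional encoder and decoder weights from the universal
#' model into the personalized model; the user-encoding mechanism and
#' Transformer fusion keep their fresh initialization. The encoder is not
#' frozen — subsequent training updates it. Layer-shape mismatches are
#' rejected with the offending layer names.
#'
#' @param psm a PSM [SaliencyModel-class] (full parts).
#' @param usm a USM [SaliencyModel-class] or a checkpoint path.
#' @return The PSM model with copied encoder/decoder weights.
#' @export
transferInit <- function(psm, usm) {
  if (is.character(usm)) usm <- loadCheckpoint(usm)
  src <- usm@params
  keys <- grep("^(enc|dec)\\.", names(psm@params), value = TRUE)
  missing <- setdiff(keys, names(src))
  if (length(missing))
    stop("USM checkpoint lacks layers: ", paste(missing, collapse = ", "))
  bad <- keys[vapply(keys, function(k) {
    !identical(dim(psm@params[[k]]), dim(src[[k]])) ||
      length(psm@params[[k]]) != length(src[[k]])
  }, logical(1))]
  if (length(bad))
    stop("shape mismatch in transferred layers (check channelScale): ",
         paste(bad, collapse = ", "))
  for (k in keys) psm@params[[k]] <- src[[k]]
  psm
}

#' Training configuration
#'
#' Reference settings per stage: the USM stage uses Adam with learning
#' rate 1e-5 and batch size 32; the PSM stage uses AdamW with learning
#' rate 1e-6, weight decay 0.05 and batch size 1, with each image
#' appearing once per subject within an epoch (8 subjects x 1000 images =
#' 8000 presentations, i.e. each image is trained eight times per epoch).
#' Early stopping patience is 5 validation evaluations for both. Tiny
#' desk-scale runs typically raise the learning rate.
#'
#' @param stage "USM" or "PSM".
#' @param lr learning rate (default per stage).
#' @param weightDecay decoupled weight decay (PSM default 0.05).
#' @param batchSize gradient-accumulation batch (default per stage).
#' @param patience early-stopping patience.
#' @param maxEpochs epoch cap.
#' @param seed RNG seed for shuffling (training is bit-reproducible under
#'   a fixed seed in single-threaded BLAS; otherwise statistically
#'   reproducible).
#' @return A validated list of settings.
#' @export
trainConfig <- function(stage = c("USM", "PSM"), lr = NULL, weightDecay = NULL,
                        batchSize = NULL, patience = 5, maxEpochs = 100,
                        seed = 1) {
  stage <- match.arg(stage)
  cfg <- list(stage = stage,
              optimizer = if (stage == "USM") "adam" else "adamw",
              lr = if (is.null(lr)) (if (stage == "USM") 1e-5 else 1e-6) else lr,
              weightDecay = if (is.null(weightDecay)) (if (stage == "USM") 0 else 0.05) else weightDecay,
              batchSize = if (is.null(batchSize)) (if (stage == "USM") 32L else 1L) else as.integer(batchSize),
              patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
              seed = as.integer(seed))
  stopifnot(cfg$patience >= 1L, cfg$batchSize >= 1L, cfg$lr > 0)
  cfg
}

.adamStep <- function(params, grads, state, lr, wd, decoupled,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    if (!decoupled && wd > 0) g <- g + wd * params[[k]]
    m <- if (is.null(state$m[[k]])) g * 0 else state$m[[k]]
    v <- if (is.null(state$v[[k]])) g * 0 else state$v[[k]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    state$m[[k]] <- m; state$v[[k]] <- v
    upd <- lr * (m / c1) / (sqrt(v / c2) + eps)
    if (decoupled && wd > 0) upd <- upd + lr * wd * params[[k]]
    params[[k]] <- params[[k]] - upd
  }
  list(params = params, state = state)
}

.sampleLoss <- function(model, s, mode) {
  fw <- .forwardNet(model, s$image, s$iVec, mode)
  tgt <- .asValues(s$target)
  list(fw = fw, loss = mean((fw$pred - tgt)^2),
       dpred = 2 * (fw$pred - tgt) / length(tgt))
}

#' Train a USM or PSM stage
#'
#' Runs epochs of minibatch gradient descent with the stage's optimizer,
#' evaluates the validation loss once per epoch, applies early stopping,
#' and returns the weights of the best validation epoch together with the
#' loss curve. Training aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param model a [SaliencyModel-class] ("USM" stage models train the
#'   encoder/decoder path; "PSM" models the full user-conditioned path).
#' @param train,val lists of samples; each sample is a list with `image`
#'   ((H, W, 3) array), `target` (map or matrix) and, for PSM, `iVec`.
#' @param config from [trainConfig()].
#' @return list with `model` (best-validation weights), `curve`
#'   (data.frame epoch/train_loss/val_loss), `epochs` and `stoppedEarly`.
#' @export
trainStage <- function(model, train, val, config) {
  stopifnot(length(train) > 0, length(val) > 0)
  mode <- if (model@stage == "USM") "usm" else "psm"
  state <- list(m = list(), v = list(), t = 0L)
  es <- earlyStopState()
  bestParams <- model@params
  bestVal <- Inf
  curve <- NULL
  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      idx <- sample(length(train))
      batches <- split(idx, ceiling(seq_along(idx) / config$batchSize))
      trainLoss <- 0
      for (bt in batches) {
        gacc <- NULL
        for (i in bt) {
          sl <- .sampleLoss(model, train[[i]], mode)
          if (!is.finite(sl$loss))
            stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", epoch))
          trainLoss <- trainLoss + sl$loss
          g <- .backwardNet(model, sl$fw$cache, sl$dpred)
          gacc <- if (is.null(gacc)) g else
            setNames(lapply(names(g), function(k) gacc[[k]] + g[[k]]), names(g))
        }
        gacc <- lapply(gacc, function(x) x / length(bt))
        st <- .adamStep(model@params, gacc, state, config$lr, config$weightDecay,
                        decoupled = config$optimizer == "adamw")
        model@params <- st$params
        state <- st$state
      }
      trainLoss <- trainLoss / length(train)
      valLoss <- mean(vapply(val, function(s) .sampleLoss(model, s, mode)$loss,
                             numeric(1)))
      curve <- rbind(curve, data.frame(epoch = epoch, train_loss = trainLoss,
                                       val_loss = valLoss))
      if (valLoss < bestVal) {
        bestVal <- valLoss
        bestParams <- model@params
      }
      up <- earlyStopUpdate(es, valLoss, config$patience)
      es <- up$state
      if (up$stop) break
    }
  })
  model@params <- bestParams
  list(model = model, curve = curve, epochs = nrow(curve),
       stoppedEarly = nrow(curve) < config$maxEpochs)
}
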