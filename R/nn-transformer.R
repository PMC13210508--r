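#' @include nn-layers.R
NULL

## Transformer blocks (pre-norm residual layout) operating on the flat
## named parameter list; `pre` is the parameter-name prefix of one block.
## Gradients are returned as flat named lists keyed by full parameter name.

.attnP <- function(params, pre) {
  list(Wq = params[[paste0(pre, "Wq")]], bq = params[[paste0(pre, "bq")]],
       Wk = params[[paste0(pre, "Wk")]], bk = params[[paste0(pre, "bk")]],
       Wv = params[[paste0(pre, "Wv")]], bv = params[[paste0(pre, "bv")]],
       Wo = params[[paste0(pre, "Wo")]], bo = params[[paste0(pre, "bo")]])
}

.ffP <- function(params, pre) {
  list(W1 = params[[paste0(pre, "W1")]], b1 = params[[paste0(pre, "b1")]],
       W2 = params[[paste0(pre, "W2")]], b2 = params[[paste0(pre, "b2")]])
}

.prefixGrads <- function(grads, pre) setNames(grads, paste0(pre, names(grads)))

## Encoder block: x + SelfAttn(LN(x)); x + FF(LN(x)).
tencForward <- function(x, params, pre, heads, scale) {
  n1 <- layernormForward(x, params[[paste0(pre, "ln1.g")]], params[[paste0(pre, "ln1.b")]])
  at <- mhaForward(n1$out, n1$out, .attnP(params, paste0(pre, "attn.")), heads, scale)
  x1 <- x + at$out
  n2 <- layernormForward(x1, params[[paste0(pre, "ln2.g")]], params[[paste0(pre, "ln2.b")]])
  f <- ffForward(n2$out, .ffP(params, paste0(pre, "ff.")))
  list(out = x1 + f$out, cache = list(n1 = n1, at = at, n2 = n2, f = f))
}

tencBackward <- function(dout, params, pre, cache) {
  g <- list()
  fb <- ffBackward(dout, .ffP(params, paste0(pre, "ff.")), cache$f$cache)
  g <- c(g, .prefixGrads(fb$grads, paste0(pre, "ff.")))
  n2b <- layernormBackward(fb$dx, params[[paste0(pre, "ln2.g")]], cache$n2$cache)
  g[[paste0(pre, "ln2.g")]] <- n2b$dg; g[[paste0(pre, "ln2.b")]] <- n2b$db
  dx1 <- dout + n2b$dx
  ab <- mhaBackward(dx1, .attnP(params, paste0(pre, "attn.")), cache$at$cache)
  g <- c(g, .prefixGrads(ab$grads, paste0(pre, "attn.")))
  n1b <- layernormBackward(ab$dxq + ab$dxkv, params[[paste0(pre, "ln1.g")]], cache$n1$cache)
  g[[paste0(pre, "ln1.g")]] <- n1b$dg; g[[paste0(pre, "ln1.b")]] <- n1b$db
  list(dx = dx1 + n1b$dx, grads = g)
}

## Decoder block: optional token self-attention, then cross-attention with
## the user token as Key/Value source, then feed-forward.
tdecForward <- function(x, u, params, pre, heads, scale, selfAttn) {
  cache <- list(selfAttn = selfAttn)
  if (selfAttn) {
    n1 <- layernormForward(x, params[[paste0(pre, "ln1.g")]], params[[paste0(pre, "ln1.b")]])
    sa <- mhaForward(n1$out, n1$out, .attnP(params, paste0(pre, "self.")), heads, scale)
    x <- x + sa$out
    cache$n1 <- n1; cache$sa <- sa
  }
  n2 <- layernormForward(x, params[[paste0(pre, "ln2.g")]], params[[paste0(pre, "ln2.b")]])
  ca <- mhaForward(n2$out, u, .attnP(params, paste0(pre, "cross.")), heads, scale)
  x1 <- x + ca$out
  n3 <- layernormForward(x1, params[[paste0(pre, "ln3.g")]], params[[paste0(pre, "ln3.b")]])
  f <- ffForward(n3$out, .ffP(params, paste0(pre, "ff.")))
  cache$n2 <- n2; cache$ca <- ca; cache$n3 <- n3; cache$f <- f
  list(out = x1 + f$out, cache = cache)
}

tdecBackward <- function(dout, params, pre, cache) {
  g <- list()
  fb <- ffBackward(dout, .ffP(params, paste0(pre, "ff.")), cache$f$cache)
  g <- c(g, .prefixGrads(fb$grads, paste0(pre, "ff.")))
  n3b <- layernormBackward(fb$dx, params[[paste0(pre, "ln3.g")]], cache$n3$cache)
  g[[paste0(pre, "ln3.g")]] <- n3b$dg; g[[paste0(pre, "ln3.b")]] <- n3b$db
  dx1 <- dout + n3b$dx
  cb <- mhaBackward(dx1, .attnP(params, paste0(pre, "cross.")), cache$ca$cache)
  g <- c(g, .prefixGrads(cb$grads, paste0(pre, "cross.")))
  n2b <- layernormBackward(cb$dxq, params[[paste0(pre, "ln2.g")]], cache$n2$cache)
  g[[paste0(pre, "ln2.g")]] <- n2b$dg; g[[paste0(pre, "ln2.b")]] <- n2b$db
  dx <- dx1 + n2b$dx
  if (cache$selfAttn) {
    sb <- mhaBackward(dx, .attnP(params, paste0(pre, "self.")), cache$sa$cache)
    g <- c(g, .prefixGrads(sb$grads, paste0(pre, "self.")))
    n1b <- layernormBackward(sb$dxq + sb$dxkv, params[[paste0(pre, "ln1.g")]], cache$n1$cache)
    g[[paste0(pre, "ln1.g")]] <- n1b$dg; g[[paste0(pre, "ln1.b")]] <- n1b$db
    dx <- dx + n1b$dx
  }
  list(dx = dx, du = cb$dxkv, grads = g)
}

## User-encoding mechanism: Linear M -> C, encLayers encoder blocks, final
## LN. With encLayers = 0 the mechanism is the bare embedding (identity
## encoder), matching the probe contract Emb == Enc.
userForward <- function(iVec, params, encLayers, heads, scale) {
  lin <- linearForward(matrix(as.numeric(iVec), 1), params[["user.lin.W"]],
                       params[["user.lin.b"]])
  emb <- lin$out
  if (encLayers == 0L)
    return(list(out = emb, emb = emb, cache = list(lin = lin$cache, layers = NULL)))
  x <- emb
  layers <- vector("list", encLayers)
  for (l in seq_len(encLayers)) {
    fw <- tencForward(x, params, sprintf("tenc%d.", l), heads, scale)
    layers[[l]] <- fw$cache
    x <- fw$out
  }
  lnf <- layernormForward(x, params[["user.lnf.g"]], params[["user.lnf.b"]])
  list(out = lnf$out, emb = emb,
       cache = list(lin = lin$cache, layers = layers, lnf = lnf))
}

userBackward <- function(du, params, encLayers, cache) {
  g <- list()
  if (encLayers > 0L) {
    lb <- layernormBackward(du, params[["user.lnf.g"]], cache$lnf$cache)
    g[["user.lnf.g"]] <- lb$dg; g[["user.lnf.b"]] <- lb$db
    du <- lb$dx
    for (l in rev(seq_len(encLayers))) {
      bk <- tencBackward(du, params, sprintf("tenc%d.", l), cache$layers[[l]])
      g <- c(g, bk$grads)
      du <- bk$dx
    }
  }
  linb <- linearBackward(du, params[["user.lin.W"]], cache$lin)
  g[["user.lin.W"]] <- linb$dW; g[["user.lin.b"]] <- linb$db
  g
}
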