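#' @include utils.R
NULL

## Low-level neural-network primitives on single samples.
## Feature maps are arrays [H, W, C]; token matrices are [T, C].
## Every *Forward returns list(out, cache); every *Backward consumes the
## upstream gradient plus the cache and returns input/parameter gradients.

.pad2d <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

## im2col for stride-1 'same' convolution with zero padding.
.im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1) / 2
  xp <- if (p > 0) .pad2d(x, p) else x
  cols <- matrix(0, H * W, k * k * C)
  slot <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    blk <- xp[i:(i + H - 1), j:(j + W - 1), , drop = FALSE]
    dim(blk) <- c(H * W, C)
    cols[, slot * C + seq_len(C)] <- blk
    slot <- slot + 1L
  }
  cols
}

.col2im <- function(dcols, H, W, C, k) {
  p <- (k - 1) / 2
  dxp <- array(0, c(H + 2 * p, W + 2 * p, C))
  slot <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    blk <- dcols[, slot * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(H, W, C)
    dxp[i:(i + H - 1), j:(j + W - 1), ] <-
      dxp[i:(i + H - 1), j:(j + W - 1), , drop = FALSE] + blk
    slot <- slot + 1L
  }
  if (p > 0) dxp[p + seq_len(H), p + seq_len(W), , drop = FALSE] else dxp
}

## W: matrix (k*k*Cin) x Cout (rows ordered like .im2col), b: length Cout.
convForward <- function(x, W, b, k) {
  d <- dim(x)
  cols <- .im2col(x, k)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  dim(y) <- c(d[1], d[2], ncol(W))
  list(out = y, cache = list(cols = cols, dimx = d, k = k))
}

convBackward <- function(dy, W, cache) {
  d <- cache$dimx
  dym <- dy; dim(dym) <- c(d[1] * d[2], ncol(W))
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- .col2im(dym %*% t(W), d[1], d[2], d[3], cache$k)
  list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(dy, cache) dy * cache

## 2x2 max pooling, stride 2 (H, W even).
poolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  oi <- seq(1, H, 2); ei <- oi + 1
  oj <- seq(1, W, 2); ej <- oj + 1
  n <- (H / 2) * (W / 2) * C
  S <- cbind(as.vector(x[oi, oj, , drop = FALSE]),
             as.vector(x[ei, oj, , drop = FALSE]),
             as.vector(x[oi, ej, , drop = FALSE]),
             as.vector(x[ei, ej, , drop = FALSE]))
  amax <- max.col(S, ties.method = "first")
  y <- S[cbind(seq_len(n), amax)]
  dim(y) <- c(H / 2, W / 2, C)
  list(out = y, cache = list(amax = amax, dimx = d))
}

poolBackward <- function(dy, cache) {
  d <- cache$dimx; H <- d[1]; W <- d[2]; C <- d[3]
  dyv <- as.vector(dy)
  dx <- array(0, d)
  oi <- seq(1, H, 2); ei <- oi + 1
  oj <- seq(1, W, 2); ej <- oj + 1
  for (kk in 1:4) {
    sel <- cache$amax == kk
    g <- ifelse(sel, dyv, 0)
    dim(g) <- c(H / 2, W / 2, C)
    if (kk == 1) dx[oi, oj, ] <- g
    else if (kk == 2) dx[ei, oj, ] <- g
    else if (kk == 3) dx[oi, ej, ] <- g
    else dx[ei, ej, ] <- g
  }
  dx
}

## 2x nearest-neighbour upsampling.
upForward <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
  list(out = y, cache = d)
}

upBackward <- function(dy, dimx) {
  H2 <- dim(dy)[1]; W2 <- dim(dy)[2]
  oi <- seq(1, H2, 2); ei <- oi + 1
  oj <- seq(1, W2, 2); ej <- oj + 1
  dy[oi, oj, , drop = FALSE] + dy[ei, oj, , drop = FALSE] +
    dy[oi, ej, , drop = FALSE] + dy[ei, ej, , drop = FALSE]
}

linearForward <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, `+`)
  list(out = y, cache = x)
}

linearBackward <- function(dy, W, cache) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

.lnEps <- 1e-5

layernormForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .lnEps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(out = y, cache = list(xhat = xhat, inv = inv))
}

layernormBackward <- function(dy, g, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmaxRows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

## Multi-head attention: queries from xq (Tq x C), keys/values from xkv.
## p holds Wq,bq,Wk,bk,Wv,bv,Wo,bo with C x C projections.
mhaForward <- function(xq, xkv, p, heads, scale) {
  C <- ncol(xq); dk <- C %/% heads
  Q <- sweep(xq %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(xkv %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(xkv %*% p$Wv, 2, p$bv, `+`)
  O <- matrix(0, nrow(xq), C)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) * scale
    A[[h]] <- softmaxRows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  list(out = out,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, O = O, A = A,
                    heads = heads, dk = dk, scale = scale))
}

mhaBackward <- function(dout, p, cache) {
  with(cache, {
    dO <- dout %*% t(p$Wo)
    dWo <- crossprod(O, dout)
    dbo <- colSums(dout)
    dQ <- matrix(0, nrow(Q), ncol(Q))
    dK <- matrix(0, nrow(K), ncol(K))
    dV <- matrix(0, nrow(V), ncol(V))
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      Ah <- A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(Ah, dOh)
      dS <- (dA - rowSums(dA * Ah)) * Ah
      dQ[, idx] <- (dS %*% K[, idx, drop = FALSE]) * scale
      dK[, idx] <- (crossprod(dS, Q[, idx, drop = FALSE])) * scale
    }
    list(dxq = dQ %*% t(p$Wq),
         dxkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
         grads = list(Wq = crossprod(xq, dQ), bq = colSums(dQ),
                      Wk = crossprod(xkv, dK), bk = colSums(dK),
                      Wv = crossprod(xkv, dV), bv = colSums(dV),
                      Wo = dWo, bo = dbo))
  })
}

ffForward <- function(x, p) {
  l1 <- linearForward(x, p$W1, p$b1)
  r <- reluForward(l1$out)
  l2 <- linearForward(r$out, p$W2, p$b2)
  list(out = l2$out, cache = list(l1 = l1$cache, r = r$cache, l2 = l2$cache))
}

ffBackward <- function(dy, p, cache) {
  b2 <- linearBackward(dy, p$W2, cache$l2)
  dr <- reluBackward(b2$dx, cache$r)
  b1 <- linearBackward(dr, p$W1, cache$l1)
  list(dx = b1$dx,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}
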