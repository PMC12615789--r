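# Transformer layer primitives with explicit forward caches and hand-derived
# backward passes. All 2-D activations are (tokens x embed); the temporal
# variants operate on (batch x time x embed) arrays with time vectorized as
# the short axis.

linear_f <- function(x, W, b) sweep(x %*% W, 2, b, "+")

linear_b <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

gelu_f <- function(x) x * stats::pnorm(x)

gelu_b <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

layernorm_f <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, inv = inv)
}

layernorm_b <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = cache$inv * (dxhat - m1 - xhat * m2),
       dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# multi-head self-attention over one sequence x (n x D)
mhsa_f <- function(x, p, heads) {
  D <- ncol(x); dh <- D %/% heads
  qkv <- linear_f(x, p$Wqkv, p$bqkv)
  O <- matrix(0, nrow(x), D)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    i <- (h - 1) * dh
    Q <- qkv[, i + 1:dh, drop = FALSE]
    K <- qkv[, D + i + 1:dh, drop = FALSE]
    V <- qkv[, 2 * D + i + 1:dh, drop = FALSE]
    A[[h]] <- softmax_rows(tcrossprod(Q, K) / sqrt(dh))
    O[, i + 1:dh] <- A[[h]] %*% V
  }
  y <- linear_f(O, p$Wo, p$bo)
  list(y = y, cache = list(x = x, qkv = qkv, A = A, O = O))
}

mhsa_b <- function(dy, p, cache, heads) {
  D <- ncol(cache$x); dh <- D %/% heads
  lo <- linear_b(dy, cache$O, p$Wo)
  dO <- lo$dx
  dqkv <- matrix(0, nrow(dO), 3 * D)
  for (h in seq_len(heads)) {
    i <- (h - 1) * dh
    Q <- cache$qkv[, i + 1:dh, drop = FALSE]
    K <- cache$qkv[, D + i + 1:dh, drop = FALSE]
    V <- cache$qkv[, 2 * D + i + 1:dh, drop = FALSE]
    A <- cache$A[[h]]
    dOh <- dO[, i + 1:dh, drop = FALSE]
    dA <- tcrossprod(dOh, V)
    dS <- A * (dA - rowSums(dA * A))
    dqkv[, i + 1:dh] <- (dS %*% K) / sqrt(dh)
    dqkv[, D + i + 1:dh] <- (crossprod(dS, Q)) / sqrt(dh)
    dqkv[, 2 * D + i + 1:dh] <- crossprod(A, dOh)
  }
  lq <- linear_b(dqkv, cache$x, p$Wqkv)
  list(dx = lq$dx,
       g = list(Wqkv = lq$dW, bqkv = lq$db, Wo = lo$dW, bo = lo$db))
}

# pre-norm transformer block on a 2-D sequence
block_f <- function(x, p, heads) {
  l1 <- layernorm_f(x, p$ln1g, p$ln1b)
  at <- mhsa_f(l1$y, p, heads)
  x1 <- x + at$y
  l2 <- layernorm_f(x1, p$ln2g, p$ln2b)
  h1 <- linear_f(l2$y, p$W1, p$b1)
  a1 <- gelu_f(h1)
  y <- x1 + linear_f(a1, p$W2, p$b2)
  list(y = y, cache = list(l1 = l1, at = at$cache, x1 = x1, l2 = l2,
                           h1 = h1, a1 = a1))
}

block_b <- function(dy, p, cache, heads) {
  l2b <- linear_b(dy, cache$a1, p$W2)
  dh1 <- gelu_b(l2b$dx, cache$h1)
  l1b <- linear_b(dh1, cache$l2$y, p$W1)
  ln2 <- layernorm_b(l1b$dx, cache$l2, p$ln2g)
  dx1 <- dy + ln2$dx
  ab <- mhsa_b(dx1, p, cache$at, heads)
  ln1 <- layernorm_b(ab$dx, cache$l1, p$ln1g)
  list(dx = dx1 + ln1$dx,
       g = list(ln1g = ln1$dg, ln1b = ln1$db,
                Wqkv = ab$g$Wqkv, bqkv = ab$g$bqkv,
                Wo = ab$g$Wo, bo = ab$g$bo,
                ln2g = ln2$dg, ln2b = ln2$db,
                W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db))
}

# ---- temporal variants: x3 is (batch B, time nt, D); nt is small (1 or 4).
# Row-wise ops (layernorm, MLP, linear) reuse the 2-D kernels on the
# column-major flattening (B*nt, D); attention is vectorized over the batch.

flat3 <- function(x3) { d <- dim(x3); dim(x3) <- c(d[1] * d[2], d[3]); x3 }
unflat3 <- function(x2, B, nt) { dim(x2) <- c(B, nt, ncol(x2)); x2 }

mhsa_time_f <- function(x3, p, heads) {
  d <- dim(x3); B <- d[1]; nt <- d[2]; D <- d[3]; dh <- D %/% heads
  qkv2 <- linear_f(flat3(x3), p$Wqkv, p$bqkv)
  qkv <- unflat3(qkv2, B, nt)
  O <- array(0, c(B, nt, D))
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    i <- (h - 1) * dh
    S <- array(0, c(B, nt, nt))
    for (ti in seq_len(nt)) for (tj in seq_len(nt))
      S[, ti, tj] <- rowSums(qkv[, ti, i + 1:dh, drop = FALSE] *
                             qkv[, tj, D + i + 1:dh, drop = FALSE]) / sqrt(dh)
    Ah <- array(0, c(B, nt, nt))
    for (ti in seq_len(nt)) {
      row <- matrix(S[, ti, ], B, nt)
      m <- do.call(pmax, lapply(seq_len(nt), function(j) row[, j]))
      e <- exp(row - m)
      Ah[, ti, ] <- e / rowSums(e)
    }
    for (ti in seq_len(nt)) for (tj in seq_len(nt))
      O[, ti, i + 1:dh] <- O[, ti, i + 1:dh] +
        Ah[, ti, tj] * qkv[, tj, 2 * D + i + 1:dh]
    A[[h]] <- Ah
  }
  y2 <- linear_f(flat3(O), p$Wo, p$bo)
  list(y = unflat3(y2, B, nt),
       cache = list(x3 = x3, qkv = qkv, A = A, O = O))
}

mhsa_time_b <- function(dy3, p, cache, heads) {
  d <- dim(cache$x3); B <- d[1]; nt <- d[2]; D <- d[3]; dh <- D %/% heads
  lo <- linear_b(flat3(dy3), flat3(cache$O), p$Wo)
  dO <- unflat3(lo$dx, B, nt)
  qkv <- cache$qkv
  dqkv <- array(0, c(B, nt, 3 * D))
  for (h in seq_len(heads)) {
    i <- (h - 1) * dh
    Ah <- cache$A[[h]]
    dA <- array(0, c(B, nt, nt))
    for (ti in seq_len(nt)) for (tj in seq_len(nt)) {
      dA[, ti, tj] <- rowSums(dO[, ti, i + 1:dh, drop = FALSE] *
                              qkv[, tj, 2 * D + i + 1:dh, drop = FALSE])
      dqkv[, tj, 2 * D + i + 1:dh] <- dqkv[, tj, 2 * D + i + 1:dh] +
        Ah[, ti, tj] * dO[, ti, i + 1:dh]
    }
    # softmax backward per query position
    dS <- array(0, c(B, nt, nt))
    for (ti in seq_len(nt)) {
      Ai <- matrix(Ah[, ti, ], B, nt)
      dAi <- matrix(dA[, ti, ], B, nt)
      dS[, ti, ] <- Ai * (dAi - rowSums(dAi * Ai))
    }
    for (ti in seq_len(nt)) for (tj in seq_len(nt)) {
      dqkv[, ti, i + 1:dh] <- dqkv[, ti, i + 1:dh] +
        dS[, ti, tj] * qkv[, tj, D + i + 1:dh] / sqrt(dh)
      dqkv[, tj, D + i + 1:dh] <- dqkv[, tj, D + i + 1:dh] +
        dS[, ti, tj] * qkv[, ti, i + 1:dh] / sqrt(dh)
    }
  }
  lq <- linear_b(flat3(dqkv), flat3(cache$x3), p$Wqkv)
  list(dx = unflat3(lq$dx, B, nt),
       g = list(Wqkv = lq$dW, bqkv = lq$db, Wo = lo$dW, bo = lo$db))
}

block_time_f <- function(x3, p, heads) {
  d <- dim(x3); B <- d[1]; nt <- d[2]
  l1 <- layernorm_f(flat3(x3), p$ln1g, p$ln1b)
  at <- mhsa_time_f(unflat3(l1$y, B, nt), p, heads)
  x1 <- x3 + at$y
  l2 <- layernorm_f(flat3(x1), p$ln2g, p$ln2b)
  h1 <- linear_f(l2$y, p$W1, p$b1)
  a1 <- gelu_f(h1)
  y <- x1 + unflat3(linear_f(a1, p$W2, p$b2), B, nt)
  list(y = y, cache = list(l1 = l1, at = at$cache, x1 = x1, l2 = l2,
                           h1 = h1, a1 = a1, B = B, nt = nt))
}

block_time_b <- function(dy3, p, cache, heads) {
  B <- cache$B; nt <- cache$nt
  l2b <- linear_b(flat3(dy3), cache$a1, p$W2)
  dh1 <- gelu_b(l2b$dx, cache$h1)
  l1b <- linear_b(dh1, cache$l2$y, p$W1)
  ln2 <- layernorm_b(l1b$dx, cache$l2, p$ln2g)
  dx1 <- dy3 + unflat3(ln2$dx, B, nt)
  ab <- mhsa_time_b(dx1, p, cache$at, heads)
  ln1 <- layernorm_b(flat3(ab$dx), cache$l1, p$ln1g)
  list(dx = dx1 + unflat3(ln1$dx, B, nt),
       g = list(ln1g = ln1$dg, ln1b = ln1$db,
                Wqkv = ab$g$Wqkv, bqkv = ab$g$bqkv,
                Wo = ab$g$Wo, bo = ab$g$bo,
                ln2g = ln2$dg, ln2b = ln2$db,
                W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db))
}

# ---- parameter-tree helpers (nested named lists of numeric arrays)

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, b = b, a = a,
                  MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

tree_unlist <- function(a) unlist(a, use.names = FALSE)

# total squared l2 norm over every leaf
tree_sq_norm <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sq_norm, 0)) else sum(a^2)
}
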