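## Differentiable building blocks, each with an explicit backward pass.
## Shapes follow the usual row-major convention: node/token features are
## rows, channels are columns.  Adjacency matrices are data, never
## differentiated through.

# Symmetrically normalized adjacency S = D^{-1/2} A D^{-1/2}.
# A must already contain the self-loops (unit diagonal).
norm_adjacency <- function(A) {
  d <- rowSums(A)
  d[d == 0] <- 1
  s <- 1 / sqrt(d)
  A * outer(s, s)
}

#' Graph convolution layer
#'
#' Computes `activation(S H W)` with `S = D^{-1/2} A D^{-1/2}` the
#' symmetrically normalized adjacency (self-loops included in `A`).
#'
#' @param H node feature matrix (N x d_in).
#' @param A adjacency matrix with self-loops (N x N, symmetric).
#' @param W weight matrix (d_in x d_out).
#' @param activation "relu" (default) or "identity".
#' @return N x d_out node feature matrix.
#' @export
graph_conv <- function(H, A, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  H <- as.matrix(H); W <- as.matrix(W)
  if (ncol(H) != nrow(W)) {
    stop_graphgo(sprintf("graph_conv: feature dim %d does not match weight rows %d",
                         ncol(H), nrow(W)))
  }
  pre <- norm_adjacency(A) %*% H %*% W
  if (activation == "relu") pmax(pre, 0) else pre
}

# forward with cache for training
graph_conv_fwd <- function(H, S, W, relu = TRUE) {
  pre <- S %*% H %*% W
  out <- if (relu) pmax(pre, 0) else pre
  list(out = out, pre = pre, H = H)
}

# dOut -> list(dH, dW); S symmetric so t(S) = S
graph_conv_bwd <- function(cache, S, W, dOut, relu = TRUE) {
  dPre <- if (relu) dOut * (cache$pre > 0) else dOut
  SH <- S %*% cache$H
  list(dH = S %*% (dPre %*% t(W)), dW = crossprod(SH, dPre))
}

#' Self-attention graph pooling
#'
#' Per-node attention scores are computed by two independent single-layer
#' graph-convolution passes `z_k = tanh(S X theta_k)` and averaged; the
#' `ceiling(ratio * N)` nodes with the highest mean score are kept (ties
#' broken by lower node index), their features gated by the score, and
#' the adjacency reduced to the induced subgraph.
#'
#' @param X node features (N x d).
#' @param A adjacency with self-loops (N x N).
#' @param theta1,theta2 attention weight vectors (length d).
#' @param ratio pooling ratio in (0, 1].
#' @return List with `X_out` (k x d gated features), `A_out` (k x k
#'   induced adjacency), `kept` (1-based kept indices, score order) and
#'   `scores` (per-node mean attention score y).
#' @export
sag_pool <- function(X, A, theta1, theta2, ratio = 0.75) {
  stopifnot(ratio > 0, ratio <= 1)
  X <- as.matrix(X)
  N <- nrow(X)
  S <- norm_adjacency(A)
  z1 <- tanh(S %*% X %*% matrix(theta1, ncol = 1))
  z2 <- tanh(S %*% X %*% matrix(theta2, ncol = 1))
  y <- as.numeric(z1 + z2) / 2
  k <- ceiling(ratio * N)
  kept <- order(-y, seq_len(N))[seq_len(k)]
  list(X_out = X[kept, , drop = FALSE] * y[kept],
       A_out = A[kept, kept, drop = FALSE],
       kept = kept, scores = y, z1 = z1, z2 = z2, S = S)
}

# backward: dXout (k x d), plus optional dY routed from elsewhere.
sag_pool_bwd <- function(cache, X, theta1, theta2, dXout) {
  kept <- cache$kept
  y <- cache$scores
  S <- cache$S
  dX <- matrix(0, nrow(X), ncol(X))
  dX[kept, ] <- dXout * y[kept]
  dy <- numeric(nrow(X))
  dy[kept] <- rowSums(dXout * X[kept, , drop = FALSE])
  dz <- dy / 2
  dW <- function(z, theta) {
    dpre <- matrix(dz * (1 - as.numeric(z)^2), ncol = 1)
    Sd <- S %*% dpre
    dtheta <- as.numeric(crossprod(X, Sd))
    dX_part <- Sd %*% matrix(theta, nrow = 1)
    list(dtheta = dtheta, dX = dX_part)
  }
  g1 <- dW(cache$z1, theta1)
  g2 <- dW(cache$z2, theta2)
  list(dX = dX + g1$dX + g2$dX, dtheta1 = g1$dtheta, dtheta2 = g2$dtheta)
}

#' Mixed mean/max graph readout
#'
#' Concatenates the node-wise mean and the node-wise elementwise maximum
#' into a fixed-length vector of twice the feature width.
#'
#' @param X node features (N x d), N >= 1.
#' @return Numeric vector of length 2d: `c(mean, max)`.
#' @export
mix_pool <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_graphgo("mix_pool: empty graph")
  c(colMeans(X), apply(X, 2, max))
}

mix_pool_bwd <- function(X, dOut) {
  d <- ncol(X); N <- nrow(X)
  dX <- matrix(rep(dOut[seq_len(d)] / N, each = N), N, d)
  argmax <- apply(X, 2, which.max)  # first max wins on ties
  dX[cbind(argmax, seq_len(d))] <- dX[cbind(argmax, seq_len(d))] + dOut[d + seq_len(d)]
  dX
}

## ---- dense / layernorm / softmax ----------------------------------------

dense_fwd <- function(X, W, b, relu = FALSE) {
  pre <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  list(out = if (relu) pmax(pre, 0) else pre, pre = pre, X = X)
}

dense_bwd <- function(cache, W, dOut, relu = FALSE) {
  dPre <- if (relu) dOut * (cache$pre > 0) else dOut
  list(dX = dPre %*% t(W), dW = crossprod(cache$X, dPre), db = colSums(dPre))
}

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dOut) {
  xhat <- cache$xhat
  dxhat <- sweep(dOut, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dOut * xhat), db = colSums(dOut))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- multi-head self-attention ------------------------------------------

mha_fwd <- function(T_, p, n_heads) {
  d <- ncol(T_)
  dk <- d / n_heads
  Q <- T_ %*% p$Wq + matrix(p$bq, nrow(T_), d, byrow = TRUE)
  K <- T_ %*% p$Wk + matrix(p$bk, nrow(T_), d, byrow = TRUE)
  V <- T_ %*% p$Wv + matrix(p$bv, nrow(T_), d, byrow = TRUE)
  O <- matrix(0, nrow(T_), d)
  P <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    Ah <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk)
    P[[h]] <- softmax_rows(Ah)
    O[, cols] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  out <- O %*% p$Wo + matrix(p$bo, nrow(T_), d, byrow = TRUE)
  list(out = out, Q = Q, K = K, V = V, O = O, P = P, T_ = T_)
}

mha_bwd <- function(cache, p, n_heads, dOut) {
  d <- ncol(cache$T_)
  dk <- d / n_heads
  dO <- dOut %*% t(p$Wo)
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dQ <- matrix(0, nrow(cache$T_), d)
  dK <- matrix(0, nrow(cache$T_), d)
  dV <- matrix(0, nrow(cache$T_), d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    Ph <- cache$P[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dPh <- dOh %*% t(Vh)
    dV[, cols] <- crossprod(Ph, dOh)
    dAh <- Ph * (dPh - rowSums(dPh * Ph))
    dQ[, cols] <- (dAh %*% cache$K[, cols, drop = FALSE]) / sqrt(dk)
    dK[, cols] <- (t(dAh) %*% cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  dT <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dT = dT,
       dWq = crossprod(cache$T_, dQ), dbq = colSums(dQ),
       dWk = crossprod(cache$T_, dK), dbk = colSums(dK),
       dWv = crossprod(cache$T_, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

## ---- transformer encoder layer (post-LN) --------------------------------

transformer_layer_fwd <- function(T_, p, n_heads, drop_masks = NULL) {
  att <- mha_fwd(T_, p, n_heads)
  a <- att$out
  if (!is.null(drop_masks)) a <- a * drop_masks$attn
  ln1 <- layernorm_fwd(T_ + a, p$ln1_g, p$ln1_b)
  f1 <- dense_fwd(ln1$out, p$W1, p$b1, relu = TRUE)
  f2 <- dense_fwd(f1$out, p$W2, p$b2, relu = FALSE)
  f <- f2$out
  if (!is.null(drop_masks)) f <- f * drop_masks$ffn
  ln2 <- layernorm_fwd(ln1$out + f, p$ln2_g, p$ln2_b)
  list(out = ln2$out, att = att, ln1 = ln1, f1 = f1, f2 = f2, ln2 = ln2,
       drop_masks = drop_masks)
}

transformer_layer_bwd <- function(cache, p, n_heads, dOut) {
  g2 <- layernorm_bwd(cache$ln2, p$ln2_g, dOut)
  dresid2 <- g2$dX
  df <- dresid2
  if (!is.null(cache$drop_masks)) df <- df * cache$drop_masks$ffn
  gf2 <- dense_bwd(cache$f2, p$W2, df, relu = FALSE)
  gf1 <- dense_bwd(cache$f1, p$W1, gf2$dX, relu = TRUE)
  dln1_out <- dresid2 + gf1$dX
  g1 <- layernorm_bwd(cache$ln1, p$ln1_g, dln1_out)
  dresid1 <- g1$dX
  da <- dresid1
  if (!is.null(cache$drop_masks)) da <- da * cache$drop_masks$attn
  gm <- mha_bwd(cache$att, p, n_heads, da)
  grads <- list(Wq = gm$dWq, bq = gm$dbq, Wk = gm$dWk, bk = gm$dbk,
                Wv = gm$dWv, bv = gm$dbv, Wo = gm$dWo, bo = gm$dbo,
                ln1_g = g1$dg, ln1_b = g1$db,
                W1 = gf1$dW, b1 = gf1$db, W2 = gf2$dW, b2 = gf2$db,
                ln2_g = g2$dg, ln2_b = g2$db)
  list(dT = dresid1 + gm$dT, grads = grads)
}
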