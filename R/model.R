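## Model assembly: six stacked ConvPoolBlocks (a 3-layer graph-convolution
## stack, self-attention pooling at ratio 0.75, mixed mean/max readout),
## summed block readouts fused with the global sequence embedding, a
## 3-layer 8-head transformer encoder over three role tokens
## (classification, graph, sequence), and a 3-layer fully connected head
## with elementwise logistic outputs.
##
## The fused vector is turned into a short token sequence because a
## transformer needs tokens to attend over: a learned classification
## token, a projected graph-readout token and a projected sequence token.
## The tokens are role-specific, so no positional encoding is needed; the
## classification token's output feeds the head.

#' Model hyperparameter configuration
#'
#' @param n_labels number of GO terms scored.
#' @param node_feature_dim width of the per-node input features.
#' @param seq_embedding_dim width of the global sequence embedding.
#' @param n_blocks stacked ConvPoolBlocks, default 6.
#' @param hidden_dim hidden width (must divide by `attention_heads`),
#'   default 64.
#' @param sag_ratio pooling keep-ratio in (0, 1], default 0.75.
#' @param transformer_layers encoder layers, default 3.
#' @param attention_heads attention heads, default 8.
#' @param classifier_layers fully connected layers in the head, default 3.
#' @param dropout dropout rate in [0, 1), default 0.2.
#' @param use_onehot_node_features whether one-hot residue encodings are
#'   concatenated to the structural node embeddings, default `TRUE`.
#' @param readout_agg how per-block readouts combine: "sum" (default,
#'   keeps the fused width independent of `n_blocks`) or "concat".
#' @param seed integer seed for parameter initialization.
#' @return A `model_config`.
#' @export
model_config <- function(n_labels, node_feature_dim, seq_embedding_dim,
                         n_blocks = 6L, hidden_dim = 64L, sag_ratio = 0.75,
                         transformer_layers = 3L, attention_heads = 8L,
                         classifier_layers = 3L, dropout = 0.2,
                         use_onehot_node_features = TRUE,
                         readout_agg = c("sum", "concat"), seed = 0L) {
  readout_agg <- match.arg(readout_agg)
  stopifnot(n_labels >= 1, node_feature_dim >= 1, seq_embedding_dim >= 1,
            n_blocks >= 1, hidden_dim >= 1, sag_ratio > 0, sag_ratio <= 1,
            transformer_layers >= 1, attention_heads >= 1,
            classifier_layers >= 1, dropout >= 0, dropout < 1)
  if (hidden_dim %% attention_heads != 0) {
    stop_graphgo("hidden_dim must be divisible by attention_heads")
  }
  structure(list(n_labels = as.integer(n_labels),
                 node_feature_dim = as.integer(node_feature_dim),
                 seq_embedding_dim = as.integer(seq_embedding_dim),
                 n_blocks = as.integer(n_blocks),
                 hidden_dim = as.integer(hidden_dim),
                 sag_ratio = sag_ratio,
                 transformer_layers = as.integer(transformer_layers),
                 attention_heads = as.integer(attention_heads),
                 classifier_layers = as.integer(classifier_layers),
                 dropout = dropout,
                 use_onehot_node_features = isTRUE(use_onehot_node_features),
                 readout_agg = readout_agg,
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Uniform fan-based (Glorot) initialization from a stream seeded by
#' `config$seed`; biases and layer-norm offsets start at zero, layer-norm
#' gains at one.
#'
#' @param config a [model_config()].
#' @return A `model_state`: nested named list of parameter matrices.
#' @export
init_model_state <- function(config) {
  d <- config$hidden_dim
  with_seed(derive_seed(config$seed, "init"), {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      din <- if (b == 1) config$node_feature_dim else d
      list(W1 = glorot(din, d), W2 = glorot(d, d), W3 = glorot(d, d),
           theta1 = as.numeric(glorot(d, 1)),
           theta2 = as.numeric(glorot(d, 1)))
    })
    rdim <- if (config$readout_agg == "sum") 2 * d else 2 * d * config$n_blocks
    fuse <- list(Wg = glorot(rdim, d), bg = numeric(d),
                 Ws = glorot(config$seq_embedding_dim, d), bs = numeric(d),
                 cls = as.numeric(glorot(d, 1)))
    tlayers <- lapply(seq_len(config$transformer_layers), function(l) {
      list(Wq = glorot(d, d), bq = numeric(d),
           Wk = glorot(d, d), bk = numeric(d),
           Wv = glorot(d, d), bv = numeric(d),
           Wo = glorot(d, d), bo = numeric(d),
           ln1_g = rep(1, d), ln1_b = numeric(d),
           W1 = glorot(d, 4 * d), b1 = numeric(4 * d),
           W2 = glorot(4 * d, d), b2 = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d))
    })
    head <- lapply(seq_len(config$classifier_layers), function(l) {
      dout <- if (l == config$classifier_layers) config$n_labels else d
      list(W = glorot(d, dout), b = numeric(dout))
    })
    structure(list(blocks = blocks, fuse = fuse, transformer = tlayers,
                   head = head),
              class = "model_state")
  })
}

#' One ConvPoolBlock forward pass
#'
#' A 3-layer graph-convolution stack, self-attention pooling and the
#' mixed mean/max readout.  Returns the reduced graph for the next block.
#'
#' @param X node features, @param A adjacency with self-loops.
#' @param params one element of `state$blocks`.
#' @param ratio pooling ratio.
#' @return List with reduced `X`, `A` and the block `readout` vector.
#' @export
conv_pool_block <- function(X, A, params, ratio = 0.75) {
  S <- norm_adjacency(A)
  H1 <- pmax(S %*% X %*% params$W1, 0)
  H2 <- pmax(S %*% H1 %*% params$W2, 0)
  H3 <- pmax(S %*% H2 %*% params$W3, 0)
  sp <- sag_pool(H3, A, params$theta1, params$theta2, ratio)
  list(X = sp$X_out, A = sp$A_out, readout = mix_pool(sp$X_out))
}

block_fwd <- function(X, A, params, ratio) {
  S <- norm_adjacency(A)
  c1 <- graph_conv_fwd(X, S, params$W1)
  c2 <- graph_conv_fwd(c1$out, S, params$W2)
  c3 <- graph_conv_fwd(c2$out, S, params$W3)
  sp <- sag_pool(c3$out, A, params$theta1, params$theta2, ratio)
  list(X_out = sp$X_out, A_out = sp$A_out, readout = mix_pool(sp$X_out),
       S = S, c1 = c1, c2 = c2, c3 = c3, sp = sp, X = X)
}

block_bwd <- function(cache, params, dXout, dReadout) {
  dXp <- dXout + mix_pool_bwd(cache$sp$X_out, dReadout)
  gs <- sag_pool_bwd(cache$sp, cache$c3$out, params$theta1, params$theta2, dXp)
  g3 <- graph_conv_bwd(cache$c3, cache$S, params$W3, gs$dX)
  g2 <- graph_conv_bwd(cache$c2, cache$S, params$W2, g3$dH)
  g1 <- graph_conv_bwd(cache$c1, cache$S, params$W1, g2$dH)
  list(dX = g1$dH,
       grads = list(W1 = g1$dW, W2 = g2$dW, W3 = g3$dW,
                    theta1 = gs$dtheta1, theta2 = gs$dtheta2))
}

make_drop_mask <- function(dimr, dimc, rate) {
  if (rate <= 0) return(matrix(1, dimr, dimc))
  matrix((runif(dimr * dimc) >= rate) / (1 - rate), dimr, dimc)
}

# Forward pass for one protein.
# input: list(A = adjacency with self-loops, X = node features, h = seq emb)
protein_fwd <- function(input, state, config, train = FALSE) {
  caches <- list()
  X <- input$X; A <- input$A
  readouts <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    bc <- block_fwd(X, A, state$blocks[[b]], config$sag_ratio)
    caches$blocks[[b]] <- bc
    readouts[[b]] <- bc$readout
    X <- bc$X_out; A <- bc$A_out
  }
  r <- if (config$readout_agg == "sum") {
    Reduce(`+`, readouts)
  } else {
    unlist(readouts, use.names = FALSE)
  }
  fu <- state$fuse
  tg <- as.numeric(matrix(r, 1) %*% fu$Wg) + fu$bg
  ts <- as.numeric(matrix(input$h, 1) %*% fu$Ws) + fu$bs
  T_ <- rbind(fu$cls, tg, ts)
  caches$r <- r
  d <- config$hidden_dim
  caches$tlayers <- vector("list", config$transformer_layers)
  for (l in seq_len(config$transformer_layers)) {
    dm <- if (train && config$dropout > 0) {
      list(attn = make_drop_mask(3, d, config$dropout),
           ffn = make_drop_mask(3, d, config$dropout))
    } else NULL
    tc <- transformer_layer_fwd(T_, state$transformer[[l]],
                                config$attention_heads, dm)
    caches$tlayers[[l]] <- tc
    T_ <- tc$out
  }
  u <- T_[1, , drop = FALSE]  # classification token
  caches$head <- vector("list", config$classifier_layers)
  caches$head_drop <- vector("list", config$classifier_layers)
  for (l in seq_len(config$classifier_layers)) {
    last <- l == config$classifier_layers
    hc <- dense_fwd(u, state$head[[l]]$W, state$head[[l]]$b, relu = !last)
    caches$head[[l]] <- hc
    u <- hc$out
    if (!last && train && config$dropout > 0) {
      dm <- make_drop_mask(1, ncol(u), config$dropout)
      caches$head_drop[[l]] <- dm
      u <- u * dm
    }
  }
  logits <- as.numeric(u)
  scores <- 1 / (1 + exp(-logits))
  list(scores = scores, logits = logits, caches = caches)
}

# Backward for one protein given dLogits; returns grads shaped like state.
protein_bwd <- function(fwd, input, state, config, dLogits) {
  caches <- fwd$caches
  grads <- zero_like(state)
  dU <- matrix(dLogits, 1)
  for (l in rev(seq_len(config$classifier_layers))) {
    last <- l == config$classifier_layers
    if (!last && !is.null(caches$head_drop[[l]])) dU <- dU * caches$head_drop[[l]]
    g <- dense_bwd(caches$head[[l]], state$head[[l]]$W, dU, relu = !last)
    grads$head[[l]]$W <- g$dW
    grads$head[[l]]$b <- g$db
    dU <- g$dX
  }
  dT <- matrix(0, 3, config$hidden_dim)
  dT[1, ] <- dU
  for (l in rev(seq_len(config$transformer_layers))) {
    g <- transformer_layer_bwd(caches$tlayers[[l]], state$transformer[[l]],
                               config$attention_heads, dT)
    grads$transformer[[l]] <- g$grads
    dT <- g$dT
  }
  dcls <- dT[1, ]
  dtg <- dT[2, ]
  dts <- dT[3, ]
  fu <- state$fuse
  grads$fuse$cls <- dcls
  grads$fuse$Wg <- outer(caches$r, dtg)
  grads$fuse$bg <- dtg
  grads$fuse$Ws <- outer(as.numeric(input$h), dts)
  grads$fuse$bs <- dts
  dr <- as.numeric(fu$Wg %*% dtg)

  dXout <- NULL
  for (b in rev(seq_len(config$n_blocks))) {
    bc <- caches$blocks[[b]]
    dReadout <- if (config$readout_agg == "sum") {
      dr
    } else {
      len <- 2 * config$hidden_dim
      dr[((b - 1) * len + 1):(b * len)]
    }
    if (is.null(dXout)) dXout <- matrix(0, nrow(bc$X_out), ncol(bc$X_out))
    g <- block_bwd(bc, state$blocks[[b]], dXout, dReadout)
    grads$blocks[[b]] <- g$grads
    dXout <- g$dX
  }
  grads
}

#' Forward scoring of a batch of proteins
#'
#' Eval-mode forward pass: a pure function of inputs and state (no
#' dropout).  Proteins are processed as a disjoint union, i.e.
#' independently.
#'
#' @param inputs named list, one entry per protein:
#'   `list(A = adjacency with self-loops, X = node features, h = global
#'   sequence embedding)`.
#' @param state a `model_state`.
#' @param config the matching [model_config()].
#' @return Score matrix (proteins x n_labels) with entries in [0, 1] and
#'   rownames the protein ids.
#' @export
model_forward <- function(inputs, state, config) {
  missing_h <- names(inputs)[vapply(inputs, function(x) is.null(x$h), logical(1))]
  if (length(missing_h)) {
    stop_graphgo(sprintf("missing sequence embedding for protein(s): %s",
                         paste(missing_h, collapse = ", ")))
  }
  out <- matrix(0, length(inputs), config$n_labels,
                dimnames = list(names(inputs), NULL))
  for (i in seq_along(inputs)) {
    out[i, ] <- protein_fwd(inputs[[i]], state, config, train = FALSE)$scores
  }
  out
}

#' Binary cross-entropy loss for multilabel scores
#' @param scores numeric vector/matrix in (0, 1).
#' @param labels 0/1 vector/matrix of the same shape.
#' @return Mean BCE over all entries.
#' @export
bce_loss <- function(scores, labels) {
  eps <- 1e-12
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

## ---- parameter-tree utilities -------------------------------------------

zero_like <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, zero_like)
    attributes(out) <- attributes(x)
    out
  } else {
    x * 0
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), use.names = FALSE) else as.numeric(x)
}

#' Save model state and config to a file
#' @param state a `model_state`; @param config its [model_config()].
#' @param path output path (RDS archive).
#' @return `path`, invisibly.
#' @export
save_model <- function(state, config, path) {
  saveRDS(list(state = state, config = config, format = "graphgo-model-1"), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path archive path.
#' @return List with `state` and `config`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "graphgo-model-1")) {
    stop_graphgo("not a graphgo model archive")
  }
  obj[c("state", "config")]
}
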