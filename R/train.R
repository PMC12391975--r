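## Dataset splitting and the training loop (Adam on elementwise binary
## cross-entropy, early stopping on validation Fmax).

#' Split specification
#' @param train_frac,valid_frac,test_frac positive fractions summing to 1;
#'   defaults 0.7 / 0.2 / 0.1.
#' @param seed integer seed.
#' @return A `split_spec`.
#' @export
split_spec <- function(train_frac = 0.7, valid_frac = 0.2, test_frac = 0.1,
                       seed = 0L) {
  stopifnot(train_frac > 0, valid_frac > 0, test_frac > 0)
  if (abs(train_frac + valid_frac + test_frac - 1) > 1e-9) {
    stop_graphgo("split fractions must sum to 1")
  }
  structure(list(train_frac = train_frac, valid_frac = valid_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly partition protein ids into train / validation / test sets
#'
#' Sizes follow largest-remainder rounding of the fractions (so 10
#' proteins at 7:2:1 give exactly 7 / 2 / 1); the partition is disjoint,
#' exhaustive, and deterministic in the seed.
#'
#' @param protein_ids character vector (>= 10 ids).
#' @param spec a [split_spec()].
#' @return List with `train`, `valid`, `test` id vectors.
#' @export
split_dataset <- function(protein_ids, spec = split_spec()) {
  n <- length(protein_ids)
  if (n < 10L) stop_graphgo("need at least 10 proteins to split")
  fr <- c(spec$train_frac, spec$valid_frac, spec$test_frac)
  raw <- n * fr
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(-(raw - sizes))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  ids <- with_seed(derive_seed(spec$seed, "split"), sample(protein_ids))
  list(train = ids[seq_len(sizes[1])],
       valid = ids[sizes[1] + seq_len(sizes[2])],
       test = ids[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Training configuration
#'
#' @param batch_size minibatch size, default 32.
#' @param epochs training epochs, default 30.
#' @param learning_rate Adam learning rate, default 1e-3.
#' @param early_stop_patience epochs without validation-Fmax improvement
#'   before stopping, default 10.
#' @param seed integer seed (shuffling and dropout).
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 30L, learning_rate = 1e-3,
                         early_stop_patience = 10L, seed = 0L) {
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate > 0,
            early_stop_patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Per-namespace tuning defaults
#'
#' Dropout 0.2 with batch size 32 for MFO and CCO; dropout 0.3 with
#' batch size 64 for BPO.
#'
#' @param namespace "MFO", "BPO" or "CCO".
#' @return List with `dropout` and `batch_size`.
#' @export
train_defaults <- function(namespace = c("MFO", "BPO", "CCO")) {
  namespace <- match.arg(namespace)
  if (namespace == "BPO") list(dropout = 0.3, batch_size = 64L)
  else list(dropout = 0.2, batch_size = 32L)
}

# One Adam step over the whole parameter tree; returns updated trees.
adam_step <- function(state, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(s, g, m_, v_) {
    if (is.list(s)) {
      out_s <- s; out_m <- m_; out_v <- v_
      for (k in seq_along(s)) {
        r <- rec(s[[k]], g[[k]], m_[[k]], v_[[k]])
        out_s[[k]] <- r$s; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(s = out_s, m = out_m, v = out_v)
    } else {
      m_ <- beta1 * m_ + (1 - beta1) * g
      v_ <- beta2 * v_ + (1 - beta2) * g^2
      mhat <- m_ / (1 - beta1^t)
      vhat <- v_ / (1 - beta2^t)
      list(s = s - lr * mhat / (sqrt(vhat) + eps), m = m_, v = v_)
    }
  }
  rec(state, grads, m, v)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

#' Train the model
#'
#' Minibatch Adam on elementwise binary cross-entropy; after every epoch
#' the validation Fmax is computed in eval mode and the best-scoring
#' state is retained.  Training stops early after
#' `early_stop_patience` epochs without improvement, and aborts with a
#' diagnostic if the loss turns non-finite.  Deterministic for fixed
#' seeds (single-threaded).
#'
#' @param inputs named list of per-protein model inputs
#'   (`list(A, X, h)`, see [model_forward()]).
#' @param labels binary matrix (proteins x terms) with rownames; must
#'   cover every id in the split.
#' @param split list with `train` and `valid` id vectors.
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `state` (best validation Fmax), `log` (data frame of
#'   epoch, train_loss, valid_fmax), `best_epoch` and `best_valid_fmax`.
#' @export
train_model <- function(inputs, labels, split, config, tconfig = train_config(),
                        verbose = FALSE) {
  if (inherits(labels, "label_matrix")) labels <- labels$matrix
  missing_ids <- setdiff(c(split$train, split$valid),
                         intersect(names(inputs), rownames(labels)))
  if (length(missing_ids)) {
    stop_graphgo(sprintf("split ids missing from inputs/labels: %s",
                         paste(head(missing_ids, 5), collapse = ", ")))
  }
  state <- init_model_state(config)
  log_df <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       valid_fmax = numeric(0))
  if (tconfig$epochs == 0L) {
    return(list(state = state, log = log_df, best_epoch = 0L,
                best_valid_fmax = NA_real_))
  }
  m <- zero_like(state); v <- zero_like(state)
  t <- 0L
  valid_inputs <- inputs[split$valid]
  valid_labels <- labels[split$valid, , drop = FALSE]
  best <- list(state = state, fmax = -Inf, epoch = 0L)
  stale <- 0L
  nl <- config$n_labels

  for (ep in seq_len(tconfig$epochs)) {
    ep_seed <- derive_seed(tconfig$seed, paste0("epoch-", ep))
    ep_loss <- with_seed(ep_seed, {
      ids <- sample(split$train)
      batches <- split(ids, ceiling(seq_along(ids) / tconfig$batch_size))
      total_loss <- 0
      for (batch in batches) {
        bgrads <- NULL
        bloss <- 0
        for (pid in batch) {
          fwd <- protein_fwd(inputs[[pid]], state, config, train = TRUE)
          y <- labels[pid, ]
          bloss <- bloss + bce_loss(fwd$scores, y)
          dLogits <- (fwd$scores - y) / (nl * length(batch))
          g <- protein_bwd(fwd, inputs[[pid]], state, config, dLogits)
          bgrads <- if (is.null(bgrads)) g else tree_add(bgrads, g)
        }
        bloss <- bloss / length(batch)
        if (!is.finite(bloss)) {
          stop_graphgo(sprintf("non-finite training loss at epoch %d", ep))
        }
        t <- t + 1L
        upd <- adam_step(state, bgrads, m, v, tconfig$learning_rate, t)
        state <- upd$s; m <- upd$m; v <- upd$v
        total_loss <- total_loss + bloss * length(batch)
      }
      total_loss / length(ids)
    })
    preds <- model_forward(valid_inputs, state, config)
    vf <- suppressWarnings(fmax(valid_labels, preds)$fmax)
    log_df <- rbind(log_df, data.frame(epoch = ep, train_loss = ep_loss,
                                       valid_fmax = vf))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  valid Fmax %.4f", ep, ep_loss, vf))
    }
    if (vf > best$fmax + 1e-12) {
      best <- list(state = state, fmax = vf, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tconfig$early_stop_patience) break
    }
  }
  list(state = best$state, log = log_df, best_epoch = best$epoch,
       best_valid_fmax = best$fmax)
}

#' Assemble per-protein model inputs
#'
#' Combines contact graphs, structural node embeddings, optional one-hot
#' residue features and global sequence embeddings into the input format
#' of [model_forward()].  Node counts must agree across sources.
#'
#' @param graphs named list of [contact_graph()]s (with self-loops).
#' @param node_embeddings named list of `embedding_table`s.
#' @param records named list of [sequence_record()]s (needed when
#'   `use_onehot` is `TRUE`).
#' @param seq_embeddings named list of `global_embedding`s.
#' @param use_onehot concatenate one-hot residue features to the node
#'   embeddings.
#' @return Named list of `list(A, X, h)` inputs.
#' @export
assemble_inputs <- function(graphs, node_embeddings, records = NULL,
                            seq_embeddings, use_onehot = TRUE) {
  ids <- names(graphs)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (pid in ids) {
    g <- graphs[[pid]]
    emb <- node_embeddings[[pid]]
    if (is.null(emb)) stop_graphgo(sprintf("no node embeddings for %s", pid))
    if (nrow(emb$vectors) != g$n_nodes) {
      stop_graphgo(sprintf("node count mismatch for %s: graph %d vs embeddings %d",
                           pid, g$n_nodes, nrow(emb$vectors)))
    }
    X <- emb$vectors
    if (use_onehot) {
      rec <- records[[pid]]
      if (is.null(rec)) stop_graphgo(sprintf("no sequence record for %s", pid))
      oh <- one_hot_encode(rec)
      if (nrow(oh) != g$n_nodes) {
        stop_graphgo(sprintf("sequence length mismatch for %s", pid))
      }
      X <- cbind(X, oh)
    }
    se <- seq_embeddings[[pid]]
    if (is.null(se)) stop_graphgo(sprintf("missing sequence embedding for %s", pid))
    out[[pid]] <- list(A = adjacency_matrix(g, include_self_loops = TRUE),
                       X = unname(X), h = se$vector)
  }
  out
}

#' All-positive baseline prediction matrix
#'
#' The constant predictor that assigns score 1 to every protein-term
#' pair; its Fmax is the floor any trained model must beat.
#'
#' @param labels binary label matrix (or `label_matrix`).
#' @return Score matrix of ones shaped like `labels`.
#' @export
all_positive_baseline <- function(labels) {
  if (inherits(labels, "label_matrix")) labels <- labels$matrix
  array(1, dim = dim(labels), dimnames = dimnames(labels))
}
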