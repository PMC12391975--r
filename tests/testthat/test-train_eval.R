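test_that("split_dataset uses largest-remainder sizes and is deterministic", {
  ids <- sprintf("P%02d", 1:10)
  sp <- split_dataset(ids, split_spec(seed = 1))
  expect_length(sp$train, 7)
  expect_length(sp$valid, 2)
  expect_length(sp$test, 1)
  expect_setequal(unlist(sp), ids)
  expect_identical(sp, split_dataset(ids, split_spec(seed = 1)))
  expect_false(identical(sp, split_dataset(ids, split_spec(seed = 2))))
  expect_error(split_dataset(ids[1:5], split_spec()), "at least 10")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("splits are disjoint and exhaustive across random id sets", {
  set.seed(0)
  for (rep in 1:50) {
    n <- sample(10:400, 1)
    ids <- sprintf("Q%05d", sample(1e5, n))
    sp <- split_dataset(ids, split_spec(seed = rep))
    all_ids <- c(sp$train, sp$valid, sp$test)
    expect_equal(length(all_ids), n)
    expect_equal(anyDuplicated(all_ids), 0)
    expect_setequal(all_ids, ids)
  }
})

test_that("fmax is exact on hand-checkable cases", {
  L <- rbind(c(1, 1, 0), c(0, 0, 1))
  # perfect predictor
  expect_equal(fmax(L, L)$fmax, 1)
  # the derived 2x3 example agrees with the literal oracle
  S <- rbind(c(0.9, 0.6, 0.2), c(0.1, 0.8, 0.7))
  expect_equal(fmax(L, S)$fmax, oracle_fmax(L, S), tolerance = 1e-12)
  # all-zero scores: only tau = 0 predicts anything, everything predicted
  S0 <- matrix(0, 2, 3)
  res <- fmax(L, S0)
  pr0 <- mean(c(2 / 3, 1 / 3))
  expect_equal(res$threshold, 0)
  expect_equal(res$fmax, 2 * pr0 * 1 / (pr0 + 1), tolerance = 1e-12)
})

test_that("fmax matches the oracle on random instances and permutes freely", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(3:20, 1); m <- sample(2:8, 1)
    L <- matrix(rbinom(n * m, 1, 0.35), n, m)
    L[rowSums(L) == 0, sample(m, 1)] <- 1
    S <- matrix(round(runif(n * m), 2), n, m)
    expect_equal(fmax(L, S)$fmax, oracle_fmax(L, S), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(fmax(L[perm, ], S[perm, ])$fmax, fmax(L, S)$fmax)
  }
})

test_that("fmax warns on proteins without true labels", {
  L <- rbind(c(1, 0), c(0, 0))
  S <- rbind(c(0.9, 0.1), c(0.2, 0.3))
  expect_warning(res <- fmax(L, S), "zero true labels")
  expect_gte(res$fmax, 0)
})

test_that("AUC and AUPR agree with brute-force oracles", {
  set.seed(2)
  for (rep in 1:15) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (all(y == 1) || all(y == 0)) y[1:2] <- c(0, 1)
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(auc_score(matrix(y, 1), matrix(s, 1)), oracle_auc(y, s),
                 tolerance = 1e-12)
    expect_equal(aupr_score(matrix(y, 1), matrix(s, 1)), oracle_aupr(y, s),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(40)
  a0 <- auc_score(matrix(y, 1), matrix(s, 1))
  expect_equal(auc_score(matrix(y, 1), matrix(exp(3 * s), 1)), a0)
  expect_equal(auc_score(matrix(y, 1), matrix(s^3, 1)), a0)
})

test_that("perfect separation gives AUC = AUPR = 1 and errors on one class", {
  y <- c(rep(0, 5), rep(1, 5))
  s <- c(runif(5, 0, 0.4), runif(5, 0.6, 1))
  expect_equal(auc_score(matrix(y, 1), matrix(s, 1)), 1)
  expect_equal(aupr_score(matrix(y, 1), matrix(s, 1)), 1)
  expect_error(auc_score(matrix(rep(1, 4), 1), matrix(runif(4), 1)), "class")
})

test_that("macro averaging differs from micro only by aggregation", {
  set.seed(4)
  L <- matrix(rbinom(60, 1, 0.4), 10, 6)
  L[, 1] <- c(rep(1, 5), rep(0, 5))
  S <- matrix(runif(60), 10, 6)
  macro <- auc_score(L, S, average = "macro")
  cols <- which(colSums(L) > 0 & colSums(L) < 10)
  manual <- mean(vapply(cols, function(j) oracle_auc(L[, j], S[, j]), 1))
  expect_equal(macro, manual, tolerance = 1e-12)
})

test_that("train_model with epochs = 0 returns the initial state and empty log", {
  cfg <- tiny_model_config()
  inputs <- setNames(lapply(1:12, function(i) random_model_input(5, seed = i)),
                     sprintf("P%02d", 1:12))
  labels <- matrix(rbinom(36, 1, 0.5), 12, 3,
                   dimnames = list(names(inputs), NULL))
  sp <- split_dataset(names(inputs), split_spec(seed = 0))
  fit <- train_model(inputs, labels, sp, cfg, train_config(epochs = 0))
  expect_equal(fit$state, init_model_state(cfg))
  expect_equal(nrow(fit$log), 0)
})

test_that("training reduces the loss and is reproducible", {
  cfg <- tiny_model_config(seed = 1)
  set.seed(10)
  n <- 14
  inputs <- setNames(lapply(1:n, function(i) random_model_input(6, seed = i)),
                     sprintf("P%02d", 1:n))
  # learnable labels: depend on the sequence embedding sign
  labels <- t(vapply(inputs, function(x) as.integer(x$h[1:3] > 0), integer(3)))
  rownames(labels) <- names(inputs)
  sp <- list(train = names(inputs)[1:10], valid = names(inputs)[11:14])
  tc <- train_config(batch_size = 5, epochs = 8, learning_rate = 3e-3, seed = 2)
  fit <- suppressWarnings(train_model(inputs, labels, sp, cfg, tc))
  expect_lt(fit$log$train_loss[8], fit$log$train_loss[1])
  fit2 <- suppressWarnings(train_model(inputs, labels, sp, cfg, tc))
  expect_identical(fit$log, fit2$log)
  expect_equal(fit$state, fit2$state)
})

test_that("assemble_inputs validates alignment and builds feature blocks", {
  g <- build_contact_graph(residue_chain("P1", 1:3, c("A", "C", "D"),
                                         rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))))
  emb <- structure(list(vectors = matrix(rnorm(9), 3, 3), dim = 3L,
                        n_nodes = 3L), class = "embedding_table")
  rec <- sequence_record("P1", "ACD")
  se <- global_embedding("P1", rnorm(4), source = "mock")
  inp <- assemble_inputs(list(P1 = g), list(P1 = emb), list(P1 = rec),
                         list(P1 = se), use_onehot = TRUE)
  expect_equal(ncol(inp$P1$X), 3 + 21)
  expect_equal(diag(inp$P1$A), rep(1, 3))
  inp2 <- assemble_inputs(list(P1 = g), list(P1 = emb), NULL,
                          list(P1 = se), use_onehot = FALSE)
  expect_equal(ncol(inp2$P1$X), 3)
  bad <- structure(list(vectors = matrix(0, 2, 3)), class = "embedding_table")
  expect_error(assemble_inputs(list(P1 = g), list(P1 = bad), list(P1 = rec),
                               list(P1 = se)), "mismatch")
})
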