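test_that("graph_conv matches hand-computed values", {
  # single node with self-loop, identity weight: fixed point
  A1 <- matrix(1, 1, 1)
  H1 <- matrix(c(2, -3), 1)
  expect_equal(graph_conv(H1, A1, diag(2), activation = "identity"), H1)

  # two joined nodes with self-loops: normalized adjacency is all-1/2
  A2 <- matrix(1, 2, 2)
  H2 <- matrix(c(1, 0), 2)
  out <- graph_conv(H2, A2, matrix(1), activation = "identity")
  expect_equal(out, matrix(c(0.5, 0.5), 2))

  expect_error(graph_conv(H2, A2, matrix(1, 3, 1)), "dim")
})

test_that("graph_conv is permutation equivariant", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 8
    inp <- random_model_input(n, node_dim = 4, seed = rep)
    W <- matrix(rnorm(4 * 6), 4, 6)
    P <- diag(n)[sample(n), ]
    lhs <- graph_conv(P %*% inp$X, P %*% inp$A %*% t(P), W)
    rhs <- P %*% graph_conv(inp$X, inp$A, W)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("sag_pool keeps ceiling(ratio*N) nodes chosen by mean score", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    inp <- random_model_input(n, node_dim = 6, seed = 100 + rep)
    th1 <- rnorm(6); th2 <- rnorm(6)
    res <- sag_pool(inp$X, inp$A, th1, th2, ratio = 0.75)
    k <- ceiling(0.75 * n)
    expect_length(res$kept, k)
    # sort oracle with low-index tie-break
    expect_equal(res$kept, order(-res$scores, seq_len(n))[1:k])
    # induced-subgraph oracle
    sub <- matrix(0, k, k)
    for (a in 1:k) for (b in 1:k) sub[a, b] <- inp$A[res$kept[a], res$kept[b]]
    expect_equal(unname(res$A_out), sub)
    # gating
    expect_equal(res$X_out, inp$X[res$kept, ] * res$scores[res$kept])
  }
  # N = 4, ratio 0.75 keeps ceiling(3) = 3 nodes
  inp <- random_model_input(4, node_dim = 3, seed = 3)
  expect_length(sag_pool(inp$X, inp$A, rnorm(3), rnorm(3), 0.75)$kept, 3)
})

test_that("sag_pool at ratio 1 is pure gating and N = 1 survives", {
  inp <- random_model_input(5, node_dim = 4, seed = 9)
  th <- rnorm(4)
  res <- sag_pool(inp$X, inp$A, th, th, ratio = 1)
  expect_length(res$kept, 5)
  expect_equal(res$X_out[order(res$kept), ], inp$X * res$scores,
               tolerance = 1e-12)
  one <- sag_pool(matrix(1:3, 1), matrix(1, 1, 1), rnorm(3), rnorm(3), 0.5)
  expect_equal(dim(one$X_out), c(1L, 3L))
})

test_that("mix_pool concatenates mean and max and is permutation invariant", {
  v <- c(4, -2, 7)
  expect_equal(mix_pool(matrix(v, 1)), c(v, v))
  expect_equal(mix_pool(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5, 1, 1))
  set.seed(4)
  X <- matrix(rnorm(24), 6, 4)
  expect_equal(mix_pool(X[sample(6), ]), mix_pool(X))
  expect_error(mix_pool(matrix(numeric(0), 0, 2)), "empty")
})

test_that("conv_pool_block reduces node counts per graph independently", {
  cfg <- tiny_model_config()
  st <- init_model_state(cfg)
  inp1 <- random_model_input(8, seed = 1)
  inp2 <- random_model_input(8, seed = 1)
  b1 <- conv_pool_block(inp1$X, inp1$A, st$blocks[[1]], 0.75)
  b2 <- conv_pool_block(inp2$X, inp2$A, st$blocks[[1]], 0.75)
  expect_equal(b1$readout, b2$readout)           # identical graphs
  expect_equal(nrow(b1$X), ceiling(0.75 * 8))
  inp3 <- random_model_input(5, seed = 2)
  b3 <- conv_pool_block(inp3$X, inp3$A, st$blocks[[1]], 0.75)
  expect_equal(nrow(b3$X), ceiling(0.75 * 5))    # independent of inp1
})

test_that("forward produces probabilities, is deterministic, and permutes rows", {
  cfg <- tiny_model_config()
  st <- init_model_state(cfg)
  inputs <- list(a = random_model_input(7, seed = 1),
                 b = random_model_input(5, seed = 2),
                 c = random_model_input(9, seed = 3))
  s1 <- model_forward(inputs, st, cfg)
  expect_equal(dim(s1), c(3L, 3L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1, model_forward(inputs, st, cfg))
  s2 <- model_forward(inputs[c(3, 1, 2)], st, cfg)
  expect_equal(s2[rownames(s1), ], s1)
  expect_error(model_forward(list(z = list(A = diag(2), X = matrix(0, 2, 5))),
                             st, cfg), "missing sequence embedding")
})

test_that("analytic gradients match finite differences for every tensor", {
  cfg <- tiny_model_config()
  st <- init_model_state(cfg)
  inp <- random_model_input(6, seed = 5)
  y <- c(1, 0, 1)
  loss_fn <- function(state) {
    bce_loss(graphgo:::protein_fwd(inp, state, cfg, train = FALSE)$scores, y)
  }
  fwd <- graphgo:::protein_fwd(inp, st, cfg, train = FALSE)
  gr <- graphgo:::protein_bwd(fwd, inp, st, cfg,
                              (fwd$scores - y) / cfg$n_labels)
  eps <- 1e-6
  paths <- param_paths(st)
  set.seed(8)
  for (pp in paths) {
    nz <- FALSE
    for (ix in unique(c(1, sample(pp$n, min(2, pp$n))))) {
      v0 <- param_get(st, pp$path)[ix]
      num <- (loss_fn(param_set_elem(st, pp$path, ix, v0 + eps)) -
              loss_fn(param_set_elem(st, pp$path, ix, v0 - eps))) / (2 * eps)
      ana <- param_get(gr, pp$path)[ix]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = paste("grad", paste(pp$path, collapse = "/")))
    }
    # gradient flow: every parameter tensor gets signal somewhere
    expect_true(any(param_get(gr, pp$path) != 0),
                label = paste("nonzero grad for", paste(pp$path, collapse = "/")))
  }
})

test_that("model state round-trips through save/load", {
  cfg <- tiny_model_config()
  st <- init_model_state(cfg)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(st, cfg, tmp)
  back <- load_model(tmp)
  expect_equal(back$state, st)
  expect_equal(back$config$hidden_dim, cfg$hidden_dim)
  saveRDS(list(x = 1), tmp)
  expect_error(load_model(tmp), "not a graphgo model")
})

test_that("config validation enforces divisibility and ranges", {
  expect_error(model_config(3, 5, 4, hidden_dim = 10, attention_heads = 8),
               "divisible")
  expect_error(model_config(0, 5, 4), "n_labels")
})
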