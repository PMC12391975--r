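test_that("alpha_pq implements the three-case walk bias", {
  expect_equal(alpha_pq(0L, 0.8, 1.2), 1.25)
  expect_equal(alpha_pq(1L, 0.8, 1.2), 1)
  expect_equal(alpha_pq(2L, 0.8, 1.2), 1 / 1.2)
  expect_equal(alpha_pq(c(0L, 1L, 2L), 1, 1), c(1, 1, 1))
  expect_error(alpha_pq(3L, 1, 1), "d_tx")
})

test_that("transition distribution matches hand-computed path-graph values", {
  g <- path3_graph()
  pr <- transition_distribution(g, prev = 0, curr = 1, walk_config(p = 0.8, q = 1.2))
  expect_equal(unname(pr[c("0", "2")]), c(0.6, 0.4), tolerance = 1e-12)

  # triangle with p = q = 1: uniform over the two non-stay neighbors
  tri <- contact_graph("tri", 3, rbind(c(0, 1), c(1, 2), c(0, 2)))
  pr <- transition_distribution(tri, prev = 0, curr = 1, walk_config(p = 1, q = 1))
  expect_equal(unname(pr), c(0.5, 0.5))
})

test_that("transition distribution equals the brute-force oracle on random graphs", {
  cfgs <- list(walk_config(p = 0.8, q = 1.2), walk_config(p = 2, q = 0.5))
  for (seed in 1:30) {
    n <- 4 + seed %% 9
    g <- random_test_graph(n, p_edge = 0.35, seed = seed)
    A <- walk_adjacency(g)
    cfg <- cfgs[[1 + seed %% 2]]
    set.seed(seed)
    v <- sample(n, 1)
    nbrs <- which(A[v, ] > 0)
    t <- sample(nbrs, 1)
    pr <- transition_distribution(g, prev = t - 1, curr = v - 1, cfg)
    orc <- oracle_transition(A, t, v, cfg$p, cfg$q)
    expect_equal(pr, orc, tolerance = 1e-12)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # first step: weight-proportional
    pr0 <- transition_distribution(g, prev = NA, curr = v - 1, cfg)
    expect_equal(pr0, oracle_transition(A, NA, v, cfg$p, cfg$q), tolerance = 1e-12)
  }
})

test_that("stranded walkers raise from transition_distribution but truncate walks", {
  iso <- contact_graph("iso", 2, rbind(c(0, 0), c(1, 1)), has_self_loops = TRUE)
  expect_error(transition_distribution(iso, NA, 0, walk_config()), "stranded")
  w <- generate_walks(iso, walk_config(walks_per_node = 2, walk_length = 5))
  expect_true(all(lengths(w) == 1))
})

test_that("walks are reproducible, start at each node, and obey walk_length", {
  g <- random_test_graph(8, seed = 4)
  cfg <- walk_config(walks_per_node = 3, walk_length = 7, seed = 11)
  w1 <- generate_walks(g, cfg)
  w2 <- generate_walks(g, cfg)
  expect_identical(w1, w2)
  expect_length(w1, 8 * 3)
  expect_true(all(lengths(w1) == 7))
  starts <- vapply(w1, `[`, integer(1), 1)
  expect_equal(sort(unique(starts)), 0:7)

  w3 <- generate_walks(g, walk_config(walks_per_node = 2, walk_length = 1))
  expect_true(all(lengths(w3) == 1))

  # consecutive walk states are always adjacent in the walk graph
  A <- walk_adjacency(g)
  for (w in w1[1:6]) {
    for (s in seq_len(length(w) - 1)) {
      expect_equal(A[w[s] + 1, w[s + 1] + 1], 1)
    }
  }
})

test_that("empirical step frequencies match the exact kernel on the path graph", {
  g <- path3_graph()
  cfg <- walk_config(p = 0.8, q = 1.2, walks_per_node = 4000, walk_length = 3,
                     seed = 5)
  w <- generate_walks(g, cfg)
  # two-step walks starting at an endpoint pass through node 1 with a known
  # predecessor; count the second transition
  from0 <- Filter(function(x) x[1] == 0 && x[2] == 1, w)
  steps <- vapply(from0, `[`, integer(1), 3)
  n <- length(steps)
  phat <- mean(steps == 0)
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(phat - 0.6), 3 * se)
})

test_that("skip-gram embeddings have the right shape and are deterministic", {
  g <- random_test_graph(10, seed = 2)
  cfg <- walk_config(walks_per_node = 4, walk_length = 20,
                     embedding_dim = 12, epochs = 2, seed = 3)
  walks <- generate_walks(g, cfg)
  t1 <- train_embeddings(walks, g$n_nodes, cfg)
  t2 <- train_embeddings(walks, g$n_nodes, cfg)
  expect_identical(t1$vectors, t2$vectors)
  expect_equal(dim(t1$vectors), c(10L, 12L))
  expect_true(all(is.finite(t1$vectors)))
})

test_that("nodes absent from all walks get zero vectors with a warning", {
  walks <- list(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L))
  expect_warning(
    tab <- train_embeddings(walks, 3L, walk_config(embedding_dim = 6)),
    "absent")
  expect_equal(tab$vectors[3, ], rep(0, 6))
  expect_true(any(tab$vectors[1, ] != 0))
})

test_that("embeddings separate structural communities (two cliques)", {
  # two 6-cliques joined by a single edge
  edges <- NULL
  for (i in 0:5) for (j in 0:5) if (i < j) edges <- rbind(edges, c(i, j))
  for (i in 6:11) for (j in 6:11) if (i < j) edges <- rbind(edges, c(i, j))
  edges <- rbind(edges, c(5, 6))
  g <- contact_graph("cliques", 12, edges)
  cfg <- walk_config(walks_per_node = 10, walk_length = 40,
                     embedding_dim = 16, epochs = 5, seed = 0)
  tab <- embed_protein(g, cfg)
  V <- tab$vectors
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  intra <- c(); inter <- c()
  for (i in 1:12) for (j in 1:12) {
    if (i < j) {
      cs <- cosine(V[i, ], V[j, ])
      if ((i <= 6) == (j <= 6)) intra <- c(intra, cs) else inter <- c(inter, cs)
    }
  }
  expect_gt(mean(intra), mean(inter))
})

test_that("embed_protein handles degenerate graphs", {
  solo <- contact_graph("solo", 1, matrix(c(0L, 0L), 1), has_self_loops = TRUE)
  tab <- suppressWarnings(embed_protein(solo, walk_config(embedding_dim = 4)))
  expect_equal(dim(tab$vectors), c(1L, 4L))
  expect_true(all(is.finite(tab$vectors)))

  ring <- contact_graph("ring", 20, cbind(0:19, c(1:19, 0)))
  tab <- embed_protein(ring, walk_config(walks_per_node = 3, walk_length = 20,
                                         epochs = 2, seed = 0))
  expect_equal(nrow(tab$vectors), 20)
  expect_true(all(is.finite(tab$vectors)))
})

test_that("embedding tables round-trip through TSV", {
  g <- random_test_graph(6, seed = 9)
  tab <- embed_protein(g, walk_config(walks_per_node = 2, walk_length = 10,
                                      embedding_dim = 5, epochs = 1, seed = 1))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_table(tab, tmp)
  back <- read_embedding_table(tmp)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-6)
})
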