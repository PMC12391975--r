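# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles (plain loops, no shared code with the
# package internals) so they can arbitrate the fast implementations.

# O(N^2) pairwise contact enumeration straight from coordinates.
oracle_contact_edges <- function(coords, threshold) {
  n <- nrow(coords)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < threshold) {
        edges <- rbind(edges, c(i - 1L, j - 1L))
      }
    }
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

# Exact biased-walk transition probabilities via literal evaluation:
# shortest-path distances from t computed with BFS over the whole graph.
oracle_transition <- function(adj, prev, curr, p, q) {
  # adj: 0/1 symmetric matrix WITHOUT self-loops; prev/curr 1-based; NA prev ok
  n <- nrow(adj)
  nbrs <- which(adj[curr, ] > 0)
  stopifnot(length(nbrs) > 0)
  if (is.na(prev)) {
    w <- adj[curr, nbrs]
    pr <- w / sum(w)
  } else {
    dist <- rep(Inf, n)
    dist[prev] <- 0
    frontier <- prev
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] > 0)) {
          if (dist[u] > d) { dist[u] <- d; nxt <- c(nxt, u) }
        }
      }
      frontier <- unique(nxt)
    }
    un <- numeric(length(nbrs))
    for (k in seq_along(nbrs)) {
      x <- nbrs[k]
      a <- if (dist[x] == 0) 1 / p else if (dist[x] == 1) 1 else 1 / q
      un[k] <- a * adj[curr, x]
    }
    pr <- un / sum(un)
  }
  names(pr) <- nbrs - 1L
  pr
}

# Literal threshold-sweep Fmax straight from the metric's definition.
oracle_fmax <- function(L, S, thresholds = seq(0, 1, by = 0.01)) {
  n <- nrow(L)
  best <- 0
  for (tau in thresholds) {
    prs <- c(); rcs <- c()
    for (i in seq_len(n)) {
      pred <- which(S[i, ] >= tau)
      truth <- which(L[i, ] == 1)
      if (length(pred) > 0) prs <- c(prs, length(intersect(pred, truth)) / length(pred))
      if (length(truth) > 0) rcs <- c(rcs, length(intersect(pred, truth)) / length(truth))
    }
    if (length(prs) == 0) next
    pr <- mean(prs)
    rc <- if (length(rcs)) mean(rcs) else 0
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

# Pairwise concordance AUC (ties get half credit).
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Pairwise concordance AUC, vectorized over the full pos x neg grid (same
# brute-force definition as oracle_auc, usable on thousands of cells).
oracle_auc_fast <- function(y, s) {
  sp <- s[y == 1]; sn <- s[y == 0]
  cmp <- outer(sp, sn, `>`) + 0.5 * outer(sp, sn, `==`)
  sum(cmp) / (length(sp) * length(sn))
}

with_seed_test <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(0)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# AUPR by explicit descent through distinct thresholds.
oracle_aupr <- function(y, s) {
  taus <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1)
  prev_rc <- 0
  area <- 0
  for (tau in taus) {
    pred <- s >= tau
    tp <- sum(pred & y == 1)
    pr <- tp / sum(pred)
    rc <- tp / P
    area <- area + (rc - prev_rc) * pr
    prev_rc <- rc
  }
  area
}

# Random undirected graph as a contact_graph (connected enough for walks).
random_test_graph <- function(n, p_edge = 0.4, seed = 1, self_loops = TRUE) {
  set.seed(seed)
  edges <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    if (i < j && runif(1) < p_edge) edges <- rbind(edges, c(i, j))
  }
  # guarantee every node has a neighbor by chaining
  for (i in 0:(n - 2)) edges <- rbind(edges, c(i, i + 1))
  if (self_loops) edges <- rbind(edges, cbind(0:(n - 1), 0:(n - 1)))
  contact_graph(sprintf("rt%d", seed), n, edges, has_self_loops = self_loops)
}

# Dense adjacency without self-loops from a contact_graph.
walk_adjacency <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes)
  e <- g$edges
  for (k in seq_len(nrow(e))) {
    if (e[k, 1] != e[k, 2]) {
      A[e[k, 1] + 1, e[k, 2] + 1] <- 1
      A[e[k, 2] + 1, e[k, 1] + 1] <- 1
    }
  }
  A
}
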