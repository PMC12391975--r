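## Per-residue structural embeddings via biased second-order random walks
## and skip-gram with negative sampling.
##
## The walk bias follows the classic two-parameter scheme: stepping from v
## with predecessor t, a neighbor x of v gets unnormalized weight
## alpha_pq(d_tx) * W_vx, where d_tx is the t->x shortest-path distance
## (necessarily 0, 1 or 2 for x adjacent to v): 1/p for returning to t,
## 1 for a common neighbor of t and v, 1/q for moving outward.  The
## defaults p = 0.8, q = 1.2 give a mildly outward-exploring walk.
## Self-loops are excluded from the walk graph (a self-step carries no
## structural information and makes d_tx ill-posed); they stay in the GNN
## adjacency.

#' Node2Vec walk and training configuration
#'
#' @param p return parameter (> 0), default 0.8.
#' @param q in-out parameter (> 0), default 1.2.
#' @param walks_per_node walks started at each node, default 10.
#' @param walk_length nodes per walk, default 80.
#' @param embedding_dim embedding width, default 30.
#' @param context_window skip-gram window radius, default 10.
#' @param negative_samples negatives per positive pair, default 5.
#' @param epochs skip-gram epochs over the walk corpus, default 5.
#' @param learning_rate initial skip-gram learning rate, default 0.025.
#' @param seed integer seed; all walk and training randomness derives
#'   from it, so results are reproducible.
#' @return A `walk_config`.
#' @export
walk_config <- function(p = 0.8, q = 1.2, walks_per_node = 10L,
                        walk_length = 80L, embedding_dim = 30L,
                        context_window = 10L, negative_samples = 5L,
                        epochs = 5L, learning_rate = 0.025, seed = 0L) {
  stopifnot(p > 0, q > 0, walks_per_node >= 1, walk_length >= 1,
            embedding_dim >= 1, context_window >= 1, negative_samples >= 1,
            epochs >= 1, learning_rate > 0)
  structure(list(p = p, q = q,
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 embedding_dim = as.integer(embedding_dim),
                 context_window = as.integer(context_window),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Second-order walk bias factor
#'
#' @param d_tx shortest-path distance from the previous node t to the
#'   candidate x; must be 0, 1 or 2.
#' @param p return parameter.
#' @param q in-out parameter.
#' @return 1/p if `d_tx == 0`, 1 if `d_tx == 1`, 1/q if `d_tx == 2`.
#' @export
alpha_pq <- function(d_tx, p, q) {
  stopifnot(p > 0, q > 0)
  if (!all(d_tx %in% c(0L, 1L, 2L))) {
    stop_graphgo("alpha_pq: d_tx must be in {0, 1, 2}")
  }
  ifelse(d_tx == 0L, 1 / p, ifelse(d_tx == 1L, 1, 1 / q))
}

#' Exact one-step transition distribution of the biased walk
#'
#' @param graph a [contact_graph()].
#' @param prev 0-based index of the previous node t, or `NA` for the first
#'   step (which uses weight-proportional probabilities).
#' @param curr 0-based index of the current node v.
#' @param config a [walk_config()] (only `p` and `q` are used).
#' @return Named numeric vector: probability over the neighbors of `curr`
#'   (names are 0-based node indices), summing to 1.
#' @export
transition_distribution <- function(graph, prev, curr, config = walk_config()) {
  nl <- neighbor_lists(graph)
  v <- as.integer(curr) + 1L
  if (v < 1L || v > graph$n_nodes) stop_graphgo("curr out of range")
  nbr <- nl$neighbors[[v]]
  w <- nl$weights[[v]]
  if (length(nbr) == 0L) {
    stop_graphgo(sprintf("stranded walker: node %d has no neighbors", curr))
  }
  if (is.na(prev)) {
    pi_vx <- w
  } else {
    t <- as.integer(prev) + 1L
    if (!(t %in% nbr)) stop_graphgo("prev must be adjacent to curr")
    tn <- nl$neighbors[[t]]
    d <- ifelse(nbr == t, 0L, ifelse(nbr %in% tn, 1L, 2L))
    pi_vx <- alpha_pq(d, config$p, config$q) * w
  }
  p <- pi_vx / sum(pi_vx)
  names(p) <- nbr - 1L
  p
}

#' Generate biased random walks over a contact graph
#'
#' Starts `walks_per_node` walks at every node.  A walk from an isolated
#' node (no neighbors once self-loops are dropped) is truncated to its
#' start node rather than raising an error.  Deterministic given
#' `config$seed`.
#'
#' @param graph a [contact_graph()].
#' @param config a [walk_config()].
#' @return List of integer vectors of 0-based node indices, each of length
#'   `walk_length` (or shorter when truncated).
#' @export
generate_walks <- function(graph, config = walk_config()) {
  nl <- neighbor_lists(graph)
  seed <- derive_seed(config$seed, paste0("walks:", graph$protein_id))
  wm <- cpp_generate_walks(nl$neighbors, nl$weights, config$p, config$q,
                           config$walks_per_node, config$walk_length, seed)
  apply(wm, 1, function(r) r[r >= 0L], simplify = FALSE)
}

#' Train skip-gram embeddings over walk corpora
#'
#' Skip-gram with negative sampling (the standard approximation of the
#' walk-neighborhood likelihood), single-threaded and deterministic given
#' the seed.  Nodes absent from every walk receive a zero vector with a
#' warning.
#'
#' @param walks list of integer vectors of 0-based node indices.
#' @param n_nodes total number of nodes in the graph.
#' @param config a [walk_config()].
#' @return An `embedding_table`: list with `vectors` (n_nodes x dim matrix,
#'   row i = node i-1) and `dim`.
#' @export
train_embeddings <- function(walks, n_nodes, config = walk_config()) {
  if (length(walks) == 0L) stop_graphgo("train_embeddings: no walks")
  seed <- derive_seed(config$seed, "sgns")
  wm <- walks_to_matrix(walks)
  emb <- cpp_train_sgns(wm, as.integer(n_nodes), config$embedding_dim,
                        config$context_window, config$negative_samples,
                        config$epochs, config$learning_rate, seed)
  seen <- sort(unique(unlist(walks, use.names = FALSE)))
  missing <- setdiff(0:(n_nodes - 1L), seen)
  if (length(missing)) {
    warning(sprintf("%d node(s) absent from all walks received zero vectors",
                    length(missing)))
    emb[missing + 1L, ] <- 0
  }
  structure(list(vectors = emb, dim = ncol(emb), n_nodes = as.integer(n_nodes)),
            class = "embedding_table")
}

walks_to_matrix <- function(walks) {
  L <- max(lengths(walks))
  m <- matrix(-1L, nrow = length(walks), ncol = L)
  for (i in seq_along(walks)) m[i, seq_along(walks[[i]])] <- walks[[i]]
  m
}

#' Embed one protein graph end to end
#'
#' Walk generation followed by skip-gram training.
#'
#' @inheritParams generate_walks
#' @return An `embedding_table` with a `protein_id` field.
#' @export
embed_protein <- function(graph, config = walk_config()) {
  walks <- generate_walks(graph, config)
  tab <- train_embeddings(walks, graph$n_nodes, config)
  tab$protein_id <- graph$protein_id
  tab
}

#' Write an embedding table as TSV (node index + vector per line)
#' @param table an `embedding_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(table$vectors))) {
    writeLines(paste(c(i - 1L, sprintf("%.8g", table$vectors[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an embedding table written by [write_embedding_table()]
#' @param path TSV path.
#' @return An `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE)
  idx <- as.integer(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- m[order(idx), , drop = FALSE]
  dimnames(m) <- NULL
  structure(list(vectors = m, dim = ncol(m), n_nodes = nrow(m)),
            class = "embedding_table")
}
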