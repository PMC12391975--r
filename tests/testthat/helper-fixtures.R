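# Small in-code fixtures shared across test files.

pdb_line <- function(serial, resname, resno, x, y, z, atom = "CA",
                     altloc = " ", chain = "A") {
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, sprintf(" %-3s", atom), altloc, resname, chain, resno, x, y, z)
}

three_residue_pdb <- function(spacing = c(0, 8, 16)) {
  paste(c(pdb_line(1, "ALA", 1, spacing[1], 0, 0),
          pdb_line(2, "GLY", 2, spacing[2], 0, 0),
          pdb_line(3, "TRP", 3, spacing[3], 0, 0),
          "END"), collapse = "\n")
}

toy_obo <- function() {
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: mid", "namespace: molecular_function",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "namespace: molecular_function",
    "is_a: GO:0000002 ! mid", "",
    sep = "\n")
}

# Diamond: D -> (B, C) -> A
diamond_obo <- function() {
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000010", "name: A", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000011", "name: B", "namespace: molecular_function",
    "is_a: GO:0000010 ! A", "",
    "[Term]", "id: GO:0000012", "name: C", "namespace: molecular_function",
    "is_a: GO:0000010 ! A", "",
    "[Term]", "id: GO:0000013", "name: D", "namespace: molecular_function",
    "is_a: GO:0000011 ! B", "is_a: GO:0000012 ! C", "",
    sep = "\n")
}

# Path graph 0-1-2 without self-loops (the canonical walk-bias example).
path3_graph <- function() {
  contact_graph("path3", 3, rbind(c(0, 1), c(1, 2)), has_self_loops = FALSE)
}

tiny_model_config <- function(n_labels = 3, node_dim = 5, seq_dim = 4,
                              seed = 7, ...) {
  model_config(n_labels = n_labels, node_feature_dim = node_dim,
               seq_embedding_dim = seq_dim, n_blocks = 2L, hidden_dim = 8L,
               transformer_layers = 2L, attention_heads = 2L,
               dropout = 0, seed = seed, ...)
}

random_model_input <- function(n_nodes, node_dim = 5, seq_dim = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n_nodes, n_nodes)
  diag(A) <- 1
  for (k in seq_len(2 * n_nodes)) {
    i <- sample(n_nodes, 1); j <- sample(n_nodes, 1)
    A[i, j] <- 1; A[j, i] <- 1
  }
  list(A = A, X = matrix(rnorm(n_nodes * node_dim), n_nodes, node_dim),
       h = rnorm(seq_dim))
}

# Navigate a nested parameter tree; used by the gradient checker.
param_paths <- function(x, pre = character(0)) {
  out <- list()
  if (is.list(x)) {
    ks <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
    for (k in seq_along(x)) {
      out <- c(out, param_paths(x[[k]], c(pre, ks[k])))
    }
  } else {
    out[[length(out) + 1]] <- list(path = pre, n = length(x))
  }
  out
}

param_get <- function(s, path) {
  for (nm in path) {
    s <- if (grepl("^[0-9]+$", nm)) s[[as.integer(nm)]] else s[[nm]]
  }
  s
}

param_set_elem <- function(s, path, ix, val) {
  idx <- paste0(vapply(path, function(nm) {
    if (grepl("^[0-9]+$", nm)) sprintf("[[%s]]", nm) else sprintf('[["%s"]]', nm)
  }, ""), collapse = "")
  eval(parse(text = paste0("s", idx, "[ix] <- val")))
  s
}
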