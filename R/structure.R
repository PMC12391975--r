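## Contact-graph construction from protein structures.
##
## A protein chain is reduced to its C-alpha trace and turned into an
## undirected residue graph: nodes are residues, and an edge joins residues
## whose C-alpha atoms lie strictly closer than a distance threshold
## (default 10 Angstrom).  Self-loops are added for the GNN adjacency.

#' Residue chain constructor
#'
#' A `residue_chain` holds the C-alpha trace of a single protein chain:
#' one row per residue with its (strictly increasing) residue number, its
#' one-letter amino-acid code and its C-alpha coordinates in Angstrom.
#'
#' @param protein_id character scalar identifier.
#' @param seq_index integer vector of residue numbers, strictly increasing.
#' @param amino_acid character vector of one-letter codes (unknowns as "X").
#' @param coords numeric matrix, one row per residue, 3 columns (x, y, z).
#' @return An object of class `residue_chain`.
#' @export
residue_chain <- function(protein_id, seq_index, amino_acid, coords) {
  coords <- as.matrix(coords)
  n <- length(seq_index)
  if (n < 1L) stop_graphgo("residue_chain: length must be >= 1")
  if (length(amino_acid) != n || nrow(coords) != n || ncol(coords) != 3L) {
    stop_graphgo("residue_chain: field lengths disagree")
  }
  if (n > 1L && any(diff(seq_index) <= 0L)) {
    stop_graphgo("residue_chain: sequence_index must be strictly increasing")
  }
  if (any(!is.finite(coords))) stop_graphgo("residue_chain: non-finite coordinates")
  structure(list(protein_id = as.character(protein_id),
                 seq_index = as.integer(seq_index),
                 amino_acid = as.character(amino_acid),
                 coords = unname(coords)),
            class = "residue_chain")
}

#' @export
length.residue_chain <- function(x) length(x$seq_index)

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("residue_chain '%s': %d residues (%s...)\n", x$protein_id,
              length(x), paste(head(x$amino_acid, 10), collapse = "")))
  invisible(x)
}

#' Extract the sequence of a residue chain as a string
#' @param chain a `residue_chain`.
#' @return character scalar.
#' @export
chain_sequence <- function(chain) paste(chain$amino_acid, collapse = "")

#' Parse a PDB structure into a C-alpha residue chain
#'
#' Reads fixed-column ATOM records and keeps one C-alpha per residue.  Only
#' the first model and the first chain encountered are used, and for
#' alternate-location C-alpha entries the first one seen is kept (altloc
#' "A" precedes "B" in well-formed files).  Residues without a C-alpha atom
#' are dropped; three-letter residue names are mapped to one-letter codes
#' with unknowns becoming "X".
#'
#' @param pdb_text character: either the path of a PDB file or its content
#'   as a single string / character vector of lines.
#' @param protein_id identifier for the chain; defaults to the file name
#'   without extension (or "protein" for literal text).
#' @return A [residue_chain()].
#' @export
parse_structure <- function(pdb_text, protein_id = NULL) {
  src <- "<text>"
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    src <- pdb_text
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(pdb_text))
    }
    lines <- readLines(pdb_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(protein_id)) protein_id <- "protein"
  }

  rec <- substr(lines, 1, 6)
  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)

  atom_idx <- which(rec == "ATOM  ")
  ca_rows <- list()
  first_chain <- NULL
  seen_res <- character(0)
  for (i in atom_idx) {
    ln <- lines[i]
    name <- trimws(substr(ln, 13, 16))
    if (name != "CA") next
    chain_id <- substr(ln, 22, 22)
    if (is.null(first_chain)) first_chain <- chain_id
    if (chain_id != first_chain) next
    resno_txt <- trimws(substr(ln, 23, 26))
    resno <- suppressWarnings(as.integer(resno_txt))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (is.na(resno) || any(is.na(xyz))) {
      stop_graphgo(sprintf("malformed ATOM record at line %d of %s", i, src),
                   class = "graphgo_parse_error")
    }
    ins <- substr(ln, 27, 27)
    key <- paste0(resno_txt, ins)
    if (key %in% seen_res) next  # first altloc / duplicate CA wins
    seen_res <- c(seen_res, key)
    ca_rows[[length(ca_rows) + 1L]] <- list(
      resno = resno, aa = aa_three_to_one(substr(ln, 18, 20)), xyz = xyz)
  }
  if (length(ca_rows) == 0L) {
    stop_graphgo(sprintf("no CA atoms found in %s", src),
                 class = "graphgo_parse_error")
  }
  resno <- vapply(ca_rows, `[[`, integer(1), "resno")
  ord <- order(resno)
  residue_chain(protein_id,
                seq_index = resno[ord],
                amino_acid = vapply(ca_rows, `[[`, character(1), "aa")[ord],
                coords = do.call(rbind, lapply(ca_rows, `[[`, "xyz"))[ord, , drop = FALSE])
}

#' Contact graph constructor
#'
#' An undirected residue graph stored as a canonical edge matrix with
#' 0-based node indices `i <= j`; self-loops, when present, appear as
#' `(i, i)` rows for every node.  Edge weights default to 1.
#'
#' @param protein_id identifier.
#' @param n_nodes number of residues / nodes.
#' @param edges integer matrix with two columns of 0-based node indices.
#' @param has_self_loops logical.
#' @param weights numeric vector, one weight per edge row (default 1).
#' @return An object of class `contact_graph`.
#' @export
contact_graph <- function(protein_id, n_nodes, edges,
                          has_self_loops = FALSE, weights = NULL) {
  n_nodes <- as.integer(n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 0L) || any(edges >= n_nodes)) {
      stop_graphgo("contact_graph: node index out of range")
    }
    # canonicalize: i <= j, unique, sorted
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    key <- edges[, 1] * n_nodes + edges[, 2]
    if (is.null(weights)) weights <- rep(1, nrow(edges))
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    weights <- weights[keep]
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
    weights <- weights[ord]
  } else {
    weights <- numeric(0)
  }
  if (any(weights <= 0)) stop_graphgo("contact_graph: weights must be positive")
  structure(list(protein_id = as.character(protein_id),
                 n_nodes = n_nodes,
                 edges = unname(edges),
                 has_self_loops = isTRUE(has_self_loops),
                 weights = as.numeric(weights)),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("contact_graph '%s': %d nodes, %d undirected edges%s\n",
              x$protein_id, x$n_nodes, nrow(x$edges),
              if (x$has_self_loops) " (self-loops)" else ""))
  invisible(x)
}

#' Build the residue contact graph of a chain
#'
#' Residues i and j (i != j) are joined iff the Euclidean distance between
#' their C-alpha atoms is strictly less than `threshold_angstrom`.  The
#' strict inequality matters: a pair at exactly the threshold is not in
#' contact.  Self-loops `(i, i)` are appended for every node when
#' `add_self_loops` is `TRUE` (they are required by the normalized graph
#' convolution but excluded from random walks).
#'
#' @param chain a [residue_chain()].
#' @param threshold_angstrom positive contact cutoff, default 10.
#' @param add_self_loops add `(i, i)` edges for every node (default `TRUE`).
#' @return A [contact_graph()].
#' @export
build_contact_graph <- function(chain, threshold_angstrom = 10.0,
                                add_self_loops = TRUE) {
  stopifnot(inherits(chain, "residue_chain"))
  if (!is.numeric(threshold_angstrom) || threshold_angstrom <= 0) {
    stop_graphgo("threshold_angstrom must be positive")
  }
  n <- length(chain)
  d <- as.matrix(stats::dist(chain$coords))
  pairs <- which(upper.tri(d) & d < threshold_angstrom, arr.ind = TRUE)
  edges <- cbind(pairs[, 1] - 1L, pairs[, 2] - 1L)
  if (add_self_loops) edges <- rbind(edges, cbind(0:(n - 1L), 0:(n - 1L)))
  contact_graph(chain$protein_id, n, edges, has_self_loops = add_self_loops)
}

# Symmetric 0/1 (weighted) dense adjacency of a contact graph.
# include_self_loops = NA keeps the graph as stored; TRUE/FALSE force.
adjacency_matrix <- function(graph, include_self_loops = NA) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  e <- graph$edges
  if (nrow(e) > 0) {
    A[cbind(e[, 1] + 1L, e[, 2] + 1L)] <- graph$weights
    A[cbind(e[, 2] + 1L, e[, 1] + 1L)] <- graph$weights
  }
  if (isTRUE(include_self_loops)) diag(A) <- pmax(diag(A), 1)
  if (identical(include_self_loops, FALSE)) diag(A) <- 0
  A
}

# Neighbor lists (1-based, self-loops excluded) with parallel edge weights.
neighbor_lists <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  keep <- e[, 1] != e[, 2]
  e <- e[keep, , drop = FALSE]
  w <- graph$weights[keep]
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1] + 1L; b <- e[k, 2] + 1L
    nbr[[a]] <- c(nbr[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
    nbr[[b]] <- c(nbr[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
  }
  for (i in seq_len(n)) {
    ord <- order(nbr[[i]])
    nbr[[i]] <- nbr[[i]][ord]; wts[[i]] <- wts[[i]][ord]
  }
  list(neighbors = nbr, weights = wts)
}

#' Write a contact graph as an edge-list text file
#'
#' Two tab-separated columns of 0-based node indices, one undirected edge
#' per line (canonical `i <= j` orientation); a `# nodes: N` header records
#' the node count so isolated nodes survive the round trip.
#'
#' @param graph a [contact_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protein: %s", graph$protein_id), con)
  writeLines(sprintf("# nodes: %d", graph$n_nodes), con)
  writeLines(sprintf("# self_loops: %d", as.integer(graph$has_self_loops)), con)
  if (nrow(graph$edges) > 0) {
    writeLines(sprintf("%d\t%d", graph$edges[, 1], graph$edges[, 2]), con)
  }
  invisible(path)
}

#' Read a contact graph from an edge-list text file
#'
#' @param path file of whitespace-separated integer pairs, one edge per
#'   line; `#` lines are treated as header/comment.
#' @param protein_id override the identifier recorded in the header.
#' @return A [contact_graph()].
#' @export
read_edge_list <- function(path, protein_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L && length(hdr) == 0L) {
    stop_graphgo(sprintf("empty edge list: %s", path),
                 class = "graphgo_parse_error")
  }
  pid <- protein_id
  if (is.null(pid)) {
    m <- grep("^# protein:", hdr, value = TRUE)
    pid <- if (length(m)) trimws(sub("^# protein:", "", m[1])) else
      sub("\\.[^.]*$", "", basename(path))
  }
  nn <- NA_integer_
  m <- grep("^# nodes:", hdr, value = TRUE)
  if (length(m)) nn <- as.integer(trimws(sub("^# nodes:", "", m[1])))
  sl <- FALSE
  m <- grep("^# self_loops:", hdr, value = TRUE)
  if (length(m)) sl <- trimws(sub("^# self_loops:", "", m[1])) == "1"

  if (length(body) == 0L) stop_graphgo(sprintf("empty edge list: %s", path),
                                       class = "graphgo_parse_error")
  toks <- strsplit(trimws(body), "[[:space:]]+")
  for (k in seq_along(toks)) {
    if (length(toks[[k]]) != 2L ||
        any(!grepl("^[0-9]+$", toks[[k]]))) {
      ln <- which(lines == body[k])[1]
      stop_graphgo(sprintf("non-integer edge token at line %d of %s", ln, path),
                   class = "graphgo_parse_error")
    }
  }
  e <- do.call(rbind, lapply(toks, as.integer))
  if (is.na(nn)) nn <- max(e) + 1L
  contact_graph(pid, nn, e, has_self_loops = sl)
}

#' @exportS3Method base::all.equal
all.equal.contact_graph <- function(target, current, ...) {
  msg <- character(0)
  if (target$n_nodes != current$n_nodes) msg <- c(msg, "n_nodes differ")
  if (!identical(target$edges, current$edges)) msg <- c(msg, "edge sets differ")
  if (target$has_self_loops != current$has_self_loops) msg <- c(msg, "self-loop flag differs")
  if (length(msg)) msg else TRUE
}
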