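## Gene Ontology handling: OBO parsing, true-path propagation of
## annotations, rare-term filtering and binary label matrices.
##
## Only is_a edges are used for propagation (the conservative CAFA-style
## default); part_of and regulates relationships are ignored.  Namespace
## roots are excluded from vocabularies because after propagation they are
## annotated to every protein and carry no signal.

GO_NAMESPACES <- c(molecular_function = "MFO",
                   biological_process = "BPO",
                   cellular_component = "CCO")

#' Parse an OBO 1.2 ontology file
#'
#' Keeps non-obsolete `[Term]` stanzas with their `id`, `name`, `namespace`
#' and `is_a` parents; all other relationship types are ignored.  Errors
#' on is_a references to undefined terms, on namespace-inconsistent is_a
#' edges and on cyclic is_a graphs.
#'
#' @param obo_text path to an OBO file, or its content as a string.
#' @return A `go_dag`: list with `terms` (named list of
#'   `(name, namespace, parents)`), `roots` and `n_terms`.
#' @export
parse_obo <- function(obo_text) {
  if (length(obo_text) == 1L && !grepl("\n", obo_text) && file.exists(obo_text)) {
    lines <- readLines(obo_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(obo_text, collapse = "\n"), "\n", fixed = TRUE))
  }
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0L) stop_graphgo("no [Term] stanzas found")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    getv <- function(key) {
      m <- grep(sprintf("^%s:", key), block, value = TRUE)
      trimws(sub(sprintf("^%s:", key), "", m))
    }
    id <- getv("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("true", getv("is_obsolete")))) next
    parents <- getv("is_a")
    parents <- vapply(strsplit(parents, "!", fixed = TRUE),
                      function(x) trimws(x[1]), character(1))
    ns <- getv("namespace")[1]
    terms[[id]] <- list(name = getv("name")[1] %||% id,
                        namespace = unname(GO_NAMESPACES[ns] %||% NA_character_),
                        parents = unique(parents[nzchar(parents)]))
  }
  if (length(terms) == 0L) stop_graphgo("no usable terms found")
  ids <- names(terms)
  for (id in ids) {
    for (p in terms[[id]]$parents) {
      if (!(p %in% ids)) {
        stop_graphgo(sprintf("term %s has is_a parent %s not defined in the ontology",
                             id, p))
      }
      if (!identical(terms[[id]]$namespace, terms[[p]]$namespace)) {
        stop_graphgo(sprintf("namespace mismatch along is_a edge %s -> %s", id, p))
      }
    }
  }
  # cycle check by Kahn's algorithm on child -> parent edges
  indeg <- setNames(integer(length(ids)), ids)
  for (id in ids) for (p in terms[[id]]$parents) indeg[p] <- indeg[p] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in terms[[v]]$parents) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(ids)) {
    stop_graphgo(sprintf("cyclic is_a relationships involving: %s",
                         paste(ids[indeg > 0L], collapse = ", ")))
  }
  roots <- ids[vapply(terms, function(t) length(t$parents) == 0L, logical(1))]
  structure(list(terms = terms, roots = roots, n_terms = length(terms)),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d root(s)\n", x$n_terms, length(x$roots)))
  invisible(x)
}

# All is_a ancestors of a term (excluding itself), memoized per call.
dag_ancestors <- function(dag, term_ids = names(dag$terms)) {
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- dag$terms[[id]]$parents
    out <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- out
    out
  }
  setNames(lapply(term_ids, anc), term_ids)
}

#' Annotation set constructor
#'
#' @param records named list: protein_id -> character vector of term ids.
#' @param dag a `go_dag`; all terms must exist in it.
#' @param namespace "MFO", "BPO" or "CCO"; annotations outside it error.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(records, dag, namespace = c("MFO", "BPO", "CCO")) {
  namespace <- match.arg(namespace)
  for (pid in names(records)) {
    terms <- unique(as.character(records[[pid]]))
    unknown <- setdiff(terms, names(dag$terms))
    if (length(unknown)) {
      stop_graphgo(sprintf("protein %s annotated with unknown term(s): %s",
                           pid, paste(unknown, collapse = ", ")))
    }
    ns <- vapply(dag$terms[terms], `[[`, character(1), "namespace")
    if (any(ns != namespace)) {
      stop_graphgo(sprintf("protein %s has annotation(s) outside namespace %s",
                           pid, namespace))
    }
    records[[pid]] <- sort(terms)
  }
  structure(list(records = records, namespace = namespace, propagated = FALSE),
            class = "annotation_set")
}

#' Read a two-column annotation TSV (protein_id, term_id)
#'
#' @param path TSV path; lines starting with `#` are skipped.
#' @inheritParams annotation_set
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path, dag, namespace = c("MFO", "BPO", "CCO")) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("protein_id", "term_id"),
                   colClasses = "character")
  if (nrow(df) == 0L) stop_graphgo(sprintf("no annotations in %s", path))
  annotation_set(split(df$term_id, df$protein_id), dag, namespace)
}

#' Write an annotation set as a two-column TSV
#' @param ann an `annotation_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pid in names(ann$records)) {
    for (t in ann$records[[pid]]) writeLines(paste(pid, t, sep = "\t"), con)
  }
  invisible(path)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Each protein's term set is closed under is_a ancestry: a protein
#' annotated with a term is implicitly annotated with every ancestor.
#' Idempotent and monotone.
#'
#' @param ann an `annotation_set`.
#' @param dag the `go_dag` the annotations refer to.
#' @return The propagated `annotation_set`.
#' @export
propagate <- function(ann, dag) {
  anc <- dag_ancestors(dag)
  ann$records <- lapply(ann$records, function(terms) {
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
  ann$propagated <- TRUE
  ann
}

#' Select the vocabulary of sufficiently frequent terms
#'
#' Terms annotated (after propagation) to at least `min_proteins` proteins
#' survive; namespace roots are always excluded as uninformative.
#'
#' @param ann a propagated `annotation_set`.
#' @param dag the `go_dag`.
#' @param min_proteins minimum protein count per term (default 25).
#' @return Character vector of term ids, sorted.
#' @export
filter_rare_terms <- function(ann, dag, min_proteins = 25L) {
  stopifnot(min_proteins >= 1L)
  counts <- table(unlist(ann$records, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_proteins])
  vocab <- setdiff(vocab, dag$roots)
  if (length(vocab) == 0L) {
    stop_graphgo(sprintf(
      "no terms annotated to >= %d proteins; lower min_proteins", min_proteins))
  }
  vocab
}

#' Build the binary protein x term label matrix
#'
#' Proteins with no surviving in-vocabulary term are dropped (their count
#' is reported via a message).
#'
#' @param ann a propagated `annotation_set`.
#' @param vocab term vocabulary (character vector).
#' @return A `label_matrix`: list with `protein_ids`, `term_vocab` and the
#'   binary `matrix` (proteins x terms, dimnames set).
#' @export
build_label_matrix <- function(ann, vocab) {
  vocab <- sort(unique(vocab))
  pids <- names(ann$records)
  m <- matrix(0L, nrow = length(pids), ncol = length(vocab),
              dimnames = list(pids, vocab))
  for (i in seq_along(pids)) {
    hits <- intersect(ann$records[[pids[i]]], vocab)
    m[i, hits] <- 1L
  }
  keep <- rowSums(m) > 0L
  if (any(!keep)) {
    message(sprintf("build_label_matrix: dropped %d protein(s) with no in-vocabulary terms",
                    sum(!keep)))
  }
  m <- m[keep, , drop = FALSE]
  structure(list(protein_ids = rownames(m), term_vocab = vocab, matrix = m),
            class = "label_matrix")
}

#' Write a label matrix as TSV (header row of term ids)
#' @param labels a `label_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_matrix <- function(labels, path) {
  df <- as.data.frame(labels$matrix)
  write.table(cbind(protein_id = labels$protein_ids, df), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a label matrix written by [write_label_matrix()]
#' @param path TSV path.
#' @return A `label_matrix`.
#' @export
read_label_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  structure(list(protein_ids = df[[1]], term_vocab = colnames(m), matrix = m),
            class = "label_matrix")
}
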