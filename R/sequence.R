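## Sequence features: per-residue one-hot encodings and a global
## per-protein embedding.  Real language-model embeddings are precomputed
## offline and loaded through an adapter; a deterministic k-mer-hash mock
## stands in for them in tests and synthetic runs.

#' Sequence record constructor
#'
#' @param protein_id identifier.
#' @param sequence uppercase string over the 20 amino-acid letters plus "X".
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(protein_id, sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || nchar(sequence) < 1L) {
    stop_graphgo("sequence_record: sequence must be a non-empty string")
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop_graphgo(sprintf("invalid residue '%s' at position %d of %s",
                         chars[bad[1]], bad[1], protein_id))
  }
  structure(list(protein_id = as.character(protein_id), sequence = sequence),
            class = "sequence_record")
}

#' Read a FASTA file into sequence records
#'
#' Nonstandard residues (B, J, O, U, Z, *) are mapped to "X".
#'
#' @param path FASTA file path.
#' @return Named list of [sequence_record()]s.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop_graphgo(sprintf("no sequences in %s", path))
  out <- lapply(seq_along(aa), function(i) {
    s <- toupper(as.character(aa[[i]]))
    s <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), "X", s)
    id <- strsplit(names(aa)[i], "[[:space:]]+")[[1]][1]
    sequence_record(id, s)
  })
  names(out) <- vapply(out, `[[`, character(1), "protein_id")
  out
}

#' Write sequence records to a FASTA file
#' @param records list of [sequence_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "protein_id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' One-hot encode a protein sequence
#'
#' @param record a [sequence_record()] (or plain string).
#' @return L x 21 binary matrix; columns follow the canonical alphabet
#'   (the 20 standard residues alphabetically, then "X"), row i carrying a
#'   single 1 at the column of residue i.
#' @export
one_hot_encode <- function(record) {
  if (is.character(record)) record <- sequence_record("seq", record)
  chars <- strsplit(record$sequence, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  m <- matrix(0, nrow = length(chars), ncol = length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Mean-pool a per-position embedding matrix into a global vector
#'
#' @param per_position L x d numeric matrix (rows = positions).
#' @return Length-d vector of column means.
#' @export
mean_pool <- function(per_position) {
  per_position <- as.matrix(per_position)
  if (nrow(per_position) < 1L) stop_graphgo("mean_pool: empty matrix")
  colMeans(per_position)
}

#' Global sequence embedding constructor
#' @param protein_id identifier.
#' @param vector finite numeric vector.
#' @param source one of "plm", "mock", "onehot-mean".
#' @return An object of class `global_embedding`.
#' @export
global_embedding <- function(protein_id, vector,
                             source = c("plm", "mock", "onehot-mean")) {
  source <- match.arg(source)
  vector <- as.numeric(vector)
  if (any(!is.finite(vector))) stop_graphgo("global_embedding: non-finite entries")
  structure(list(protein_id = as.character(protein_id), vector = vector,
                 dim = length(vector), source = source),
            class = "global_embedding")
}

#' Load precomputed protein-language-model embeddings
#'
#' Adapter for embeddings produced offline by any external embedder.  The
#' file is tab-separated: protein_id then the embedding values, one protein
#' per line.  The dimensionality is inferred from the data and must be
#' consistent across proteins; it is data, not a constant of the package.
#'
#' @param path TSV file path.
#' @return Named list of [global_embedding()]s (source "plm").
#' @export
load_plm_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop_graphgo(sprintf("no embeddings in %s", path))
  out <- list()
  dim0 <- NULL
  for (k in seq_along(lines)) {
    toks <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    id <- toks[1]
    v <- suppressWarnings(as.numeric(toks[-1]))
    if (length(v) == 0L || any(is.na(v))) {
      stop_graphgo(sprintf("malformed embedding line %d of %s", k, path))
    }
    if (is.null(dim0)) dim0 <- length(v)
    if (length(v) != dim0) {
      stop_graphgo(sprintf(
        "inconsistent embedding dims in %s: protein %s has %d, expected %d",
        path, id, length(v), dim0))
    }
    out[[id]] <- global_embedding(id, v, source = "plm")
  }
  out
}

#' Write global embeddings as a TSV adapter file
#' @param embeddings named list of [global_embedding()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in embeddings) {
    writeLines(paste(c(e$protein_id, sprintf("%.8g", e$vector)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Deterministic mock sequence embedding
#'
#' Test stand-in for an external language model: the embedding is a seeded
#' random projection of the sequence's 3-mer count profile, L2-normalized.
#' Identical sequences map to identical vectors and near-identical
#' sequences to nearby vectors, which is all the downstream model needs
#' from a global sequence feature.
#'
#' @param record a [sequence_record()] (or plain string).
#' @param dim embedding dimensionality (default 64).
#' @param seed integer seed for the projection.
#' @return A [global_embedding()] with source "mock".
#' @export
mock_embed <- function(record, dim = 64L, seed = 0L) {
  if (is.character(record)) record <- sequence_record("seq", record)
  stopifnot(dim >= 1L)
  chars <- strsplit(record$sequence, "")[[1]]
  L <- length(chars)
  k <- 3L
  na <- length(AA_ALPHABET)
  idx <- match(chars, AA_ALPHABET) - 1L
  counts <- numeric(na^k)
  if (L >= k) {
    for (i in seq_len(L - k + 1L)) {
      key <- idx[i] * na^2 + idx[i + 1L] * na + idx[i + 2L] + 1L
      counts[key] <- counts[key] + 1
    }
  } else {
    counts[idx[1] + 1L] <- 1
  }
  nz <- which(counts > 0)
  # per-kmer deterministic pseudo-random projection row, independent of
  # which other kmers occur: hash(seed, kmer) seeds a tiny LCG stream
  v <- numeric(dim)
  for (key in nz) {
    h <- derive_seed(seed, paste0("kmer", key))
    s <- as.double(h)
    row <- numeric(dim)
    for (j in seq_len(dim)) {
      s <- (s * 48271) %% 2147483647
      row[j] <- s / 2147483647 - 0.5
    }
    v <- v + counts[key] * row
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  global_embedding(record$protein_id, v, source = "mock")
}

#' Mock-embed a set of records
#' @param records named list of [sequence_record()]s.
#' @inheritParams mock_embed
#' @return Named list of [global_embedding()]s.
#' @export
mock_embed_all <- function(records, dim = 64L, seed = 0L) {
  out <- lapply(records, mock_embed, dim = dim, seed = seed)
  names(out) <- vapply(records, `[[`, character(1), "protein_id")
  out
}
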