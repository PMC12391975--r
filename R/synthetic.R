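## Self-contained toy datasets with planted sequence and structure signal.
##
## Chains are ideal-geometry C-alpha traces (alpha-helix, extended strand,
## or a self-avoiding random coil), so contact density separates fold
## modes cleanly: an extended chain only contacts |i-j| <= 2 neighbours
## (3.8 / 7.6 Angstrom under a 10 Angstrom cutoff) while a helix contacts
## out to |i-j| ~ 7.  Labels are planted as functions of sequence motifs
## and of measured contact density, so sequence-only, structure-only and
## fused models are all meaningfully testable.

FOLD_MODES <- c("helix", "extended", "random-coil")

#' Generate an ideal-geometry C-alpha chain
#'
#' Geometry per mode: `helix` uses the standard alpha-helix C-alpha
#' parameters (2.3 Angstrom radius, 100 degree turn, 1.5 Angstrom rise per
#' residue); `extended` places residues collinearly at 3.8 Angstrom
#' spacing; `random-coil` is a self-avoiding walk with 3.8 Angstrom steps.
#'
#' @param length number of residues (>= 2).
#' @param fold_mode one of `"helix"`, `"extended"`, `"random-coil"`.
#' @param seed integer seed (used by the coil walk and by sequence
#'   generation when `sequence` is `NULL`).
#' @param sequence optional amino-acid string of matching length; random
#'   uniform over the 20 standard residues when omitted.
#' @param protein_id identifier, default `"synth"`.
#' @return List with the [residue_chain()] (`chain`) and the serialized
#'   PDB text (`pdb`).
#' @export
generate_chain <- function(length, fold_mode = c("helix", "extended", "random-coil"),
                           seed = 0L, sequence = NULL, protein_id = "synth") {
  fold_mode <- match.arg(fold_mode)
  stopifnot(length >= 2L)
  if (is.null(sequence)) {
    sequence <- with_seed(derive_seed(seed, paste0("seq:", protein_id)), {
      paste(sample(AA_ALPHABET[1:20], length, replace = TRUE), collapse = "")
    })
  }
  stopifnot(nchar(sequence) == length)

  coords <- switch(fold_mode,
    helix = {
      i <- 0:(length - 1L)
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    extended = cbind(3.8 * (0:(length - 1L)), 0, 0),
    `random-coil` = with_seed(derive_seed(seed, paste0("coil:", protein_id)), {
      xyz <- matrix(0, length, 3)
      dir <- c(1, 0, 0)
      for (i in 2:length) {
        ok <- FALSE
        for (try in 1:200) {
          cand_dir <- dir + rnorm(3, sd = 0.9)
          cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
          cand <- xyz[i - 1L, ] + 3.8 * cand_dir
          prior <- xyz[seq_len(max(0, i - 2L)), , drop = FALSE]
          if (nrow(prior) == 0 ||
              min(sqrt(rowSums(sweep(prior, 2, cand)^2))) > 3.6) {
            ok <- TRUE; break
          }
        }
        # after exhausting retries keep the last candidate: a rare slight
        # clash is harmless in a toy trace
        xyz[i, ] <- cand
        if (ok) dir <- cand_dir
      }
      xyz
    })
  )
  chain <- residue_chain(protein_id, seq_index = seq_len(length),
                         amino_acid = strsplit(sequence, "")[[1]],
                         coords = coords)
  list(chain = chain, pdb = write_pdb_text(chain))
}

#' Serialize a residue chain as PDB ATOM records
#' @param chain a [residue_chain()].
#' @return Character scalar of fixed-column PDB text.
#' @export
write_pdb_text <- function(chain) {
  res3 <- unname(AA_ONE_TO_THREE[chain$amino_acid])
  res3[is.na(res3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(res3), res3, chain$seq_index,
    chain$coords[, 1], chain$coords[, 2], chain$coords[, 3])
  paste(c(lines, "TER", "END", ""), collapse = "\n")
}

#' Synthetic dataset specification
#'
#' Defaults describe the package's reference toy world: 200 proteins of
#' 30-80 residues, a 12-term three-level ontology, four sequence-motif
#' terms, two contact-density terms, one coil-fold term and one
#' hydrophobicity term, with 5% independent label noise.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer pair (min, max) residues.
#' @param n_terms total ontology terms including the root.
#' @param dag_depth levels in the ontology (root = level 1), default 3.
#' @param motifs named character vector: motif string -> planted
#'   prevalence is fixed at `motif_prob`; names are informative only.
#' @param motif_prob probability a motif is planted in a protein.
#' @param contact_bands list of numeric pairs (lo, hi) of mean contact
#'   degree (self-loops excluded); non-overlapping.
#' @param label_noise independent flip probability in [0, 0.5).
#' @param seed master seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200L, length_range = c(30L, 80L),
                           n_terms = 12L, dag_depth = 3L,
                           motifs = c("HKWWH", "CYCYC", "DEDED", "PGPGP"),
                           motif_prob = 0.35,
                           contact_bands = list(c(0, 4.5), c(8.5, Inf)),
                           label_noise = 0.05, seed = 0L) {
  stopifnot(n_proteins >= 1, length_range[1] >= 10, length_range[2] >= length_range[1],
            n_terms >= 4, dag_depth >= 2, label_noise >= 0, label_noise < 0.5)
  n_special <- length(motifs) + length(contact_bands) + 2L  # + coil + hydrophobic
  if (n_terms - 1L - ceiling((n_terms - 1L) / 4) < n_special) {
    stop_graphgo("n_terms too small for the requested motif/contact terms")
  }
  for (i in seq_along(contact_bands)) {
    for (j in seq_along(contact_bands)) {
      if (i < j && contact_bands[[i]][2] > contact_bands[[j]][1] &&
          contact_bands[[j]][2] > contact_bands[[i]][1]) {
        stop_graphgo("contact bands must be non-overlapping")
      }
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_terms = as.integer(n_terms), dag_depth = as.integer(dag_depth),
                 motifs = motifs, motif_prob = motif_prob,
                 contact_bands = contact_bands,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Miniature is_a tree: 1 root, ceiling((n-1)/4) internal terms (split
# across dag_depth - 2 levels when deeper than 3), the rest leaves.
synthetic_dag_layout <- function(n_terms, dag_depth) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  root <- ids[1]
  n_internal <- if (dag_depth == 2L) 0L else ceiling((n_terms - 1L) / 4)
  internal <- if (n_internal > 0) ids[2:(1 + n_internal)] else character(0)
  leaves <- ids[(2 + n_internal):n_terms]
  parents <- setNames(vector("list", n_terms), ids)
  parents[[root]] <- character(0)
  if (n_internal > 0) {
    levels <- max(1L, dag_depth - 2L)
    lev <- rep(seq_len(levels), length.out = n_internal)
    prev_level <- root
    for (l in seq_len(levels)) {
      this_level <- internal[lev == l]
      for (k in seq_along(this_level)) {
        parents[[this_level[k]]] <- prev_level[1 + (k - 1) %% length(prev_level)]
      }
      prev_level <- this_level
    }
    for (k in seq_along(leaves)) {
      parents[[leaves[k]]] <- prev_level[1 + (k - 1) %% length(prev_level)]
    }
  } else {
    for (k in seq_along(leaves)) parents[[leaves[k]]] <- root
  }
  list(ids = ids, root = root, internal = internal, leaves = leaves,
       parents = parents)
}

synthetic_obo_text <- function(layout, term_names) {
  out <- c("format-version: 1.2", "ontology: synthetic-go", "")
  for (id in layout$ids) {
    stanza <- c("[Term]",
                sprintf("id: %s", id),
                sprintf("name: %s", term_names[[id]]),
                "namespace: molecular_function")
    for (p in layout$parents[[id]]) {
      stanza <- c(stanza, sprintf("is_a: %s ! %s", p, term_names[[p]]))
    }
    out <- c(out, stanza, "")
  }
  paste(out, collapse = "\n")
}

HYDROPHOBIC_AA <- c("A", "V", "I", "L", "M", "F", "W", "Y")

#' Generate a complete synthetic dataset on disk
#'
#' Writes `pdb/<id>.pdb` structures, `sequences.fasta`, `ontology.obo`,
#' `annotations.tsv` (leaf-level, pre-propagation) and `truth.tsv`
#' (per-protein fold mode, contact density and planted term assignments).
#' Leaf terms are assigned from planted motifs, contact-density bands,
#' coil fold and hydrophobic composition; each leaf label is then flipped
#' independently with probability `label_noise`.  Fully reproducible from
#' `spec$seed`: the same spec yields byte-identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return List describing the dataset: file paths, the term layout and
#'   the roles of each planted term (`motif_terms`, `contact_terms`,
#'   `fold_term`, `composition_term`).
#' @export
generate_dataset <- function(spec = synthetic_spec(), out_dir) {
  dir.create(file.path(out_dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  layout <- synthetic_dag_layout(spec$n_terms, spec$dag_depth)

  motif_terms <- layout$leaves[seq_along(spec$motifs)]
  k <- length(spec$motifs)
  contact_terms <- layout$leaves[k + seq_along(spec$contact_bands)]
  k <- k + length(spec$contact_bands)
  fold_term <- layout$leaves[k + 1L]
  composition_term <- layout$leaves[k + 2L]

  term_names <- setNames(as.list(sprintf("synthetic term %d", seq_along(layout$ids))),
                         layout$ids)
  term_names[[layout$root]] <- "synthetic root"
  for (i in seq_along(motif_terms)) {
    term_names[[motif_terms[i]]] <- sprintf("motif %s binding", spec$motifs[i])
  }
  for (i in seq_along(contact_terms)) {
    term_names[[contact_terms[i]]] <- sprintf("contact density band %d", i)
  }
  term_names[[fold_term]] <- "random coil fold"
  term_names[[composition_term]] <- "hydrophobic rich"

  writeLines(synthetic_obo_text(layout, term_names),
             file.path(out_dir, "ontology.obo"))

  ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  lengths_ <- with_seed(derive_seed(spec$seed, "lengths"),
                        sample(spec$length_range[1]:spec$length_range[2],
                               spec$n_proteins, replace = TRUE))
  folds <- with_seed(derive_seed(spec$seed, "folds"),
                     sample(FOLD_MODES, spec$n_proteins, replace = TRUE))

  records <- vector("list", spec$n_proteins)
  truth <- vector("list", spec$n_proteins)
  ann_lines <- character(0)
  for (i in seq_len(spec$n_proteins)) {
    L <- lengths_[i]
    sq <- with_seed(derive_seed(spec$seed, paste0("protein-seq:", ids[i])), {
      s <- sample(AA_ALPHABET[1:20], L, replace = TRUE)
      planted <- logical(length(spec$motifs))
      for (m in seq_along(spec$motifs)) {
        if (runif(1) < spec$motif_prob) {
          planted[m] <- TRUE
          mot <- strsplit(spec$motifs[m], "")[[1]]
          pos <- sample.int(L - length(mot) + 1L, 1L)
          s[pos:(pos + length(mot) - 1L)] <- mot
        }
      }
      list(seq = s, planted = planted)
    })
    seq_str <- paste(sq$seq, collapse = "")
    gc_ <- generate_chain(L, folds[i], seed = derive_seed(spec$seed, ids[i]),
                          sequence = seq_str, protein_id = ids[i])
    writeLines(gc_$pdb, file.path(out_dir, "pdb", paste0(ids[i], ".pdb")),
               sep = "")
    graph <- build_contact_graph(gc_$chain)
    density <- 2 * sum(graph$edges[, 1] != graph$edges[, 2]) / graph$n_nodes

    # motif terms follow actual motif presence (planting + chance)
    has_motif <- vapply(spec$motifs, function(m) grepl(m, seq_str, fixed = TRUE),
                        logical(1))
    in_band <- vapply(spec$contact_bands, function(b)
      density >= b[1] && density < b[2], logical(1))
    hyd_frac <- mean(sq$seq %in% HYDROPHOBIC_AA)
    leaf_on <- setNames(logical(length(layout$leaves)), layout$leaves)
    leaf_on[motif_terms] <- has_motif
    leaf_on[contact_terms] <- in_band
    leaf_on[fold_term] <- folds[i] == "random-coil"
    leaf_on[composition_term] <- hyd_frac > 0.45

    if (spec$label_noise > 0) {
      flips <- with_seed(derive_seed(spec$seed, paste0("noise:", ids[i])),
                         runif(length(leaf_on)) < spec$label_noise)
      leaf_on <- xor(leaf_on, flips)
    }
    on_terms <- names(leaf_on)[leaf_on]
    ann_lines <- c(ann_lines, paste(ids[i], on_terms, sep = "\t"))
    records[[i]] <- sequence_record(ids[i], seq_str)
    truth[[i]] <- data.frame(protein_id = ids[i], length = L,
                             fold_mode = folds[i],
                             contact_density = round(density, 4),
                             hydrophobic_frac = round(hyd_frac, 4),
                             motifs_present = paste(spec$motifs[has_motif],
                                                    collapse = ","),
                             stringsAsFactors = FALSE)
  }
  names(records) <- ids
  write_fasta(records, file.path(out_dir, "sequences.fasta"))
  writeLines(ann_lines, file.path(out_dir, "annotations.tsv"))
  write.table(do.call(rbind, truth), file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  list(out_dir = out_dir,
       files = list(pdb_dir = file.path(out_dir, "pdb"),
                    fasta = file.path(out_dir, "sequences.fasta"),
                    obo = file.path(out_dir, "ontology.obo"),
                    annotations = file.path(out_dir, "annotations.tsv"),
                    truth = file.path(out_dir, "truth.tsv")),
       layout = layout,
       motif_terms = setNames(motif_terms, spec$motifs),
       contact_terms = contact_terms,
       fold_term = fold_term, composition_term = composition_term,
       spec = spec)
}
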