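test_that("extended chains contact only |i-j| <= 2 neighbors", {
  gc_ <- generate_chain(12, "extended", seed = 1)
  g <- build_contact_graph(gc_$chain, 10, add_self_loops = FALSE)
  offs <- abs(g$edges[, 1] - g$edges[, 2])
  expect_true(all(offs %in% c(1, 2)))
  # every |i-j| in {1,2} pair present: 3.8 and 7.6 < 10, 11.4 >= 10
  expect_equal(nrow(g$edges), 11 + 10)
})

test_that("helix chains contact (i, i+3) and (i, i+4) pairs", {
  gh <- generate_chain(20, "helix", seed = 1)
  g <- build_contact_graph(gh$chain, 10, add_self_loops = FALSE)
  offs <- abs(g$edges[, 1] - g$edges[, 2])
  expect_true(3 %in% offs)
  expect_true(4 %in% offs)
  # denser than the extended trace of the same length
  ge <- build_contact_graph(generate_chain(20, "extended")$chain, 10, FALSE)
  expect_gt(nrow(g$edges), nrow(ge$edges))
})

test_that("generated PDB text round-trips through parse_structure", {
  for (mode in c("helix", "extended", "random-coil")) {
    gc_ <- generate_chain(15, mode, seed = 3, protein_id = "rt")
    chain <- parse_structure(gc_$pdb)
    expect_length(chain, 15)
    expect_equal(chain$coords, gc_$chain$coords, tolerance = 1e-2)
    expect_equal(chain$amino_acid, gc_$chain$amino_acid)
  }
})

test_that("random-coil traces keep near-constant step length", {
  gc_ <- generate_chain(30, "random-coil", seed = 7)
  steps <- sqrt(rowSums(diff(gc_$chain$coords)^2))
  expect_equal(steps, rep(3.8, 29), tolerance = 1e-6)
})

test_that("datasets are byte-identical for a fixed seed", {
  spec <- synthetic_spec(n_proteins = 6, length_range = c(12L, 20L),
                         label_noise = 0.05, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(spec, d1)
  generate_dataset(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  spec2 <- synthetic_spec(n_proteins = 6, length_range = c(12L, 20L),
                          label_noise = 0.05, seed = 43)
  generate_dataset(spec2, d3)
  expect_false(identical(readLines(file.path(d1, "annotations.tsv")),
                         readLines(file.path(d3, "annotations.tsv"))))
})

test_that("all emitted files parse with the package readers", {
  spec <- synthetic_spec(n_proteins = 8, length_range = c(12L, 25L), seed = 5)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(spec, dir)
  dag <- parse_obo(ds$files$obo)
  expect_equal(dag$n_terms, spec$n_terms)
  recs <- read_fasta(ds$files$fasta)
  expect_length(recs, 8)
  ann <- read_annotations(ds$files$annotations, dag, "MFO")
  expect_s3_class(ann, "annotation_set")
  for (f in list.files(ds$files$pdb_dir, full.names = TRUE)) {
    ch <- parse_structure(f)
    expect_gte(length(ch), 12)
  }
  # sequence in FASTA matches the PDB-derived sequence
  ch <- parse_structure(file.path(ds$files$pdb_dir, "P0001.pdb"))
  expect_equal(chain_sequence(ch), recs$P0001$sequence)
})

test_that("noise-free motif terms follow motif presence exactly", {
  spec <- synthetic_spec(n_proteins = 25, length_range = c(20L, 40L),
                         label_noise = 0, seed = 9)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(spec, dir)
  recs <- read_fasta(ds$files$fasta)
  ann <- read.table(ds$files$annotations, sep = "\t",
                    col.names = c("protein_id", "term_id"))
  for (m in seq_along(spec$motifs)) {
    term <- ds$motif_terms[[m]]
    has <- vapply(recs, function(r) grepl(spec$motifs[m], r$sequence,
                                          fixed = TRUE), logical(1))
    annotated <- names(recs) %in% ann$protein_id[ann$term_id == term]
    expect_equal(unname(annotated), unname(has), label = spec$motifs[m])
  }
})

test_that("planted motif signal is recoverable at 5% noise", {
  # n chosen for statistical power: ~100 predicted positives per motif,
  # so the expected 0.95 precision sits ~5 sigma above the 0.9 bound
  spec <- synthetic_spec(n_proteins = 300, length_range = c(30L, 60L),
                         label_noise = 0.05, seed = 11)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(spec, dir)
  recs <- read_fasta(ds$files$fasta)
  ann <- read.table(ds$files$annotations, sep = "\t",
                    col.names = c("protein_id", "term_id"))
  # the trivial motif-presence classifier is precise for each motif term
  for (m in seq_along(spec$motifs)) {
    term <- ds$motif_terms[[m]]
    pred_pos <- names(recs)[vapply(recs, function(r)
      grepl(spec$motifs[m], r$sequence, fixed = TRUE), logical(1))]
    if (length(pred_pos) == 0) next
    truth <- ann$protein_id[ann$term_id == term]
    precision <- mean(pred_pos %in% truth)
    expect_gt(precision, 0.9)
  }
})

test_that("contact-density bands separate fold modes", {
  spec <- synthetic_spec(n_proteins = 30, length_range = c(20L, 40L),
                         label_noise = 0, seed = 13)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(spec, dir)
  truth <- read.table(ds$files$truth, header = TRUE, sep = "\t")
  ext <- truth$contact_density[truth$fold_mode == "extended"]
  hel <- truth$contact_density[truth$fold_mode == "helix"]
  expect_true(all(ext < 4.5))
  expect_true(all(hel >= 8.5))
})

test_that("spec validation rejects overlapping bands and tiny ontologies", {
  expect_error(synthetic_spec(contact_bands = list(c(0, 6), c(5, 10))),
               "non-overlapping")
  expect_error(synthetic_spec(n_terms = 5), "n_terms too small")
})
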