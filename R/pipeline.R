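## Reproducible end-to-end pipeline with digest-based stage skipping.
##
## Stages: simulate (optional) -> build-graphs -> embed-nodes ->
## embed-seqs -> prepare-labels -> train -> evaluate.  Every stage
## records md5 digests of its inputs, parameters and outputs; a rerun
## skips a stage whose digests all match, and any stage that does run
## forces every downstream stage to run too.

GRAPHGO_VERSION <- "graphgo-0.1.0"

#' Pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param data_dir input dataset directory containing `pdb/`,
#'   `sequences.fasta`, `ontology.obo`, `annotations.tsv`; ignored when
#'   `simulate` is given.
#' @param simulate optional [synthetic_spec()]: generate the dataset
#'   under `out_dir/data` first.
#' @param namespace GO namespace of the annotations, default "MFO".
#' @param threshold contact threshold in Angstrom, default 10.
#' @param walk a [walk_config()].
#' @param seq_mode "mock" (deterministic k-mer embedding) or "plm"
#'   (load precomputed embeddings from `plm_path`).
#' @param seq_dim mock embedding width, default 64.
#' @param plm_path embedding TSV for `seq_mode = "plm"`.
#' @param min_proteins rare-term threshold, default 25.
#' @param model_args named list of overrides passed to [model_config()]
#'   (e.g. `hidden_dim`, `n_blocks`, `use_onehot_node_features`).
#' @param split a [split_spec()].
#' @param train a [train_config()].
#' @param seed master seed; stage seeds derive from it unless the
#'   section configs carry their own.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, data_dir = NULL, simulate = NULL,
                            namespace = "MFO", threshold = 10,
                            walk = walk_config(), seq_mode = c("mock", "plm"),
                            seq_dim = 64L, plm_path = NULL,
                            min_proteins = 25L, model_args = list(),
                            split = split_spec(), train = train_config(),
                            seed = 0L) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(simulate) && is.null(data_dir)) {
    stop_graphgo("pipeline_config: need data_dir or a simulate spec")
  }
  structure(list(out_dir = out_dir, data_dir = data_dir, simulate = simulate,
                 namespace = namespace, threshold = threshold, walk = walk,
                 seq_mode = seq_mode, seq_dim = as.integer(seq_dim),
                 plm_path = plm_path, min_proteins = as.integer(min_proteins),
                 model_args = model_args, split = split, train = train,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

digest_files <- function(paths) {
  paths <- sort(unlist(paths))
  paths <- paths[file.exists(paths)]
  md5 <- tools::md5sum(paths)
  paste(basename(paths), unname(md5), sep = "=")
}

stage_signature <- function(params, inputs, outputs) {
  c(paste0("version=", GRAPHGO_VERSION),
    paste0("params=", paste(deparse(params), collapse = "")),
    paste0("in:", digest_files(inputs)),
    paste0("out:", digest_files(outputs)))
}

# Run one stage with digest-based skipping.  Returns TRUE if it ran.
run_stage <- function(name, out_dir, params, inputs, outputs, force, fn,
                      log = message) {
  digest_dir <- file.path(out_dir, ".digests")
  dir.create(digest_dir, recursive = TRUE, showWarnings = FALSE)
  sigfile <- file.path(digest_dir, paste0(name, ".sig"))
  outs_exist <- length(outputs) > 0 && all(file.exists(unlist(outputs)))
  if (!force && outs_exist && file.exists(sigfile)) {
    current <- stage_signature(params, inputs, outputs)
    if (identical(readLines(sigfile, warn = FALSE), current)) {
      log(sprintf("[%s] up to date, skipped", name))
      return(FALSE)
    }
  }
  log(sprintf("[%s] running", name))
  ok <- tryCatch({ fn(); TRUE }, error = function(e) {
    stop_graphgo(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  writeLines(stage_signature(params, inputs, outputs), sigfile)
  TRUE
}

#' Run the full pipeline
#'
#' Executes every stage with digest-based skipping and writes all
#' artifacts under `config$out_dir`: `graphs/`, `node_embeddings/`,
#' `seq_embeddings.tsv`, `labels.tsv`, `split.tsv`, `model.rds`,
#' `predictions.tsv` and `metrics.txt`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return List with `metrics` (named list: fmax, auc, aupr on the test
#'   split), `stages_run` (named logical) and `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else message
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ran <- c()

  ## -- simulate ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    data_dir <- file.path(out, "data")
    r <- run_stage("simulate", out, params = config$simulate,
                   inputs = character(0),
                   outputs = list(file.path(data_dir, "sequences.fasta"),
                                  file.path(data_dir, "ontology.obo"),
                                  file.path(data_dir, "annotations.tsv")),
                   force = FALSE, log = log,
                   fn = function() generate_dataset(config$simulate, data_dir))
    ran["simulate"] <- r
  } else {
    data_dir <- config$data_dir
    ran["simulate"] <- FALSE
  }
  pdb_dir <- file.path(data_dir, "pdb")
  pdb_files <- sort(list.files(pdb_dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdb_files) == 0L) stop_graphgo(sprintf("no PDB files in %s", pdb_dir))
  ids <- sub("\\.pdb$", "", basename(pdb_files))

  ## -- build-graphs ------------------------------------------------------
  graph_dir <- file.path(out, "graphs")
  graph_files <- file.path(graph_dir, paste0(ids, ".edgelist"))
  force <- any(ran)
  r <- run_stage("build-graphs", out,
                 params = list(threshold = config$threshold),
                 inputs = pdb_files, outputs = graph_files,
                 force = force, log = log, fn = function() {
    dir.create(graph_dir, showWarnings = FALSE)
    for (i in seq_along(pdb_files)) {
      chain <- parse_structure(pdb_files[i])
      g <- build_contact_graph(chain, config$threshold, add_self_loops = TRUE)
      write_edge_list(g, graph_files[i])
    }
  })
  ran["build-graphs"] <- r

  ## -- embed-nodes -------------------------------------------------------
  emb_dir <- file.path(out, "node_embeddings")
  emb_files <- file.path(emb_dir, paste0(ids, ".tsv"))
  force <- any(ran)
  wc <- config$walk
  wc$seed <- derive_seed(config$seed, "embed-nodes")
  r <- run_stage("embed-nodes", out, params = wc,
                 inputs = graph_files, outputs = emb_files,
                 force = force, log = log, fn = function() {
    dir.create(emb_dir, showWarnings = FALSE)
    for (i in seq_along(graph_files)) {
      g <- read_edge_list(graph_files[i], protein_id = ids[i])
      tab <- suppressWarnings(embed_protein(g, wc))
      write_embedding_table(tab, emb_files[i])
    }
  })
  ran["embed-nodes"] <- r

  ## -- embed-seqs --------------------------------------------------------
  fasta <- file.path(data_dir, "sequences.fasta")
  seq_emb_file <- file.path(out, "seq_embeddings.tsv")
  force <- any(ran)
  r <- run_stage("embed-seqs", out,
                 params = list(mode = config$seq_mode, dim = config$seq_dim,
                               seed = derive_seed(config$seed, "embed-seqs")),
                 inputs = c(fasta, config$plm_path), outputs = seq_emb_file,
                 force = force, log = log, fn = function() {
    if (config$seq_mode == "plm") {
      embs <- load_plm_embeddings(config$plm_path)
    } else {
      records <- read_fasta(fasta)
      embs <- mock_embed_all(records, dim = config$seq_dim,
                             seed = derive_seed(config$seed, "embed-seqs"))
    }
    write_embeddings(embs, seq_emb_file)
  })
  ran["embed-seqs"] <- r

  ## -- prepare-labels ----------------------------------------------------
  obo <- file.path(data_dir, "ontology.obo")
  ann_file <- file.path(data_dir, "annotations.tsv")
  labels_file <- file.path(out, "labels.tsv")
  force <- any(ran)
  r <- run_stage("prepare-labels", out,
                 params = list(namespace = config$namespace,
                               min_proteins = config$min_proteins),
                 inputs = c(obo, ann_file), outputs = labels_file,
                 force = force, log = log, fn = function() {
    dag <- parse_obo(obo)
    ann <- read_annotations(ann_file, dag, config$namespace)
    ann <- propagate(ann, dag)
    vocab <- filter_rare_terms(ann, dag, config$min_proteins)
    labs <- build_label_matrix(ann, vocab)
    write_label_matrix(labs, labels_file)
  })
  ran["prepare-labels"] <- r

  ## -- train -------------------------------------------------------------
  model_file <- file.path(out, "model.rds")
  split_file <- file.path(out, "split.tsv")
  force <- any(ran)
  r <- run_stage("train", out,
                 params = list(model = config$model_args, train = config$train,
                               split = config$split, seed = config$seed),
                 inputs = c(emb_files, seq_emb_file, labels_file),
                 outputs = c(model_file, split_file),
                 force = force, log = log, fn = function() {
    ds <- pipeline_load_dataset(config, data_dir, ids, graph_files, emb_files,
                                seq_emb_file, labels_file)
    sp <- config$split
    sp$seed <- derive_seed(config$seed, "split")
    split <- split_dataset(ds$labels$protein_ids, sp)
    tc <- config$train
    tc$seed <- derive_seed(config$seed, "train")
    fit <- train_model(ds$inputs, ds$labels$matrix, split, ds$mconfig, tc)
    save_model(fit$state, ds$mconfig, model_file)
    sdf <- data.frame(
      protein_id = c(split$train, split$valid, split$test),
      subset = rep(c("train", "valid", "test"), lengths(split)))
    write.table(sdf, split_file, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fit$log, file.path(out, "train_log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  ran["train"] <- r

  ## -- evaluate ----------------------------------------------------------
  pred_file <- file.path(out, "predictions.tsv")
  metrics_file <- file.path(out, "metrics.txt")
  force <- any(ran)
  r <- run_stage("evaluate", out, params = list(),
                 inputs = c(model_file, split_file, labels_file,
                            emb_files, seq_emb_file),
                 outputs = c(pred_file, metrics_file),
                 force = force, log = log, fn = function() {
    ds <- pipeline_load_dataset(config, data_dir, ids, graph_files, emb_files,
                                seq_emb_file, labels_file)
    mod <- load_model(model_file)
    sdf <- read.table(split_file, sep = "\t", header = TRUE,
                      colClasses = "character")
    test_ids <- sdf$protein_id[sdf$subset == "test"]
    preds <- model_forward(ds$inputs[test_ids], mod$state, mod$config)
    colnames(preds) <- ds$labels$term_vocab
    pl <- data.frame(
      protein_id = rep(test_ids, each = ncol(preds)),
      term_id = rep(colnames(preds), times = length(test_ids)),
      score = sprintf("%.6f", as.numeric(t(preds))))
    write.table(pl, pred_file, sep = "\t", quote = FALSE, row.names = FALSE)
    yt <- ds$labels$matrix[test_ids, , drop = FALSE]
    met <- list(
      fmax = suppressWarnings(fmax(yt, preds)$fmax),
      auc = auc_score(yt, preds),
      aupr = aupr_score(yt, preds))
    write_metrics_report(met, metrics_file)
  })
  ran["evaluate"] <- r

  metrics_lines <- read.table(metrics_file, sep = "\t",
                              col.names = c("metric", "value"))
  metrics <- setNames(as.list(metrics_lines$value), metrics_lines$metric)
  list(metrics = metrics, stages_run = ran,
       paths = list(out_dir = out, data_dir = data_dir,
                    labels = labels_file, model = model_file,
                    predictions = pred_file, metrics = metrics_file,
                    split = split_file))
}

# Load every artifact needed by train/evaluate into memory.
pipeline_load_dataset <- function(config, data_dir, ids, graph_files,
                                  emb_files, seq_emb_file, labels_file) {
  graphs <- setNames(lapply(seq_along(ids), function(i)
    read_edge_list(graph_files[i], protein_id = ids[i])), ids)
  embs <- setNames(lapply(emb_files, read_embedding_table), ids)
  seq_embs_raw <- load_plm_embeddings(seq_emb_file)
  records <- read_fasta(file.path(data_dir, "sequences.fasta"))
  labs <- read_label_matrix(labels_file)
  use_onehot <- config$model_args$use_onehot_node_features %||% TRUE
  keep <- labs$protein_ids
  inputs <- assemble_inputs(graphs[keep], embs[keep], records[keep],
                            seq_embs_raw[keep], use_onehot = use_onehot)
  margs <- config$model_args
  margs$use_onehot_node_features <- use_onehot
  margs$n_labels <- length(labs$term_vocab)
  margs$node_feature_dim <- config$walk$embedding_dim +
    if (use_onehot) length(AA_ALPHABET) else 0L
  margs$seq_embedding_dim <- length(seq_embs_raw[[1]]$vector)
  if (is.null(margs$seed)) margs$seed <- derive_seed(config$seed, "model")
  mconfig <- do.call(model_config, margs)
  list(inputs = inputs, labels = labs, mconfig = mconfig, records = records)
}
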