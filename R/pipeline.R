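SEQ_BLOCKS <- c("CTD", "PseKNC", "NPS", "NPPS", "NCP_ND", "EIIP", "BPB")

#' Per-dataset feature-block presets
#'
#' Named block lists matched to the published benchmark sets: `A101`
#' (PseKNC, CTD, NPS), `A25` (EIIP, NPPS, NPS, PseKNC, NCP-ND), `S21`
#' (NPPS, NCP-ND) and `H41` (NCP-ND, PseKNC, NPPS).
#'
#' @param name Preset name, or `NULL` to list all presets.
#' @return A character vector of block names (or a named list of them).
#' @export
preset_blocks <- function(name = NULL) {
  presets <- list(
    A101 = c("PseKNC", "CTD", "NPS"),
    A25 = c("EIIP", "NPPS", "NPS", "PseKNC", "NCP_ND"),
    S21 = c("NPPS", "NCP_ND"),
    H41 = c("NCP_ND", "PseKNC", "NPPS")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
      paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

#' Pipeline configuration
#'
#' Assembles every stage parameter of the end-to-end predictor into one
#' config object. A single global `seed` propagates to all stage seeds
#' (split, similarity-matrix initialization, walks, skip-gram, booster)
#' unless a stage block overrides its own seed.
#'
#' @param blocks Character vector of sequence-feature block names (subset of
#'   CTD, PseKNC, NPS, NPPS, NCP_ND, EIIP, BPB), a preset name (`"A101"`,
#'   `"A25"`, `"S21"`, `"H41"`), or `"auto"` for importance-based selection.
#' @param n_keep Blocks kept under `"auto"` selection.
#' @param pseknc,nps,npps Encoder parameter lists: `pseknc = list(k, lambda,
#'   w)`, `nps = list(d_max)`, `npps = list(k = c(1, 2))`.
#' @param flnsa Similarity-learner parameters (`c`, `mu`, `max_iter`, `tol`,
#'   `t`); see [flnsa_similarity()] and [build_graph()].
#' @param embeddings Which embeddings to compute, with their parameters:
#'   a named list among `socdim`, `node2vec`, `grarep` (use `NULL` entries
#'   for defaults); or `FALSE`/empty list to run on sequence features only.
#' @param train A [train_config()] (its seed is overridden by `seed`).
#' @param train_fraction,stratified Train/test split specification.
#' @param fit_on_all Fit the BPB/NPPS frequency tables on all samples
#'   instead of the training split only. Default `FALSE` (leakage-safe).
#' @param inductive Restrict the similarity graph to training samples and
#'   map each test sample to the embedding of its nearest training neighbor.
#'   Default `FALSE`: the network is built over the whole dataset
#'   (transductive), mirroring the published protocol.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(blocks = "auto", n_keep = 3L,
                            pseknc = list(), nps = list(), npps = list(),
                            flnsa = list(), embeddings = list(
                              socdim = NULL, node2vec = NULL, grarep = NULL
                            ),
                            train = train_config(),
                            train_fraction = 0.8, stratified = TRUE,
                            fit_on_all = FALSE, inductive = FALSE,
                            seed = 1L) {
  if (length(blocks) == 1L && blocks %in% names(preset_blocks())) {
    blocks <- preset_blocks(blocks)
  }
  if (!identical(blocks, "auto")) {
    unknown <- setdiff(blocks, SEQ_BLOCKS)
    if (length(unknown)) {
      abort(sprintf("unknown feature block(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  if (isFALSE(embeddings)) embeddings <- list()
  structure(
    list(
      blocks = blocks, n_keep = as.integer(n_keep),
      pseknc = utils::modifyList(list(k = 3L, lambda = 2L, w = 0.1), pseknc),
      nps = utils::modifyList(list(d_max = 3L), nps),
      npps = utils::modifyList(list(k = c(1L, 2L)), npps),
      flnsa = utils::modifyList(
        list(c = 10L, mu = 1, max_iter = 200L, tol = 1e-6, t = NULL), flnsa
      ),
      embeddings = embeddings, train = train,
      train_fraction = train_fraction, stratified = stratified,
      fit_on_all = fit_on_all, inductive = inductive,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

encode_blocks <- function(data, fit_data, cfg) {
  enc <- list()
  out <- list()
  for (b in cfg$blocks) {
    out[[b]] <- switch(b,
      CTD = encode_ctd(data),
      EIIP = encode_eiip(data),
      NCP_ND = encode_ncp_nd(data),
      NPS = encode_nps(data, d_max = cfg$nps$d_max),
      PseKNC = encode_pseknc(data,
        k = cfg$pseknc$k, lambda = cfg$pseknc$lambda, w = cfg$pseknc$w
      ),
      BPB = {
        enc$bpb <- fit_bpb(fit_data)
        encode_bpb(data, enc$bpb)
      },
      NPPS = {
        sub <- lapply(cfg$npps$k, function(k) {
          m <- fit_npps(fit_data, k = k)
          enc[[paste0("npps_k", k)]] <<- m
          encode_npps(data, m)
        })
        fuse_features(sub)
      }
    )
  }
  list(blocks = out, encoders = enc)
}

#' Run the end-to-end m6A prediction pipeline
#'
#' Executes: stratified train/test split; fitting of the class-conditional
#' encoders (BPB, NPPS) on the training split only; encoding of all samples;
#' FLNSA similarity network over the whole dataset (transductive default);
#' SocDim / Node2Vec / GraRep embeddings; fusion of the selected sequence
#' blocks with the embeddings; class-weighted boosted-tree training; and
#' evaluation on the held-out split. Returns the metrics report together
#' with the fitted model, the importance report and a run manifest that
#' reproduces the run bit-for-bit (see [run_manifest()]).
#'
#' @param data A sample-set tibble (e.g. from [read_fasta_samples()] or
#'   [generate_dataset()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (metrics JSON/TSV, ROC
#'   TSV, importance TSV, model bundle, manifest).
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `m6a_run` with elements `metrics`,
#'   `predictions`, `model`, `importance`, `graph`, `selected_blocks`,
#'   `manifest`, and `timings`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- validate_sample_set(data)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[m6ager] ", fmt), ...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- tic() - t0
    say("%s done (%.2fs)", name, timings[[name]])
    r
  }
  seed <- config$seed

  sp <- stage("split", split_dataset(data,
    train_fraction = config$train_fraction,
    seed = seed, stratified = config$stratified
  ))
  fit_data <- if (config$fit_on_all) data else sp$train

  blocks_cfg <- config
  if (identical(config$blocks, "auto")) {
    blocks_cfg$blocks <- SEQ_BLOCKS
    all_enc <- stage("encode_candidates", encode_blocks(sp$train, sp$train, blocks_cfg))
    sel <- stage("select_blocks", select_feature_blocks(
      sp$train, all_enc$blocks,
      cfg = train_config(
        iterations = 100L, depth = config$train$depth,
        learning_rate = config$train$learning_rate, seed = seed
      ),
      n_keep = config$n_keep
    ))
  } else {
    sel <- config$blocks
  }
  say("selected blocks: %s", paste(sel, collapse = ", "))
  blocks_cfg$blocks <- sel
  enc <- stage("encode", encode_blocks(data, fit_data, blocks_cfg))
  seq_features <- fuse_features(enc$blocks)

  emb_blocks <- list()
  graph <- NULL
  if (length(config$embeddings)) {
    graph_input <- if (config$inductive) {
      seq_features[match(sp$train$id, seq_features$id), , drop = FALSE]
    } else {
      seq_features
    }
    graph <- stage("graph", {
      fl <- config$flnsa
      sim <- flnsa_similarity(graph_input,
        c = min(fl$c, nrow(graph_input) - 1L), mu = fl$mu,
        max_iter = fl$max_iter, tol = fl$tol, seed = seed + 1L
      )
      build_graph(sim, X = graph_input, t = fl[["t"]])
    })
    emb_blocks <- stage("embed", {
      e <- config$embeddings
      out <- list()
      if ("socdim" %in% names(e)) {
        out$SocDim <- do.call(socdim_embed, c(list(graph), e$socdim))
      }
      if ("node2vec" %in% names(e)) {
        args <- utils::modifyList(list(seed = seed + 2L), e$node2vec %||% list())
        out$N2V <- do.call(node2vec_embed, c(list(graph), args))
      }
      if ("grarep" %in% names(e)) {
        args <- utils::modifyList(list(seed = seed + 3L), e$grarep %||% list())
        out$GraRep <- do.call(grarep_embed, c(list(graph), args))
      }
      out
    })
    if (config$inductive) {
      emb_blocks <- lapply(emb_blocks, function(b) {
        inductive_extend(b, seq_features, sp$train$id)
      })
    }
  }

  fused <- fuse_features(c(list(seq_features), unname(emb_blocks)))
  train_X <- fused[match(sp$train$id, fused$id), , drop = FALSE]
  test_X <- fused[match(sp$test$id, fused$id), , drop = FALSE]

  tcfg <- config$train
  tcfg$seed <- seed
  model <- stage("train", train_model(train_X, sp$train$label, tcfg,
    encoders = enc$encoders
  ))
  preds <- stage("predict", predict(model, test_X))
  metrics <- stage("evaluate", compute_metrics(sp$test$label,
    y_pred = preds$label, y_score = preds$score
  ))
  importance <- feature_importance(model, top_n = min(20L, length(model$columns)))

  manifest <- list(
    config = config_to_list(config), selected_blocks = sel,
    n_samples = nrow(data), seq_length = nchar(data$sequence[[1L]]),
    data_digest = sample_digest(data),
    package_version = as.character(utils::packageVersion("m6ager"))
  )
  run <- structure(
    list(
      metrics = metrics, predictions = preds, model = model,
      importance = importance, graph = graph, selected_blocks = sel,
      split = list(train_ids = sp$train$id, test_ids = sp$test$id),
      features = fused, seq_feature_cols = colnames(feature_matrix(seq_features)),
      manifest = manifest, timings = timings, data = data
    ),
    class = "m6a_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

inductive_extend <- function(block, seq_features, train_ids) {
  # map each non-training sample to the embedding of its nearest training
  # neighbor in (rescaled) sequence-feature space
  Xall <- minmax_rescale(feature_matrix(seq_features))
  tr <- match(train_ids, seq_features$id)
  te <- setdiff(seq_len(nrow(Xall)), tr)
  Bm <- feature_matrix(block)
  if (!length(te)) return(block)
  d2 <- outer(rowSums(Xall[te, , drop = FALSE]^2), rowSums(Xall[tr, , drop = FALSE]^2), "+") -
    2 * tcrossprod(Xall[te, , drop = FALSE], Xall[tr, , drop = FALSE])
  nn <- apply(d2, 1L, which.min)
  full <- matrix(0, nrow(Xall), ncol(Bm), dimnames = list(NULL, colnames(Bm)))
  full[tr, ] <- Bm
  full[te, ] <- Bm[nn, , drop = FALSE]
  new_feature_block(seq_features$id, full, attr(block, "block"))
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$train <- unclass(out$train)
  out$embeddings <- lapply(out$embeddings, function(e) e %||% list())
  out
}

config_from_list <- function(lst) {
  lst$train <- do.call(train_config, lst$train)
  lst$embeddings <- lapply(lst$embeddings, function(e) if (length(e)) e else NULL)
  # JSON has no NULL scalar: an absent threshold round-trips as empty/missing
  if (!length(lst$flnsa[["t"]])) lst$flnsa["t"] <- list(NULL)
  do.call(pipeline_config, lst)
}

sample_digest <- function(data) {
  # order-sensitive content fingerprint, no external digest dependency
  s <- paste(data$id, data$label, data$sequence, collapse = ";")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2147483647
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics(run$metrics,
    json_path = file.path(out_dir, "metrics.json"),
    tsv_path = file.path(out_dir, "metrics.tsv"),
    roc_path = file.path(out_dir, "roc.tsv")
  )
  utils::write.table(run$importance$features, file.path(out_dir, "importance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(run$predictions, file.path(out_dir, "predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  save_model(run$model, file.path(out_dir, "model"))
  saveRDS(run, file.path(out_dir, "run.rds"))
  if (!is.null(run$graph)) {
    write_edge_list(run$graph, file.path(out_dir, "graph_edges.tsv"),
      file.path(out_dir, "graph_nodes.txt")
    )
  }
  invisible(out_dir)
}

#' Score new sequence segments with a finished pipeline run
#'
#' Encodes new samples with the run's fitted encoders (BPB/NPPS frequency
#' tables learned on the original training split) and its encoder
#' parameters; embedding features, which are defined only for nodes of the
#' training-time similarity graph, are transferred from the nearest original
#' sample in rescaled sequence-feature space. The fused vector is then
#' scored by the trained model.
#'
#' @param run An `m6a_run` from [run_pipeline()].
#' @param new_data A sample-set tibble at the same segment length (labels,
#'   if present, are ignored).
#' @param threshold Probability cutoff for the hard label.
#' @return A tibble `id`, `score`, `label`.
#' @export
predict_samples <- function(run, new_data, threshold = 0.5) {
  stopifnot(inherits(run, "m6a_run"))
  new_data <- as_tibble(new_data)
  if (!"label" %in% names(new_data)) new_data$label <- 0L
  new_data <- validate_sample_set(new_data)
  config <- config_from_list(run$manifest$config)
  blocks <- encode_blocks_fitted(new_data, config, run$selected_blocks,
    run$model$encoders
  )
  seq_new <- fuse_features(blocks)
  seq_cols <- run$seq_feature_cols
  if (!identical(colnames(feature_matrix(seq_new)), seq_cols)) {
    abort("encoded features of the new data do not match the run's sequence features")
  }
  feat <- run$features
  emb_cols <- setdiff(setdiff(names(feat), "id"), seq_cols)
  if (length(emb_cols)) {
    ref_raw <- as.matrix(feat[, seq_cols, drop = FALSE])
    lo <- apply(ref_raw, 2L, min)
    rng <- apply(ref_raw, 2L, max) - lo
    rng[rng == 0] <- 1
    ref <- sweep(sweep(ref_raw, 2L, lo), 2L, rng, "/")
    qry <- sweep(sweep(feature_matrix(seq_new), 2L, lo), 2L, rng, "/")
    d2 <- outer(rowSums(qry^2), rowSums(ref^2), "+") - 2 * tcrossprod(qry, ref)
    nn <- apply(d2, 1L, which.min)
    emb <- as.matrix(feat[nn, emb_cols, drop = FALSE])
    fb_emb <- new_feature_block(seq_new$id, emb, "transferred")
    attr(fb_emb, "block_map") <- attr(run$features, "block_map")[emb_cols]
    fused <- fuse_features(seq_new, fb_emb)
  } else {
    fused <- seq_new
  }
  attr(fused, "block_map") <- run$model$block_map
  predict(run$model, fused, threshold = threshold)
}

encode_blocks_fitted <- function(data, config, sel, encoders) {
  out <- list()
  for (b in sel) {
    out[[b]] <- switch(b,
      CTD = encode_ctd(data),
      EIIP = encode_eiip(data),
      NCP_ND = encode_ncp_nd(data),
      NPS = encode_nps(data, d_max = config$nps$d_max),
      PseKNC = encode_pseknc(data,
        k = config$pseknc$k, lambda = config$pseknc$lambda, w = config$pseknc$w
      ),
      BPB = encode_bpb(data, encoders$bpb),
      NPPS = fuse_features(lapply(config$npps$k, function(k) {
        encode_npps(data, encoders[[paste0("npps_k", k)]])
      }))
    )
  }
  out
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the configuration recorded in a run
#' manifest; with the same input data this reproduces the metrics report
#' bit-for-bit.
#'
#' @param manifest A manifest list from a previous run, or the path of a
#'   written `manifest.json`.
#' @param data The same sample set used by the original run (checked against
#'   the manifest's content fingerprint).
#' @inheritParams run_pipeline
#' @return An `m6a_run`.
#' @export
run_manifest <- function(manifest, data, out_dir = NULL, quiet = TRUE) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  data <- validate_sample_set(data)
  if (!is.null(manifest$data_digest) &&
    manifest$data_digest != sample_digest(data)) {
    abort("supplied data does not match the manifest's dataset fingerprint")
  }
  run_pipeline(data, config_from_list(manifest$config), out_dir = out_dir, quiet = quiet)
}

#' @export
print.m6a_run <- function(x, ...) {
  cat(sprintf(
    "<m6a_run> %d samples, blocks: %s%s\n",
    x$manifest$n_samples, paste(x$selected_blocks, collapse = ", "),
    if (is.null(x$graph)) " (no graph)" else ""
  ))
  print(x$metrics)
  invisible(x)
}
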