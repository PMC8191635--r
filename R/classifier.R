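#' Training configuration for the gradient-boosted tree classifier
#'
#' The booster is a gradient-boosted decision-tree ensemble (xgboost backend)
#' with a logistic-loss objective. Class imbalance is handled by per-class
#' weights; `"auto"` sets the weight of class y to
#' (total samples) / (2 * samples of class y), i.e. inversely proportional
#' to the class size, so both classes carry equal total weighted mass.
#'
#' @param iterations Number of boosting rounds.
#' @param depth Tree depth.
#' @param learning_rate Shrinkage (eta).
#' @param class_weights `"auto"`, or a numeric pair `c(neg, pos)` of weights
#'   for classes 0 and 1.
#' @param seed Integer seed; training is single-threaded and deterministic.
#' @param backend Boosting backend identifier (only `"xgboost"` is built in).
#' @return A `train_config` list.
#' @export
train_config <- function(iterations = 500L, depth = 6L, learning_rate = 0.05,
                         class_weights = "auto", seed = 1L,
                         backend = "xgboost") {
  if (!identical(backend, "xgboost")) {
    abort(sprintf("unknown boosting backend '%s'", backend))
  }
  stopifnot(iterations >= 1L, depth >= 1L, learning_rate > 0)
  structure(
    list(
      iterations = as.integer(iterations), depth = as.integer(depth),
      learning_rate = learning_rate, class_weights = class_weights,
      seed = as.integer(seed), backend = backend
    ),
    class = "train_config"
  )
}

resolve_class_weights <- function(class_weights, y) {
  if (identical(class_weights, "auto")) {
    n <- length(y)
    cw <- c(`0` = n / (2 * sum(y == 0L)), `1` = n / (2 * sum(y == 1L)))
  } else {
    stopifnot(is.numeric(class_weights), length(class_weights) == 2L)
    cw <- setNames(as.numeric(class_weights), c("0", "1"))
  }
  cw
}

#' Train the m6A site classifier
#'
#' Fits a class-weighted gradient-boosted decision-tree model on a fused
#' feature block. Deterministic for a fixed seed (single-threaded backend).
#'
#' @param train_X An `m6a_features` tibble (fused features of the training
#'   samples).
#' @param train_y Integer labels (0/1), one per row of `train_X`.
#' @param cfg A [train_config()].
#' @param encoders Optional list of fitted encoder models and parameters
#'   needed to encode new data (stored with the model for prediction-time
#'   reuse).
#' @return An object of class `m6a_model`.
#' @export
train_model <- function(train_X, train_y, cfg = train_config(), encoders = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  Xm <- feature_matrix(train_X)
  y <- as.integer(train_y)
  if (length(y) != nrow(Xm)) abort("train_y length must match the number of rows of train_X")
  if (length(unique(y)) < 2L) abort("training labels contain a single class")
  if (any(table(y) < 2L)) abort("need at least 2 samples per class")
  if (any(!is.finite(Xm))) abort("training features contain non-finite values")
  cw <- resolve_class_weights(cfg$class_weights, y)
  dtrain <- xgboost::xgb.DMatrix(Xm, label = y, weight = unname(cw[as.character(y)]))
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", max_depth = cfg$depth,
      eta = cfg$learning_rate, nthread = 1L, seed = cfg$seed,
      eval_metric = "logloss"
    ),
    data = dtrain, nrounds = cfg$iterations, verbose = 0
  )
  structure(
    list(
      booster = booster, columns = colnames(Xm),
      block_map = block_map(train_X)[colnames(Xm)],
      config = cfg, class_weights = cw, encoders = encoders,
      n_train = nrow(Xm)
    ),
    class = "m6a_model"
  )
}

#' @export
print.m6a_model <- function(x, ...) {
  cat(sprintf(
    "<m6a_model> %s, %d rounds, depth %d, eta %g | %d features, %d training samples\n",
    x$config$backend, x$config$iterations, x$config$depth,
    x$config$learning_rate, length(x$columns), x$n_train
  ))
  invisible(x)
}

#' Predict m6A site probabilities
#'
#' @param object A fitted `m6a_model`.
#' @param X An `m6a_features` tibble with exactly the training columns.
#' @param threshold Probability cutoff for the hard label (default 0.5).
#' @param ... Unused.
#' @return A tibble with `id`, `score` (probability of the positive class)
#'   and `label` (score >= threshold).
#' @export
predict.m6a_model <- function(object, X, threshold = 0.5, ...) {
  Xm <- feature_matrix(X)
  missing <- setdiff(object$columns, colnames(Xm))
  extra <- setdiff(colnames(Xm), object$columns)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "feature columns do not match training columns%s%s",
      if (length(missing)) paste0("; missing: ", paste(head(missing, 3), collapse = ", ")) else "",
      if (length(extra)) paste0("; extra: ", paste(head(extra, 3), collapse = ", ")) else ""
    ))
  }
  Xm <- Xm[, object$columns, drop = FALSE]
  score <- predict(object$booster, xgboost::xgb.DMatrix(Xm))
  tibble(id = X$id, score = as.numeric(score), label = as.integer(score >= threshold))
}

embedding_blocks <- function() c("SocDim", "N2V", "GraRep")

#' Feature-importance report
#'
#' Ranks features by the backend's importance score (gain), aggregates
#' scores per encoder/embedding block, and reports which fraction of the
#' `top_n` features comes from graph-embedding blocks.
#'
#' @param model A fitted `m6a_model`.
#' @param top_n Number of top features to report (clamped, with a warning,
#'   to the number of features).
#' @return An object of class `m6a_importance`: tibbles `$features` (ranked
#'   `feature`, `score`, `block`), `$blocks` (per-block aggregate over the
#'   full ranking and share of the top-n), and `$embedding_fraction`.
#' @export
feature_importance <- function(model, top_n = 20L) {
  stopifnot(inherits(model, "m6a_model"))
  if (top_n > length(model$columns)) {
    warn(sprintf("top_n = %d exceeds the %d features; clamping", top_n, length(model$columns)))
    top_n <- length(model$columns)
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  score <- setNames(rep(0, length(model$columns)), model$columns)
  score[imp$Feature] <- imp$Gain
  ord <- order(score, decreasing = TRUE)
  feats <- tibble(
    feature = model$columns[ord],
    score = unname(score[ord]),
    block = unname(model$block_map[model$columns[ord]])
  )
  top <- head(feats, top_n)
  blocks <- feats |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(
      fraction = .data$score / sum(.data$score),
      top_n_share = purrr::map_dbl(.data$block, ~ mean(top$block == .x))
    )
  structure(
    list(
      features = top, blocks = blocks, top_n = top_n,
      embedding_fraction = mean(top$block %in% embedding_blocks())
    ),
    class = "m6a_importance"
  )
}

#' @export
print.m6a_importance <- function(x, ...) {
  cat(sprintf(
    "<m6a_importance> top %d features (%.0f%% from graph embeddings)\n",
    x$top_n, 100 * x$embedding_fraction
  ))
  print(head(x$features, 10L))
  invisible(x)
}

#' Select sequence-feature blocks by aggregate importance
#'
#' Trains a preliminary model on all fused candidate blocks using an
#' internal stratified validation split of the training data, aggregates
#' importance per block, and keeps the `n_keep` highest-scoring blocks. An
#' explicit `override` list of block names wins over the automatic choice
#' (the per-dataset block lists of the published benchmarks are supplied
#' this way; see [preset_blocks()]).
#'
#' @param train A training sample-set tibble (labels are used).
#' @param candidate_blocks Named list of `m6a_features` blocks, rows aligned
#'   with `train`.
#' @param cfg A [train_config()] for the preliminary model.
#' @param n_keep Number of blocks to keep (clamped, with a warning).
#' @param override Optional character vector of block names to use verbatim.
#' @return Character vector of selected block names.
#' @export
select_feature_blocks <- function(train, candidate_blocks, cfg = train_config(),
                                  n_keep = 3L, override = NULL) {
  if (!is.null(override)) {
    unknown <- setdiff(override, names(candidate_blocks))
    if (length(unknown)) {
      abort(sprintf("unknown block(s) in override: %s", paste(unknown, collapse = ", ")))
    }
    return(override)
  }
  if (length(candidate_blocks) < 2L) abort("need at least 2 candidate blocks")
  if (n_keep > length(candidate_blocks)) {
    warn("n_keep exceeds the number of candidate blocks; keeping all")
    n_keep <- length(candidate_blocks)
  }
  fused <- fuse_features(candidate_blocks)
  # block-level map: sub-blocks (e.g. NPPS_xi1/NPPS_xi2) keep their list name
  bm <- attr(fused, "block_map")
  for (nm in names(candidate_blocks)) {
    bm[names(block_map(candidate_blocks[[nm]]))] <- nm
  }
  attr(fused, "block_map") <- bm
  halves <- split_dataset(train, train_fraction = 0.8, seed = cfg$seed, stratified = TRUE)
  fit_idx <- match(halves$train$id, fused$id)
  pre <- train_model(fused[fit_idx, ], halves$train$label, cfg)
  pre$block_map <- bm[pre$columns]
  imp <- feature_importance(pre, top_n = length(pre$columns))
  ranked <- imp$blocks$block[order(imp$blocks$score, decreasing = TRUE)]
  ranked[seq_len(n_keep)]
}

#' Save / load a trained model bundle
#'
#' Writes a directory with the backend model file, a JSON manifest (feature
#' columns, block map, configuration, class weights) and, when present, the
#' fitted encoder models (BPB / NPPS frequency tables) as JSON so new data
#' can be encoded at prediction time. `load_model()` restores a model whose
#' predictions are bit-identical to the original's.
#'
#' @param model A fitted `m6a_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_model()` the directory, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "m6a_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  manifest <- list(
    columns = model$columns, block_map = as.list(model$block_map),
    config = unclass(model$config), class_weights = as.list(model$class_weights),
    n_train = model$n_train,
    encoders = encoders_to_list(model$encoders),
    package_version = as.character(utils::packageVersion("m6ager"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cfg <- do.call(train_config, manifest$config)
  structure(
    list(
      booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
      columns = manifest$columns,
      block_map = unlist(manifest$block_map),
      config = cfg,
      class_weights = unlist(manifest$class_weights),
      encoders = encoders_from_list(manifest$encoders),
      n_train = manifest$n_train
    ),
    class = "m6a_model"
  )
}

encoders_to_list <- function(encoders) {
  if (is.null(encoders)) return(NULL)
  lapply(encoders, function(e) {
    if (inherits(e, c("bpb_model", "npps_model"))) {
      c(list(.class = class(e)[1L]), lapply(unclass(e), function(x) {
        if (is.matrix(x)) list(values = x, rownames = rownames(x)) else x
      }))
    } else e
  })
}

encoders_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  lapply(lst, function(e) {
    if (is.list(e) && !is.null(e$.class)) {
      cls <- e$.class
      e$.class <- NULL
      e <- lapply(e, function(x) {
        if (is.list(x) && !is.null(x$values)) {
          m <- as.matrix(x$values)
          rownames(m) <- x$rownames
          colnames(m) <- NULL
          m
        } else x
      })
      structure(e, class = cls)
    } else e
  })
}
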