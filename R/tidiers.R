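#' Tidy a metrics report
#'
#' @param x An `m6a_metrics` object.
#' @param ... Unused.
#' @return A long tibble with columns `metric` and `value` (percent metrics
#'   on the 0-100 scale).
#' @export
tidy.m6a_metrics <- function(x, ...) {
  tidyr::pivot_longer(
    metrics_row(x)[, c("acc", "mcc", "sen", "spe", "f1", "auc")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' Glance at a metrics report
#'
#' @inheritParams tidy.m6a_metrics
#' @return A one-row tibble: metrics plus confusion counts.
#' @export
glance.m6a_metrics <- function(x, ...) metrics_row(x)

#' Tidy a fitted classifier: per-feature importance
#'
#' @param x An `m6a_model`.
#' @param ... Unused.
#' @return A tibble with `feature`, `score`, `block`, ranked by score.
#' @export
tidy.m6a_model <- function(x, ...) {
  feature_importance(x, top_n = length(x$columns))$features
}

#' Glance at a fitted classifier
#'
#' @inheritParams tidy.m6a_model
#' @return A one-row tibble with backend, hyperparameters, feature and
#'   training-sample counts and the class weights.
#' @export
glance.m6a_model <- function(x, ...) {
  tibble(
    backend = x$config$backend, iterations = x$config$iterations,
    depth = x$config$depth, learning_rate = x$config$learning_rate,
    n_features = length(x$columns), n_train = x$n_train,
    weight_neg = unname(x$class_weights["0"]),
    weight_pos = unname(x$class_weights["1"])
  )
}

#' Tidy an importance report
#'
#' @param x An `m6a_importance`.
#' @param ... Unused.
#' @export
tidy.m6a_importance <- function(x, ...) x$features

#' Glance at a pipeline run
#'
#' @param x An `m6a_run`.
#' @param ... Unused.
#' @return The one-row metrics tibble of the held-out evaluation.
#' @export
glance.m6a_run <- function(x, ...) glance(x$metrics)

#' Tidy a pipeline run: per-sample held-out predictions
#'
#' @inheritParams glance.m6a_run
#' @export
tidy.m6a_run <- function(x, ...) {
  dplyr::left_join(x$predictions,
    dplyr::select(x$data, "id", truth = "label"),
    by = "id"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
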