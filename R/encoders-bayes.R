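positional_freq <- function(sm) {
  # 4 x L column-stochastic positional nucleotide frequencies
  f <- apply(sm, 2L, tabulate, nbins = 4L) / nrow(sm)
  rownames(f) <- RNA_BASES
  f
}

pair_positional_freq <- function(sm, k) {
  # 16 x (L - k - 1) frequencies of ordered pairs at (i, i + k + 1)
  L <- ncol(sm)
  i <- seq_len(L - k - 1L)
  code <- (sm[, i, drop = FALSE] - 1L) * 4L + sm[, i + k + 1L, drop = FALSE]
  f <- apply(code, 2L, tabulate, nbins = 16L) / nrow(sm)
  rownames(f) <- paste0(rep(RNA_BASES, each = 4L), rep(RNA_BASES, 4L))
  f
}

split_classes <- function(train) {
  train <- validate_sample_set(train, enforce_shape = FALSE)
  if (length(unique(train$label)) < 2L) {
    abort("training set must contain both classes (positive and negative frequency tables are required)")
  }
  list(
    pos = seq_matrix(train$sequence[train$label == 1L]),
    neg = seq_matrix(train$sequence[train$label == 0L]),
    L = nchar(train$sequence[[1L]])
  )
}

#' Fit a bi-profile Bayes (BPB) model
#'
#' Estimates, from the training data only, the positional nucleotide
#' frequency tables f+ (4 x L, positives) and f- (negatives): the frequency
#' of each nucleotide at each position within its class.
#'
#' @param train A sample-set tibble containing both classes.
#' @return An object of class `bpb_model` with elements `f_pos`, `f_neg`, `L`.
#' @export
fit_bpb <- function(train) {
  cl <- split_classes(train)
  structure(
    list(f_pos = positional_freq(cl$pos), f_neg = positional_freq(cl$neg), L = cl$L),
    class = "bpb_model"
  )
}

#' Bi-profile Bayes (BPB) encoding
#'
#' For each position i the observed nucleotide n contributes the pair
#' (f+(n, i), f-(n, i)) of its class-conditional positional frequencies,
#' interleaved along the sequence: 2L features.
#'
#' @inheritParams encode_ctd
#' @param model A fitted [fit_bpb()] model (trained at the same length L).
#' @return An `m6a_features` tibble with 2L `BPB_*` columns.
#' @export
encode_bpb <- function(data, model) {
  stopifnot(inherits(model, "bpb_model"))
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm)
  if (L != model$L) {
    abort(sprintf("sequence length %d does not match model length %d", L, model$L))
  }
  n <- nrow(sm)
  mat <- matrix(0, n, 2L * L)
  for (i in seq_len(L)) {
    mat[, 2L * i - 1L] <- model$f_pos[cbind(sm[, i], i)]
    mat[, 2L * i] <- model$f_neg[cbind(sm[, i], i)]
  }
  colnames(mat) <- paste0(
    "BPB_p", rep(seq_len(L), each = 2L), "_", rep(c("pos", "neg"), L)
  )
  new_feature_block(data$id, mat, "BPB")
}

#' Fit a nucleotide pair position specificity (NPPS) model
#'
#' Estimates, separately on the positive and negative training samples, the
#' positional single-nucleotide frequencies Fs (4 x L) and the k-spaced pair
#' frequencies Fd (16 x (L - k - 1)), where a k-spaced pair occupies
#' positions i and i + k + 1 with k intervening bases.
#'
#' @inheritParams fit_bpb
#' @param k Pair spacing (number of intervening nucleotides), default 1.
#' @return An object of class `npps_model` with the four frequency tables.
#' @export
fit_npps <- function(train, k = 1L) {
  cl <- split_classes(train)
  if (cl$L <= k + 1L) abort("sequence length must exceed k + 1")
  structure(
    list(
      k = as.integer(k), L = cl$L,
      Fs_pos = positional_freq(cl$pos), Fs_neg = positional_freq(cl$neg),
      Fd_pos = pair_positional_freq(cl$pos, k),
      Fd_neg = pair_positional_freq(cl$neg, k)
    ),
    class = "npps_model"
  )
}

#' Nucleotide pair position specificity (NPPS) encoding
#'
#' For each output position j = k+2 .. L, with (n1, n2) the nucleotides at
#' positions (j - k - 1, j), the class-conditional probability of n1 given
#' n2 is p(+/-) = Fd(n1 n2, j - k - 1) / Fs(n2, j), defined as 0 when the
#' denominator is 0; the feature is p+ - p-. L - k - 1 features in \[-1, 1\].
#'
#' @inheritParams encode_ctd
#' @param model A fitted [fit_npps()] model.
#' @return An `m6a_features` tibble with L - k - 1 `NPPS_xi*` columns; the
#'   column `NPPS_xi<k>_<i>` covers the pair at positions (i, i + k + 1).
#' @export
encode_npps <- function(data, model) {
  stopifnot(inherits(model, "npps_model"))
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm); k <- model$k
  if (L != model$L) {
    abort(sprintf("sequence length %d does not match model length %d", L, model$L))
  }
  i <- seq_len(L - k - 1L) # first pair position; second is j = i + k + 1
  pair <- (sm[, i, drop = FALSE] - 1L) * 4L + sm[, i + k + 1L, drop = FALSE]
  cond_p <- function(Fd, Fs) {
    num <- matrix(Fd[cbind(as.vector(pair), rep(i, each = nrow(sm)))], nrow = nrow(sm))
    den <- matrix(Fs[cbind(as.vector(sm[, i + k + 1L, drop = FALSE]),
      rep(i + k + 1L, each = nrow(sm)))], nrow = nrow(sm))
    out <- num / den
    out[den == 0] <- 0
    out
  }
  mat <- cond_p(model$Fd_pos, model$Fs_pos) - cond_p(model$Fd_neg, model$Fs_neg)
  colnames(mat) <- paste0("NPPS_xi", k, "_", i)
  new_feature_block(data$id, mat, paste0("NPPS_xi", k))
}
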