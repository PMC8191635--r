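#' Composition-Transition-Distribution (CTD) encoding
#'
#' Global sequence descriptors: 4 nucleotide composition fractions; 6
#' transition frequencies, one per unordered pair of distinct nucleotides,
#' counting adjacent occurrences in either order over the L-1 adjacent
#' positions; and 5 distribution descriptors per nucleotide — the relative
#' position (position / L) of its 1st, ceiling(0.25 n)-th, ceiling(0.5 n)-th,
#' ceiling(0.75 n)-th and n-th occurrence, 0 when the nucleotide is absent.
#' 30 features per sequence.
#'
#' @param data A sample-set tibble (see [validate_sample_set()]).
#' @return An `m6a_features` tibble: `id` plus 30 `CTD_*` columns.
#' @export
encode_ctd <- function(data) {
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm)
  n <- nrow(sm)
  comp <- t(apply(sm, 1L, tabulate, nbins = 4L)) / L
  colnames(comp) <- paste0("CTD_comp_", RNA_BASES)

  pairs <- utils::combn(4L, 2L) # 6 unordered distinct pairs
  a <- sm[, -L, drop = FALSE]
  b <- sm[, -1L, drop = FALSE]
  trans <- sapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    rowSums((a == i & b == j) | (a == j & b == i)) / (L - 1L)
  })
  trans <- matrix(trans, nrow = n)
  colnames(trans) <- paste0(
    "CTD_trans_", RNA_BASES[pairs[1L, ]], RNA_BASES[pairs[2L, ]]
  )

  qs <- c(0, 0.25, 0.5, 0.75, 1)
  dist <- matrix(0, n, 20L)
  for (s in seq_len(n)) {
    for (nt in 1:4) {
      occ <- which(sm[s, ] == nt)
      if (length(occ)) {
        k <- pmax(1L, ceiling(qs * length(occ)))
        dist[s, (nt - 1L) * 5L + 1:5] <- occ[k] / L
      }
    }
  }
  colnames(dist) <- paste0(
    "CTD_dist_", rep(RNA_BASES, each = 5L), "_q", rep(c(0, 25, 50, 75, 100), 4L)
  )
  new_feature_block(data$id, cbind(comp, trans, dist), "CTD")
}

#' Electron-ion interaction pseudopotential (EIIP) encoding
#'
#' Replaces each nucleotide by its EIIP constant: A = 0.1260, C = 0.0806,
#' G = 0.1335, U = 0.1340 (the published value for T, which U replaces).
#' L features per sequence.
#'
#' @inheritParams encode_ctd
#' @return An `m6a_features` tibble with L `EIIP_p*` columns.
#' @export
encode_eiip <- function(data) {
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  eiip <- c(A = 0.1260, C = 0.0806, G = 0.1335, U = 0.1340)
  mat <- matrix(eiip[RNA_BASES][sm], nrow = nrow(sm))
  colnames(mat) <- paste0("EIIP_p", seq_len(ncol(sm)))
  new_feature_block(data$id, mat, "EIIP")
}

#' Nucleotide chemical property and density (NCP-ND) encoding
#'
#' Each position contributes the three chemical-property bits of its
#' nucleotide — ring structure, hydrogen bonding, functional group, with
#' A = (1,1,1), U = (0,1,0), C = (0,0,1), G = (1,0,0) — followed by the
#' cumulative nucleotide density, the count of that nucleotide among
#' positions 1..i divided by i. 4L features, position-major.
#'
#' @inheritParams encode_ctd
#' @return An `m6a_features` tibble with 4L `NCP_ND_p*` columns.
#' @export
encode_ncp_nd <- function(data) {
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm); n <- nrow(sm)
  ncp <- rbind(A = c(1, 1, 1), C = c(0, 0, 1), G = c(1, 0, 0), U = c(0, 1, 0))
  mat <- matrix(0, n, 4L * L)
  dens <- matrix(0, n, L)
  for (nt in 1:4) {
    hit <- sm == nt
    cum <- t(apply(hit, 1L, cumsum)) / rep(seq_len(L), each = 1L)[col(hit)]
    dens[hit] <- cum[hit]
  }
  for (i in seq_len(L)) {
    mat[, (i - 1L) * 4L + 1:3] <- ncp[RNA_BASES[sm[, i]], , drop = FALSE]
    mat[, (i - 1L) * 4L + 4L] <- dens[, i]
  }
  colnames(mat) <- paste0(
    "NCP_ND_p", rep(seq_len(L), each = 4L), "_",
    rep(c("ring", "hbond", "func", "dens"), L)
  )
  new_feature_block(data$id, mat, "NCP_ND")
}

#' Nucleotide pair spectrum (NPS) encoding
#'
#' Frequencies of k-spaced ordered nucleotide pairs n1{k}n2 (k arbitrary
#' nucleotides between n1 and n2, i.e. positions i and i+k+1), for k = 1 to
#' `d_max`, each count divided by L-k-1. With the default `d_max = 3` the
#' encoding has 4 x 4 x 3 = 48 features.
#'
#' @inheritParams encode_ctd
#' @param d_max Maximum spacing (default 3).
#' @return An `m6a_features` tibble with 16 * d_max `NPS_k*` columns.
#' @export
encode_nps <- function(data, d_max = 3L) {
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm); n <- nrow(sm)
  stopifnot(d_max >= 1L)
  if (L < d_max + 2L) abort("sequence too short for requested d_max")
  blocks <- lapply(seq_len(d_max), function(k) {
    i <- seq_len(L - k - 1L)
    a <- sm[, i, drop = FALSE]
    b <- sm[, i + k + 1L, drop = FALSE]
    code <- (a - 1L) * 4L + b # 1..16 ordered pair index
    cnt <- t(apply(code, 1L, tabulate, nbins = 16L)) / (L - k - 1L)
    colnames(cnt) <- paste0(
      "NPS_k", k, "_", rep(RNA_BASES, each = 4L), rep(RNA_BASES, 4L)
    )
    cnt
  })
  new_feature_block(data$id, do.call(cbind, blocks), "NPS")
}

#' Fuse feature blocks by horizontal concatenation
#'
#' Column-wise concatenation of encoder and embedding outputs into one
#' design matrix. All blocks must carry the same samples in the same order;
#' column labels keep their block prefixes so any feature traces back to its
#' encoder.
#'
#' @param ... `m6a_features` tibbles, or a single list of them.
#' @return One fused `m6a_features` tibble.
#' @export
fuse_features <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "m6a_features")) {
    blocks <- blocks[[1L]]
  }
  stopifnot(length(blocks) >= 1L)
  ids <- blocks[[1L]]$id
  for (b in blocks) {
    if (!identical(b$id, ids)) abort("feature blocks carry different samples or row orders")
  }
  if (length(blocks) == 1L) return(blocks[[1L]])
  mats <- lapply(blocks, feature_matrix)
  maps <- unlist(lapply(blocks, block_map))
  cols <- unlist(lapply(mats, colnames))
  if (anyDuplicated(cols)) {
    abort(sprintf("duplicate feature labels across blocks: %s",
      paste(head(cols[duplicated(cols)], 3), collapse = ", ")))
  }
  out <- new_feature_block(ids, do.call(cbind, mats), "fused")
  attr(out, "block_map") <- setNames(unname(maps), cols)
  out
}
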