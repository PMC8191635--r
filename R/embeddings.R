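modularity_matrix <- function(A, normalizer = c("edges", "nodes")) {
  normalizer <- match.arg(normalizer)
  A <- as.matrix(A)
  deg <- rowSums(A)
  denom <- switch(normalizer,
    edges = sum(deg), # 2 |E|
    nodes = nrow(A) # literal node-count variant
  )
  A - tcrossprod(deg) / denom
}

#' Modularity-spectrum (SocDim) node embedding
#'
#' Builds the modularity matrix B = A - d d' / 2|E| of the sample graph and
#' embeds each node by the eigenvectors of the d largest eigenvalues of B
#' (each scaled to unit norm). These "social dimensions" capture soft
#' community structure of the similarity network. With the edge-count
#' normalizer every row of B sums to zero; a literal node-count variant is
#' available via `normalizer = "nodes"`.
#'
#' @param graph A built `m6a_graph` (see [build_graph()]); must be connected.
#' @param d Embedding width (number of top eigenvectors), d < m.
#' @param normalizer `"edges"` (standard, default) or `"nodes"`.
#' @return An `m6a_features` tibble with columns `SocDim_1..d`.
#' @export
socdim_embed <- function(graph, d = 16L, normalizer = "edges") {
  stopifnot(inherits(graph, "m6a_graph"), !is.null(graph$adjacency))
  m <- length(graph$node_ids)
  if (d >= m) abort("embedding width d must be smaller than the number of nodes")
  A <- graph$adjacency
  deg <- Matrix::rowSums(A)
  two_e <- if (normalizer == "edges") sum(deg) else m
  if (m <= 400L) {
    e <- eigen(modularity_matrix(A, normalizer), symmetric = TRUE)
    vec <- e$vectors[, seq_len(d), drop = FALSE]
    val <- e$values[seq_len(d)]
  } else {
    matvec <- function(x, args = NULL) as.numeric(A %*% x) - deg * sum(deg * x) / two_e
    e <- RSpectra::eigs_sym(matvec, k = d, n = m, which = "LA",
      opts = list(tol = 1e-12, maxitr = 5000L))
    ord <- order(e$values, decreasing = TRUE)
    vec <- e$vectors[, ord, drop = FALSE]
    val <- e$values[ord]
  }
  vec <- apply(vec, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v # reproducible sign
  })
  colnames(vec) <- paste0("SocDim_", seq_len(d))
  fb <- new_feature_block(graph$node_ids, vec, "SocDim")
  attr(fb, "eigenvalues") <- val
  fb
}

#' Node2Vec biased-random-walk embedding
#'
#' Simulates second-order random walks whose transitions are biased by the
#' return parameter p and in-out parameter q (at p = q = 1 the walk reduces
#' to a uniform first-order walk), then learns node vectors with a skip-gram
#' model trained by stochastic gradient descent with negative sampling on the
#' walk corpus. Fully seeded and single-threaded, so reruns are identical.
#'
#' @inheritParams socdim_embed
#' @param d Embedding width.
#' @param p,q Return / in-out bias parameters (> 0).
#' @param walk_length,walks_per_node Walk corpus size controls.
#' @param window Skip-gram context window.
#' @param epochs Passes of SGD over the corpus. The walk corpus already
#'   visits every node `walks_per_node * walk_length / m`-fold, so a single
#'   pass (the reference node2vec default) suffices.
#' @param negative Negative samples per positive pair.
#' @param seed Integer seed for walks and SGD.
#' @return An `m6a_features` tibble with columns `N2V_1..d`.
#' @export
node2vec_embed <- function(graph, d = 16L, p = 1, q = 1, walk_length = 30L,
                           walks_per_node = 20L, window = 5L, epochs = 1L,
                           negative = 5L, seed = 1L) {
  stopifnot(inherits(graph, "m6a_graph"), !is.null(graph$adjacency))
  if (walk_length < 2L) abort("walk_length must be at least 2")
  stopifnot(p > 0, q > 0, d >= 1L, window >= 1L, epochs >= 1L)
  walks <- node2vec_walks(graph, p, q, walk_length, walks_per_node, seed)
  m <- length(graph$node_ids)
  emb <- sgns_train_cpp(
    walks - 1L, m, as.integer(d), as.integer(window), as.integer(negative),
    as.integer(epochs), 0.025, as.integer(seed) + 1L
  )
  colnames(emb) <- paste0("N2V_", seq_len(d))
  new_feature_block(graph$node_ids, emb, "N2V")
}

#' Generate the biased walk corpus used by [node2vec_embed()]
#'
#' @inheritParams node2vec_embed
#' @return An integer matrix, one walk per row, entries are 1-based node
#'   indices in graph node order.
#' @export
node2vec_walks <- function(graph, p = 1, q = 1, walk_length = 30L,
                           walks_per_node = 20L, seed = 1L) {
  stopifnot(inherits(graph, "m6a_graph"), !is.null(graph$adjacency))
  adj <- lapply(igraph::adjacent_vertices(
    graph$graph, igraph::V(graph$graph)
  ), function(v) sort(as.integer(v)))
  nb_flat <- unlist(adj, use.names = FALSE) - 1L
  nb_ptr <- c(0L, cumsum(lengths(adj)))
  node2vec_walks_cpp(
    nb_flat, nb_ptr, as.numeric(p), as.numeric(q),
    as.integer(walk_length), as.integer(walks_per_node), as.integer(seed)
  ) + 1L
}

#' GraRep k-step transition-factorization embedding
#'
#' From the row-normalized transition matrix S of the sample graph, each
#' step k = 1..k_max yields a positive log-probability matrix
#' max(log(S^k_ij / mean_i(S^k_ij)), 0) which is factorized by truncated SVD
#' to d dimensions (embedding = U sqrt(Sigma)); the k-step representations
#' are concatenated. Captures increasingly global neighborhood structure
#' with growing k.
#'
#' @inheritParams socdim_embed
#' @param d Embedding width per step.
#' @param k_max Number of transition steps.
#' @param seed Seed for the truncated SVD initialization.
#' @return An `m6a_features` tibble with columns `GraRep_k<k>_<i>`,
#'   k_max * d columns in total.
#' @export
grarep_embed <- function(graph, d = 16L, k_max = 2L, seed = 1L) {
  stopifnot(inherits(graph, "m6a_graph"), !is.null(graph$adjacency))
  m <- length(graph$node_ids)
  stopifnot(k_max >= 1L, d >= 1L)
  if (k_max * d >= m) abort("k_max * d must be smaller than the number of nodes")
  A <- graph$adjacency
  S <- A / Matrix::rowSums(A) # row-stochastic transition matrix
  Ak <- S
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k > 1L) Ak <- Ak %*% S
    X <- grarep_log_matrix(Ak)
    sv <- withr::with_seed(seed + k, {
      if (d < min(dim(X)) / 3) {
        irlba::irlba(X, nv = d)
      } else {
        s <- svd(as.matrix(X), nu = d, nv = d)
        list(u = s$u, d = s$d[seq_len(d)], v = s$v)
      }
    })
    emb <- sv$u %*% diag(sqrt(sv$d), d, d)
    emb <- apply(emb, 2L, function(v) if (v[which.max(abs(v))] < 0) -v else v)
    colnames(emb) <- paste0("GraRep_k", k, "_", seq_len(d))
    out[[k]] <- emb
  }
  new_feature_block(graph$node_ids, do.call(cbind, out), "GraRep")
}

grarep_log_matrix <- function(Ak) {
  Ak <- methods::as(methods::as(Ak, "generalMatrix"), "CsparseMatrix")
  cm <- Matrix::colMeans(Ak)
  j <- rep(seq_len(ncol(Ak)), diff(Ak@p))
  X <- Ak
  X@x <- pmax(log(Ak@x / cm[j]), 0) # unstored zeros map to 0 as well
  Matrix::drop0(X)
}
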