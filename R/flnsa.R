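#' Learn a sample-similarity matrix by linear neighborhood reconstruction
#'
#' The fast linear neighborhood similarity approach (FLNSA) quantifies the
#' similarity w_ij of sample j to sample i by how much j contributes to the
#' best nonnegative linear reconstruction of i from its c nearest neighbors
#' (Euclidean distance on min-max rescaled features). W minimizes
#' 0.5 * ||X - (C . W) X||_F^2 + 0.5 * mu * ||(C . W) e - e||^2 subject to
#' W >= 0 and support C (the neighbor indicator), via the multiplicative
#' update W_ij <- W_ij (X X' + mu e e')_ij / ((C.W) X X' + mu (C.W) e e')_ij,
#' which keeps the objective non-increasing. Rows of C . W are renormalized
#' to sum to exactly 1 at exit.
#'
#' @param X An `m6a_features` tibble (or numeric matrix with rownames) of
#'   fused sequence features, m samples x n features, finite values.
#' @param c Neighbor count, 0 < c < m.
#' @param mu Regularization coefficient for the row-stochasticity penalty.
#' @param max_iter Iteration cap for the multiplicative updates.
#' @param tol Stop when the objective decreases by less than `tol`.
#' @param seed Seed for the random nonnegative initialization of W.
#' @param rescale Min-max rescale each feature column to \[0,1\] first
#'   (required for the multiplicative update to preserve nonnegativity when
#'   features, e.g. NPPS, can be negative). Default `TRUE`.
#' @return An object of class `m6a_graph` with the sparse weight matrix `W`
#'   (rows indexed like `node_ids`), the neighbor index matrix `neighbors`
#'   (m x c), the objective trace, and (until [build_graph()] is applied)
#'   no adjacency.
#' @export
flnsa_similarity <- function(X, c = 10L, mu = 1, max_iter = 200L, tol = 1e-6,
                             seed = 1L, rescale = TRUE) {
  ids <- if (inherits(X, "m6a_features")) X$id else rownames(X)
  Xm <- if (inherits(X, "m6a_features")) feature_matrix(X) else as.matrix(X)
  m <- nrow(Xm)
  ids <- ids %||% as.character(seq_len(m))
  if (any(!is.finite(Xm))) abort("FLNSA input contains non-finite values")
  if (m < 3L) abort("FLNSA needs at least 3 samples")
  c <- as.integer(c)
  if (c <= 0L || c >= m) abort(sprintf("neighbor count c must satisfy 0 < c < m (= %d)", m))
  stopifnot(mu > 0, tol >= 0)
  if (rescale) Xm <- minmax_rescale(Xm)

  nb <- knn_indices(Xm, c) # m x c, ties broken by lowest index
  G <- tcrossprod(Xm) # X X', nonnegative after rescaling

  W <- withr::with_seed(seed, matrix(runif(m * c, 0.1, 1), m, c))
  rows <- rep(seq_len(m), c)
  sparseW <- function(W) {
    Matrix::sparseMatrix(
      i = rows, j = as.vector(nb), x = as.vector(W), dims = c(m, m)
    )
  }
  Gnb <- matrix(G[cbind(rows, as.vector(nb))], m, c) # G[i, nb[i,j]]
  objective <- function(S) {
    R <- Xm - as.matrix(S %*% Xm)
    0.5 * sum(R^2) + 0.5 * mu * sum((Matrix::rowSums(S) - 1)^2)
  }

  obj <- rep(NA_real_, max_iter + 1L)
  S <- sparseW(W)
  obj[1L] <- objective(S)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    SG <- as.matrix(S %*% G)
    rs <- Matrix::rowSums(S)
    num <- W * (Gnb + mu)
    den <- matrix(SG[cbind(rows, as.vector(nb))], m, c) + mu * rs
    W <- num / pmax(den, .Machine$double.eps)
    S <- sparseW(W)
    obj[it + 1L] <- objective(S)
    if (obj[it] - obj[it + 1L] < tol) break
  }
  # enforce the row-stochastic constraint exactly at exit
  rs <- Matrix::rowSums(sparseW(W))
  W <- W / pmax(rs, .Machine$double.eps)

  structure(
    list(
      W = sparseW(W), neighbors = nb, node_ids = ids,
      params = list(c = c, mu = mu, max_iter = max_iter, tol = tol, seed = seed),
      objective = obj[!is.na(obj)], iterations = it, adjacency = NULL
    ),
    class = "m6a_graph"
  )
}

minmax_rescale <- function(Xm) {
  lo <- apply(Xm, 2L, min)
  hi <- apply(Xm, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(Xm, 2L, lo), 2L, rng, "/")
}

knn_indices <- function(Xm, c) {
  m <- nrow(Xm)
  sq <- rowSums(Xm^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Xm)
  diag(D2) <- Inf # self excluded
  t(apply(D2, 1L, function(d) order(d)[seq_len(c)])) # order() ties -> lowest index
}

#' Derive the unweighted sample graph from a learned similarity matrix
#'
#' Symmetrizes the FLNSA weight matrix by the elementwise maximum of W and
#' W', zeroes the diagonal, removes edges with weight below the threshold
#' `t`, and sets surviving edge weights to 1. The embeddings downstream
#' require a connected graph: if the result is disconnected the neighbor
#' count is escalated (c <- min(2c, m - 1)), FLNSA is re-run, and the
#' construction retried, a bounded number of times.
#'
#' @param sim An `m6a_graph` from [flnsa_similarity()].
#' @param X The feature input used to learn `sim` (needed if the neighbor
#'   count has to be escalated).
#' @param t Edge-weight cutoff; edges with weight < t are removed. Default:
#'   the median of the positive symmetrized weights.
#' @param max_escalations Maximum number of neighbor-count escalations.
#' @return The `m6a_graph` with a symmetric, zero-diagonal, binary, connected
#'   `adjacency` (a sparse matrix) and the `igraph` object in `$graph`.
#' @export
build_graph <- function(sim, X = NULL, t = NULL, max_escalations = 5L) {
  stopifnot(inherits(sim, "m6a_graph"))
  m <- length(sim$node_ids)
  for (esc in 0:max_escalations) {
    Wsym <- pmax_sparse(sim$W, Matrix::t(sim$W))
    Matrix::diag(Wsym) <- 0
    Wsym <- Matrix::drop0(Wsym)
    tt <- t %||% median(Wsym@x)
    A <- Wsym
    A@x <- as.numeric(A@x >= tt)
    A <- Matrix::drop0(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) {
      sim$adjacency <- methods::as(A, "CsparseMatrix")
      sim$graph <- g
      sim$threshold <- tt
      return(sim)
    }
    c_now <- sim$params$c
    if (c_now >= m - 1L) {
      abort(if (tt <= 0) {
        "graph disconnected at c = m - 1 and t = 0; this should be impossible"
      } else {
        sprintf("graph still disconnected at c = m - 1; lower the threshold t (currently %.3g)", tt)
      })
    }
    if (is.null(X)) abort("graph is disconnected; supply X so the neighbor count can be escalated")
    p <- sim$params
    sim <- flnsa_similarity(X,
      c = min(2L * c_now, m - 1L), mu = p$mu,
      max_iter = p$max_iter, tol = p$tol, seed = p$seed
    )
  }
  abort("graph still disconnected after the maximum number of neighbor-count escalations; lower t or raise c")
}

pmax_sparse <- function(A, B) {
  # elementwise max of two nonnegative sparse matrices
  D <- A - B
  D@x <- pmax(D@x, 0)
  B + D
}

#' Build an `m6a_graph` from a given adjacency matrix
#'
#' Wraps an existing undirected, unweighted graph in the container the
#' embedding functions consume, bypassing similarity learning. Mostly useful
#' for experimenting with the embeddings on known graph topologies.
#'
#' @param A Symmetric binary adjacency matrix (dense or sparse), zero
#'   diagonal.
#' @param node_ids Optional node identifiers (defaults to row numbers).
#' @return A built `m6a_graph`.
#' @export
graph_from_adjacency <- function(A, node_ids = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (!Matrix::isSymmetric(A)) abort("adjacency must be symmetric")
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  A@x <- rep(1, length(A@x))
  m <- nrow(A)
  structure(
    list(
      W = A, neighbors = NULL, node_ids = node_ids %||% as.character(seq_len(m)),
      params = list(c = NA_integer_), objective = numeric(), iterations = 0L,
      adjacency = A,
      graph = igraph::graph_from_adjacency_matrix(A, mode = "undirected"),
      threshold = 0
    ),
    class = "m6a_graph"
  )
}

#' @export
print.m6a_graph <- function(x, ...) {
  cat(sprintf(
    "<m6a_graph> %d nodes, c = %d%s\n", length(x$node_ids), x$params$c,
    if (is.null(x$adjacency)) " (similarity only; run build_graph())"
    else sprintf(", %d edges (t = %.4g)", sum(x$adjacency) / 2, x$threshold)
  ))
  invisible(x)
}

#' Write a graph as an edge list
#'
#' Two tab-separated id columns, one row per undirected edge, plus a node
#' order file so downstream consumers can restore the sample order.
#'
#' @param sim A built `m6a_graph`.
#' @param edge_path,node_path Output paths.
#' @export
write_edge_list <- function(sim, edge_path, node_path = NULL) {
  stopifnot(inherits(sim, "m6a_graph"), !is.null(sim$adjacency))
  el <- igraph::as_edgelist(sim$graph, names = FALSE)
  df <- data.frame(
    from = sim$node_ids[el[, 1L]], to = sim$node_ids[el[, 2L]]
  )
  utils::write.table(df, edge_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  if (!is.null(node_path)) writeLines(sim$node_ids, node_path)
  invisible(edge_path)
}
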