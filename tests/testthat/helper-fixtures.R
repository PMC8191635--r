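# Small in-code fixtures shared across tests.

samples_from <- function(sequences, labels = NULL, validate = TRUE) {
  d <- tibble::tibble(
    id = sprintf("s%02d", seq_along(sequences)),
    label = labels %||% rep(c(1L, 0L), length.out = length(sequences)),
    sequence = sequences
  )
  if (validate) suppressWarnings(m6ager::validate_sample_set(d)) else d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_samples <- function(n, L, seed = 1L, labels = NULL) {
  withr::with_seed(seed, {
    center <- (L + 1L) %/% 2L
    seqs <- vapply(seq_len(n), function(i) {
      x <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      x[center] <- "A"
      paste0(x, collapse = "")
    }, character(1))
    samples_from(seqs, labels)
  })
}

# barbell: two k-cliques joined by a single bridge edge
barbell_adjacency <- function(k = 4L) {
  m <- 2L * k
  A <- matrix(0, m, m)
  A[1:k, 1:k] <- 1
  A[(k + 1):m, (k + 1):m] <- 1
  diag(A) <- 0
  A[k, k + 1L] <- A[k + 1L, k] <- 1
  A
}

star_adjacency <- function(leaves = 8L) {
  m <- leaves + 1L
  A <- matrix(0, m, m)
  A[1, 2:m] <- A[2:m, 1] <- 1
  A
}

# independent projected-gradient solver for the linear-neighborhood
# objective J(W) = 0.5||X - (C.W)X||_F^2 + 0.5*mu*||(C.W)e - e||^2,
# W >= 0 with support restricted to the neighbor sets
flnsa_oracle <- function(Xm, neighbors, mu) {
  m <- nrow(Xm)
  cc <- ncol(neighbors)
  rows <- rep(seq_len(m), cc)
  cols <- as.vector(neighbors)
  to_S <- function(w) {
    Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(m, m))
  }
  obj <- function(w) {
    S <- to_S(w)
    R <- Xm - as.matrix(S %*% Xm)
    0.5 * sum(R^2) + 0.5 * mu * sum((Matrix::rowSums(S) - 1)^2)
  }
  grad <- function(w) {
    S <- to_S(w)
    Gfull <- -(Xm - as.matrix(S %*% Xm)) %*% t(Xm) +
      mu * tcrossprod(Matrix::rowSums(S) - 1, rep(1, m))
    Gfull[cbind(rows, cols)]
  }
  fit <- stats::optim(rep(1 / cc, m * cc), obj, grad,
    method = "L-BFGS-B", lower = 0,
    control = list(maxit = 2000L, factr = 1e4)
  )
  list(objective = fit$value, w = fit$par)
}

flnsa_objective <- function(Xm, sim, mu) {
  R <- Xm - as.matrix(sim$W %*% Xm)
  0.5 * sum(R^2) + 0.5 * mu * sum((Matrix::rowSums(sim$W) - 1)^2)
}
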