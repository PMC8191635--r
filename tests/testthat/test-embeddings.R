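test_that("modularity matrix rows sum to zero with the edge-count normalizer", {
  g <- graph_from_adjacency(barbell_adjacency(4))
  B <- m6ager:::modularity_matrix(g$adjacency, "edges")
  expect_equal(rowSums(B), rep(0, 8), ignore_attr = TRUE, tolerance = 1e-12)
  # independent construction of the same matrix
  B_ref <- igraph::modularity_matrix(g$graph)
  expect_equal(B, as.matrix(B_ref), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the leading modularity eigenvector splits the barbell cliques", {
  g <- graph_from_adjacency(barbell_adjacency(4))
  emb <- socdim_embed(g, d = 1)
  s <- sign(emb$SocDim_1)
  expect_true(all(s[1:4] == s[1]))
  expect_true(all(s[5:8] == s[5]))
  expect_true(s[1] != s[5])
})

test_that("SocDim returns d unit-norm eigenpairs with small residuals", {
  g <- graph_from_adjacency(barbell_adjacency(5))
  d <- 3L
  emb <- socdim_embed(g, d = d)
  V <- as.matrix(emb[, -1])
  expect_equal(dim(V), c(10L, d))
  expect_equal(colSums(V^2), rep(1, d), ignore_attr = TRUE, tolerance = 1e-9)
  B <- m6ager:::modularity_matrix(g$adjacency, "edges")
  lam <- attr(emb, "eigenvalues")
  for (j in seq_len(d)) {
    expect_lt(sqrt(sum((B %*% V[, j] - lam[j] * V[, j])^2)), 1e-6)
  }
  expect_error(socdim_embed(g, d = 10), "smaller")
})

test_that("SocDim embeddings are equivariant under node relabeling (up to sign)", {
  A <- barbell_adjacency(4)
  perm <- withr::with_seed(71, sample(8))
  g1 <- socdim_embed(graph_from_adjacency(A), d = 2)
  g2 <- socdim_embed(graph_from_adjacency(A[perm, perm]), d = 2)
  M1 <- as.matrix(g1[, -1])[perm, ]
  M2 <- as.matrix(g2[, -1])
  for (j in 1:2) {
    expect_true(max(abs(M1[, j] - M2[, j])) < 1e-6 ||
      max(abs(M1[, j] + M2[, j])) < 1e-6)
  }
})

test_that("walks only traverse edges of the graph and are seed-reproducible", {
  g <- graph_from_adjacency(barbell_adjacency(4))
  A <- as.matrix(g$adjacency)
  w <- node2vec_walks(g, p = 0.5, q = 2, walk_length = 10, walks_per_node = 5, seed = 3)
  for (r in seq_len(nrow(w))) {
    steps <- cbind(w[r, -ncol(w)], w[r, -1])
    expect_true(all(A[steps] == 1))
  }
  w2 <- node2vec_walks(g, p = 0.5, q = 2, walk_length = 10, walks_per_node = 5, seed = 3)
  expect_identical(w, w2)
  w3 <- node2vec_walks(g, p = 0.5, q = 2, walk_length = 10, walks_per_node = 5, seed = 4)
  expect_false(identical(w, w3))
})

test_that("at p = q = 1 next hops from a star center are uniform over leaves", {
  leaves <- 8L
  g <- graph_from_adjacency(star_adjacency(leaves))
  w <- node2vec_walks(g, p = 1, q = 1, walk_length = 41, walks_per_node = 60, seed = 5)
  from_center <- w[, -ncol(w)] == 1L
  nxt <- w[, -1][from_center]
  n <- length(nxt)
  expect_gte(n, 10000)
  counts <- table(factor(nxt, levels = 2:(leaves + 1)))
  p0 <- 1 / leaves
  tol <- 3 * sqrt(n * p0 * (1 - p0))
  expect_true(all(abs(counts - n * p0) <= tol))
})

test_that("node2vec returns a finite, seeded m x d block in node order", {
  g <- graph_from_adjacency(barbell_adjacency(5), node_ids = sprintf("n%02d", 1:10))
  e1 <- node2vec_embed(g, d = 8, seed = 7)
  e2 <- node2vec_embed(g, d = 8, seed = 7)
  expect_identical(e1, e2)
  expect_equal(e1$id, sprintf("n%02d", 1:10))
  expect_equal(ncol(e1) - 1L, 8L)
  expect_true(all(is.finite(as.matrix(e1[, -1]))))
  expect_error(node2vec_embed(g, walk_length = 1), "walk_length")
})

test_that("GraRep separates two cliques and concatenates k-step blocks", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1
  A[6:10, 6:10] <- 1
  diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1
  g <- graph_from_adjacency(A)
  emb <- grarep_embed(g, d = 2, k_max = 2, seed = 9)
  expect_equal(ncol(emb) - 1L, 4L)
  M <- as.matrix(emb[, -1])
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pairs <- t(utils::combn(10, 2))
  cs <- apply(pairs, 1, function(pr) cosine(M[pr[1], ], M[pr[2], ]))
  within <- (pairs[, 1] <= 5 & pairs[, 2] <= 5) | (pairs[, 1] > 5 & pairs[, 2] > 5)
  expect_gt(mean(cs[within]), mean(cs[!within]))
})

test_that("GraRep transition rows sum to one", {
  g <- graph_from_adjacency(barbell_adjacency(4))
  S <- g$adjacency / Matrix::rowSums(g$adjacency)
  expect_equal(Matrix::rowSums(S), rep(1, 8), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("embedding row order matches graph node order for all methods", {
  d <- random_samples(30, 21, seed = 73)
  fb <- encode_ctd(d)
  g <- build_graph(flnsa_similarity(fb, c = 5, seed = 19), X = fb)
  expect_equal(g$node_ids, d$id)
  expect_equal(socdim_embed(g, d = 4)$id, d$id)
  expect_equal(node2vec_embed(g, d = 4, seed = 1)$id, d$id)
  expect_equal(grarep_embed(g, d = 4, k_max = 2, seed = 1)$id, d$id)
})
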