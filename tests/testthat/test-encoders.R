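# Hand-derived worked examples use short artificial sequences; the encoders
# accept any uniform length, so toy inputs below are built without the
# segment-shape validation applied to real datasets.

short <- function(seqs, labels = NULL) {
  samples_from(seqs, labels, validate = FALSE)
}

test_that("CTD worked examples match hand evaluation", {
  fb <- short("AAAA")
  x <- encode_ctd(fb)
  expect_equal(unlist(x[1, paste0("CTD_comp_", c("A", "C", "G", "U"))],
    use.names = FALSE), c(1, 0, 0, 0))
  expect_true(all(x[1, grepl("CTD_trans", names(x))] == 0))
  expect_equal(unlist(x[1, paste0("CTD_dist_A_q", c(0, 25, 50, 75, 100))],
    use.names = FALSE), c(0.25, 0.25, 0.5, 0.75, 1))
  expect_true(all(x[1, grepl("CTD_dist_[CGU]", names(x))] == 0))

  y <- encode_ctd(short("ACAC"))
  expect_equal(y$CTD_trans_AC, 1)
  expect_true(all(y[1, setdiff(grep("CTD_trans", names(y), value = TRUE),
    "CTD_trans_AC")] == 0))
})

test_that("CTD composition fractions sum to 1 on random sequences", {
  d <- random_samples(50, 21, seed = 9)
  x <- encode_ctd(d)
  expect_equal(rowSums(x[, grepl("CTD_comp", names(x))]), rep(1, 50),
    ignore_attr = TRUE)
})

test_that("EIIP maps nucleotides to the published constants", {
  x <- encode_eiip(short("ACGUA"))
  expect_equal(unlist(x[1, -1], use.names = FALSE),
    c(0.1260, 0.0806, 0.1335, 0.1340, 0.1260))
  y <- encode_eiip(short("AAAA"))
  expect_true(all(y[1, -1] == 0.1260))
  for (L in c(21L, 41L)) {
    expect_equal(ncol(encode_eiip(random_samples(3, L))) - 1L, L)
  }
})

test_that("NCP-ND encodes chemical bits and cumulative densities", {
  x <- encode_ncp_nd(short("AU"))
  expect_equal(unlist(x[1, paste0("NCP_ND_p1_", c("ring", "hbond", "func"))],
    use.names = FALSE), c(1, 1, 1)) # A
  expect_equal(unlist(x[1, paste0("NCP_ND_p2_", c("ring", "hbond", "func"))],
    use.names = FALSE), c(0, 1, 0)) # U
  expect_equal(x$NCP_ND_p2_dens, 0.5) # one U among the first two positions
  y <- encode_ncp_nd(short("AAAA"))
  expect_true(all(y[1, grepl("dens", names(y))] == 1))
})

test_that("NPS counts k-spaced pairs with the stated dimension", {
  d <- random_samples(5, 21, seed = 1)
  x <- encode_nps(d, d_max = 3)
  expect_equal(ncol(x) - 1L, 48L)
  # per-k frequencies partition the L - k - 1 pair positions
  for (k in 1:3) {
    expect_equal(
      rowSums(x[, grepl(paste0("NPS_k", k, "_"), names(x))]),
      rep(1, 5), ignore_attr = TRUE
    )
  }
  y <- encode_nps(short("AAAAAA"), d_max = 1)
  expect_equal(y$NPS_k1_AA, 1)
  expect_true(all(y[1, setdiff(names(y)[-1], "NPS_k1_AA")] == 0))
})

test_that("PseKNC components sum to 1 and reduce to k-mer frequencies at lambda 0", {
  d <- random_samples(20, 21, seed = 4)
  for (lam in c(0L, 2L, 5L)) {
    x <- encode_pseknc(d, k = 3, lambda = lam, w = 0.1)
    expect_equal(ncol(x) - 1L, 64L + lam)
    expect_equal(rowSums(x[, -1]), rep(1, 20), ignore_attr = TRUE)
  }
  x0 <- encode_pseknc(d, k = 2, lambda = 0)
  # with lambda = 0 the vector is exactly the normalized k-mer frequencies
  counts <- t(sapply(d$sequence, function(s) {
    kmers <- substring(s, 1:20, 2:21)
    tab <- table(factor(kmers, levels = sub("PseKNC_", "", names(x0)[-1])))
    as.numeric(tab) / 20
  }))
  expect_equal(as.matrix(x0[, -1]), counts, ignore_attr = TRUE)
})

test_that("PseKNC correlation tiers vanish on homopolymers", {
  x <- encode_pseknc(short(strrep("A", 15)), k = 2, lambda = 3)
  expect_true(all(x[1, paste0("PseKNC_theta", 1:3)] == 0))
})

test_that("PseKNC rejects lambda >= L - 1", {
  expect_error(encode_pseknc(random_samples(2, 9), lambda = 8), "lambda")
})

test_that("the shipped property table is standardized per property", {
  P <- pseknc_property_table()
  expect_equal(dim(P), c(6L, 16L))
  expect_equal(rowMeans(P), rep(0, 6), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowMeans(P^2), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("encoders are pure: identical input gives bit-identical output", {
  d <- random_samples(10, 21, seed = 42)
  expect_identical(encode_ctd(d), encode_ctd(d))
  expect_identical(encode_pseknc(d), encode_pseknc(d))
  expect_identical(encode_nps(d), encode_nps(d))
})

test_that("fusion concatenates columns and keeps block traceability", {
  d <- random_samples(8, 21, seed = 6)
  a <- encode_ctd(d)
  b <- encode_nps(d)
  f <- fuse_features(a, b)
  expect_equal(ncol(f) - 1L, 30L + 48L)
  bm <- attr(f, "block_map")
  expect_equal(unname(bm[["NPS_k1_AA"]]), "NPS")
  expect_equal(unname(bm[["CTD_comp_A"]]), "CTD")
  expect_identical(fuse_features(a), a) # single block: identity
  d2 <- random_samples(8, 21, seed = 7)
  d2$id <- rev(d2$id)
  expect_error(fuse_features(a, encode_ctd(d2)), "row order|different samples")
})

test_that("feature TSV round-trips values and block map", {
  d <- random_samples(6, 21, seed = 8)
  f <- fuse_features(encode_ctd(d), encode_eiip(d))
  p <- tempfile(fileext = ".tsv")
  write_features(f, p)
  g <- read_features(p)
  expect_equal(as.matrix(g[, -1]), as.matrix(f[, -1]), tolerance = 1e-12)
  expect_equal(attr(g, "block_map"), attr(f, "block_map"))
})
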