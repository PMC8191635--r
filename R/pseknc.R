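#' RNA dinucleotide physicochemical property table
#'
#' Loads the six standard RNA dinucleotide structural properties (Rise, Roll,
#' Shift, Slide, Tilt, Twist) used by the pseudo k-tuple correlation terms,
#' and z-score standardizes each property over the 16 dinucleotides (mean 0,
#' variance 1). A custom table with the same shape can be supplied to
#' [encode_pseknc()].
#'
#' @param path Optional CSV with a `property` column and one column per
#'   dinucleotide (AA..UU); defaults to the table shipped with the package.
#' @return A 6 x 16 numeric matrix, rows = properties, columns =
#'   dinucleotides, each row standardized.
#' @export
pseknc_property_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rna_dinucleotide_properties.csv",
    package = "m6ager", mustWork = TRUE
  )
  tab <- read.csv(path, check.names = FALSE)
  dinucs <- paste0(rep(RNA_BASES, each = 4L), rep(RNA_BASES, 4L))
  stopifnot(all(dinucs %in% names(tab)))
  m <- as.matrix(tab[, dinucs])
  rownames(m) <- tab$property
  # population z-score per property across the 16 dinucleotides
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  (m - mu) / sdv
}

#' Pseudo k-tuple nucleotide composition (PseKNC) encoding
#'
#' Combines local k-mer composition with global sequence-order information.
#' The first 4^k components are the normalized k-mer frequencies f_u; the
#' last `lambda` components are weighted tier-correlation factors theta_j,
#' where theta_j averages, over all dinucleotide pairs j apart, the squared
#' difference of their standardized physicochemical property values across
#' the six properties. Components u are f_u / (1 + w * sum(theta)) for
#' u <= 4^k and w * theta_(u - 4^k) / (1 + w * sum(theta)) above, so the
#' full vector always sums to 1.
#'
#' @inheritParams encode_ctd
#' @param k k-tuple size (default 3).
#' @param lambda Number of counted correlation tiers, 0 <= lambda < L - 1.
#' @param w Weight factor for the correlation tiers (default 0.1).
#' @param property_table Standardized 6 x 16 property matrix; defaults to
#'   [pseknc_property_table()].
#' @return An `m6a_features` tibble with 4^k + lambda `PseKNC_*` columns.
#' @export
encode_pseknc <- function(data, k = 3L, lambda = 2L, w = 0.1,
                          property_table = NULL) {
  data <- validate_sample_set(data, enforce_shape = FALSE)
  sm <- seq_matrix(data$sequence)
  L <- ncol(sm); n <- nrow(sm)
  stopifnot(k >= 1L, lambda >= 0L, w > 0)
  if (lambda >= L - 1L) abort("lambda must be < L - 1 (each tier needs at least one dinucleotide pair)")
  P <- property_table %||% pseknc_property_table()

  # k-mer frequencies (4^k), lexicographic over A,C,G,U
  nk <- L - k + 1L
  code <- matrix(0L, n, nk)
  for (j in seq_len(k)) {
    code <- code * 4L + (sm[, j:(j + nk - 1L), drop = FALSE] - 1L)
  }
  fmat <- t(apply(code + 1L, 1L, tabulate, nbins = 4L^k)) / nk

  # dinucleotide index per position (1..16) and per-pair correlation
  di <- (sm[, -L, drop = FALSE] - 1L) * 4L + sm[, -1L, drop = FALSE]
  theta <- matrix(0, n, max(lambda, 0L))
  if (lambda > 0L) {
    for (j in seq_len(lambda)) {
      i <- seq_len(L - j - 1L)
      d1 <- di[, i, drop = FALSE]
      d2 <- di[, i + j, drop = FALSE]
      corr <- matrix(colMeans((P[, d1, drop = FALSE] - P[, d2, drop = FALSE])^2),
        nrow = n
      )
      theta[, j] <- rowMeans(corr)
    }
  }
  denom <- 1 + w * rowSums(theta)
  mat <- cbind(fmat / denom, if (lambda > 0L) w * theta / denom)
  kmers <- apply(
    do.call(expand.grid, rep(list(RNA_BASES), k))[, k:1, drop = FALSE],
    1L, paste0, collapse = ""
  )
  colnames(mat) <- c(
    paste0("PseKNC_", kmers),
    if (lambda > 0L) paste0("PseKNC_theta", seq_len(lambda))
  )
  new_feature_block(data$id, mat, "PseKNC")
}
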