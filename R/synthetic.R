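#' Generate a synthetic m6A benchmark dataset
#'
#' Emulates the published m6A benchmark sets (fixed-length segments with the
#' candidate adenosine at the center, positives enriched for an RRACH-style
#' consensus, configurable class imbalance) so that every pipeline stage is
#' testable without downloading data. Positives carry the consensus motif
#' centered on the site: each motif position follows the IUPAC consensus with
#' probability `motif_strength`, otherwise it is drawn from the background.
#' Negatives are background sequence with a forced center A and no enriched
#' consensus.
#'
#' @param n_pos,n_neg Numbers of positive / negative segments.
#' @param L Odd segment length (published sets use 21, 25, 41 or 101).
#' @param motif IUPAC consensus placed around the center of positives; must
#'   contain an `A` at its anchor (center of the motif). Default `"RRACH"`
#'   (R = A/G, H = A/C/U), the canonical m6A consensus.
#' @param motif_strength Per-position probability, in \[0,1\], that a
#'   positive's motif position follows the consensus instead of background.
#'   At 1 every positive conforms to the motif; at 0 positives and negatives
#'   are statistically indistinguishable.
#' @param background Nucleotide sampling weights, named A/C/G/U. The default
#'   is uniform; `background = "mrna"` applies a mildly A/U-rich composition.
#' @param secondary_motif_prob Probability that a positive also receives a
#'   weak off-center copy of the motif (gives spaced-pair encoders signal
#'   beyond the center window). Default 0 (off).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A sample-set tibble (`id`, `label`, `sequence`).
#' @examples
#' d <- generate_dataset(n_pos = 5, n_neg = 5, L = 21, seed = 1)
#' table(d$label)
#' @export
generate_dataset <- function(n_pos, n_neg, L = 41L, motif = "RRACH",
                             motif_strength = 0.9, background = NULL,
                             secondary_motif_prob = 0, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, motif_strength >= 0, motif_strength <= 1)
  if (L %% 2L == 0L || L < 5L) abort("L must be odd and >= 5")
  motif <- toupper(motif)
  mlen <- nchar(motif)
  if (mlen %% 2L == 0L || mlen > L) abort("motif length must be odd and <= L")
  mchars <- strsplit(motif, "")[[1]]
  if (!all(mchars %in% names(IUPAC_RNA))) abort("motif must be IUPAC RNA codes")
  anchor <- (mlen + 1L) %/% 2L
  if (mchars[anchor] != "A") abort("motif anchor (center) must be A")
  bg <- background_weights(background)
  center <- (L + 1L) %/% 2L
  m_start <- center - anchor + 1L

  withr::with_seed(seed, {
    draw_bg <- function(n) {
      matrix(sample(RNA_BASES, n * L, replace = TRUE, prob = bg), nrow = n)
    }
    place_motif <- function(mat, rows, start) {
      for (j in seq_len(mlen)) {
        opts <- IUPAC_RNA[[mchars[j]]]
        use <- rows[runif(length(rows)) < motif_strength]
        if (length(use)) {
          mat[cbind(use, start + j - 1L)] <-
            sample(opts, length(use), replace = TRUE)
        }
      }
      mat
    }
    pos <- draw_bg(n_pos)
    pos <- place_motif(pos, seq_len(n_pos), m_start)
    pos[, center] <- "A"
    if (secondary_motif_prob > 0 && L >= 2L * mlen + 3L) {
      hit <- which(runif(n_pos) < secondary_motif_prob)
      if (length(hit)) {
        offs <- sample(c(seq_len(max(1L, m_start - mlen - 1L)),
                         seq(center + anchor + 1L, L - mlen + 1L)),
                       length(hit), replace = TRUE)
        for (i in seq_along(hit)) pos <- place_motif(pos, hit[i], offs[i])
        pos[, center] <- "A"
      }
    }
    neg <- draw_bg(n_neg)
    neg[, center] <- "A"
    tibble(
      id = c(sprintf("pos_%d", seq_len(n_pos)), sprintf("neg_%d", seq_len(n_neg))),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      sequence = c(
        apply(pos, 1L, paste0, collapse = ""),
        apply(neg, 1L, paste0, collapse = "")
      )
    )
  })
}

background_weights <- function(background) {
  if (is.null(background)) {
    return(setNames(rep(0.25, 4), RNA_BASES))
  }
  if (identical(background, "mrna")) {
    # mildly A/U-rich, typical of mRNA around m6A peaks
    return(c(A = 0.3, C = 0.2, G = 0.2, U = 0.3))
  }
  stopifnot(is.numeric(background), setequal(names(background), RNA_BASES))
  background[RNA_BASES] / sum(background)
}
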