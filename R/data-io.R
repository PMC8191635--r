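#' Read labeled m6A sequence segments from FASTA
#'
#' Reads fixed-length RNA sequence segments with the candidate adenosine at
#' the center. Two input modes are supported: a pair of FASTA files (positive
#' = experimentally annotated m6A sites, negative = non-m6A) or a single FASTA
#' whose headers carry a `|label=0` / `|label=1` suffix. Sequences are
#' upper-cased and DNA-style `T` is converted to `U`.
#'
#' @param path_pos Path to the positive-class FASTA (plain or gzip).
#' @param path_neg Path to the negative-class FASTA. If `NULL`, `path_pos` is
#'   read in single-file mode and labels are parsed from headers.
#' @param strict_center_a If `TRUE`, a non-A center nucleotide is an error;
#'   otherwise a warning (user data may include candidate sites off-consensus).
#' @return A tibble with columns `id`, `label` (1 = m6A, 0 = non-m6A) and
#'   `sequence`, one row per segment. All sequences share one odd length.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "GGACU", ">s2", "AGACA"), fa)
#' read_fasta_samples(fa, fa)
#' @export
read_fasta_samples <- function(path_pos, path_neg = NULL, strict_center_a = FALSE) {
  if (is.null(path_neg)) {
    recs <- read_one_fasta(path_pos)
    lab <- sub("^.*\\|label=([01]).*$", "\\1", recs$id)
    if (any(lab == recs$id)) {
      abort("single-file mode requires a '|label=0' or '|label=1' header suffix on every record")
    }
    recs$label <- as.integer(lab)
    recs$id <- sub("\\|label=[01]", "", recs$id)
  } else {
    pos <- read_one_fasta(path_pos)
    neg <- read_one_fasta(path_neg)
    pos$label <- 1L
    neg$label <- 0L
    recs <- dplyr::bind_rows(pos, neg)
  }
  validate_sample_set(recs[, c("id", "label", "sequence")],
    strict_center_a = strict_center_a
  )
}

read_one_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) abort(sprintf("FASTA file is empty: %s", path))
  tibble(id = names(ss), sequence = unname(as.character(ss)))
}

#' Validate and normalize a sample-set tibble
#'
#' Enforces the sample-set contract: columns `id`, `label`, `sequence`;
#' sequences over \{A,C,G,U\} after upper-casing and T->U conversion; one
#' shared odd length >= 5; unique ids. The center nucleotide should be A
#' (the candidate methylation site); violations warn by default.
#'
#' @param data A data frame with columns `id`, `label`, `sequence`.
#' @param enforce_shape Enforce the segment-shape contract (odd length >= 5,
#'   center-A check). The encoders relax this: they are defined for any
#'   uniform length.
#' @inheritParams read_fasta_samples
#' @return The normalized tibble.
#' @export
validate_sample_set <- function(data, strict_center_a = FALSE,
                                enforce_shape = TRUE) {
  data <- as_tibble(data)
  need <- c("id", "label", "sequence")
  if (!all(need %in% names(data))) {
    abort(sprintf("sample set needs columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(data) == 0L) abort("sample set is empty")
  data$id <- as.character(data$id)
  data$label <- as.integer(data$label)
  if (!all(data$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  if (anyDuplicated(data$id)) {
    abort(sprintf("duplicate sample ids: %s",
      paste(head(unique(data$id[duplicated(data$id)]), 3), collapse = ", ")))
  }
  data$sequence <- chartr("acgut", "ACGUU", data$sequence)
  data$sequence <- gsub("T", "U", data$sequence, fixed = TRUE)
  bad <- grepl("[^ACGU]", data$sequence)
  if (any(bad)) {
    abort(sprintf("illegal characters (not A/C/G/T/U) in record(s): %s",
      paste(head(data$id[bad], 3), collapse = ", ")))
  }
  lens <- nchar(data$sequence)
  if (length(unique(lens)) != 1L) {
    off <- data$id[lens != lens[1L]][1L]
    abort(sprintf("sequences have mixed lengths (%s); first offending record: %s",
      paste(sort(unique(lens)), collapse = ", "), off))
  }
  L <- lens[1L]
  if (enforce_shape) {
    if (L < 5L || L %% 2L == 0L) {
      abort(sprintf("segment length must be odd and >= 5, got %d", L))
    }
    center <- substr(data$sequence, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
    if (any(center != "A")) {
      msg <- sprintf("%d record(s) do not have A at the center position", sum(center != "A"))
      if (strict_center_a) abort(msg) else warn(msg)
    }
  }
  data[, need]
}

#' Write a sample set to FASTA
#'
#' Single-file form: labels are encoded as a `|label=` suffix so that
#' [read_fasta_samples()] round-trips ids, labels and sequences exactly.
#'
#' @param data A validated sample-set tibble.
#' @param path Output path (single-file mode), or `NULL` when using
#'   `path_pos`/`path_neg`.
#' @param path_pos,path_neg Optional pair of paths for two-file output.
#' @return Invisibly, the path(s) written.
#' @export
write_fasta_samples <- function(data, path = NULL, path_pos = NULL, path_neg = NULL) {
  data <- validate_sample_set(data)
  fa <- function(d, p, suffix = TRUE) {
    ids <- if (suffix) paste0(d$id, "|label=", d$label) else d$id
    writeLines(paste0(">", ids, "\n", d$sequence), p)
    p
  }
  if (!is.null(path)) {
    return(invisible(fa(data, path)))
  }
  stopifnot(!is.null(path_pos), !is.null(path_neg))
  invisible(c(
    fa(dplyr::filter(data, .data$label == 1L), path_pos, suffix = FALSE),
    fa(dplyr::filter(data, .data$label == 0L), path_neg, suffix = FALSE)
  ))
}

#' Split a sample set into training and test subsets
#'
#' Random, seeded, by default stratified by class so the class ratio of the
#' input (which the imbalanced-data experiments depend on) is preserved
#' within rounding.
#'
#' @param data A sample-set tibble.
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @return A list with tibbles `train` and `test`; disjoint, union = input.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L, stratified = TRUE) {
  data <- validate_sample_set(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (stratified && any(table(data$label) < 5L)) {
    abort("stratified split needs at least 5 samples of each class")
  }
  idx <- withr::with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(nrow(data)), data$label), function(i) {
        sample(i, round(train_fraction * length(i)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(data)), round(train_fraction * nrow(data)))
    }
  })
  list(
    train = data[sort(idx), , drop = FALSE],
    test = data[setdiff(seq_len(nrow(data)), idx), , drop = FALSE]
  )
}
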