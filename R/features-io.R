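#' Write / read a feature block as TSV
#'
#' Tab-separated matrix with a header row of feature labels and the sample
#' id as the first column. The block assignment of each column is stored in
#' a sidecar `<path>.blocks` file (two columns: feature, block) so reading
#' restores full traceability.
#'
#' @param fb An `m6a_features` tibble.
#' @param path Output path.
#' @return `write_features()` the path, invisibly; `read_features()` the
#'   restored `m6a_features` tibble.
#' @export
write_features <- function(fb, path) {
  stopifnot(inherits(fb, "m6a_features"))
  utils::write.table(fb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bm <- block_map(fb)
  utils::write.table(
    data.frame(feature = names(bm), block = unname(bm)),
    paste0(path, ".blocks"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  fb <- new_feature_block(as.character(df[[1L]]), mat, "restored")
  bp <- paste0(path, ".blocks")
  if (file.exists(bp)) {
    bm <- utils::read.delim(bp)
    attr(fb, "block_map") <- setNames(bm$block, bm$feature)[colnames(mat)]
  }
  fb
}
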