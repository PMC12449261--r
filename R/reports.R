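# Human-readable TSV reports for segments and kinship.

#' Write an IBD segment report
#'
#' Tab-separated text with header columns `sample1`, `sample2`,
#' `chromosome`, `start_bp`, `end_bp`, `length_mb`, `type`, `n_windows`,
#' sorted by (sample1, sample2, chromosome, start_bp) so output is
#' deterministic.
#'
#' @param segments segment data.frame as produced by [ibd_scan()] /
#'   [detect_pair()]; an empty data.frame yields a header-only file.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- names(.empty_segments())
  if (is.null(segments) || nrow(segments) == 0) {
    seg <- .empty_segments()
  } else {
    stopifnot(all(cols %in% names(segments)))
    seg <- .sort_segments(segments[, cols, drop = FALSE])
  }
  utils::write.table(seg, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back an IBD segment report
#'
#' @param path a file written by [write_segments()].
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(sample1 = "character",
                                          sample2 = "character",
                                          chromosome = "character"))
  if (nrow(seg) == 0) return(.empty_segments())
  seg
}

#' Write a kinship report
#'
#' Tab-separated text with columns `sample1`, `sample2`, `L_ibd1_mb`,
#' `L_ibd2_mb`, `theta`, `degree`.
#'
#' @param kin kinship data.frame as produced by [pair_kinship()] rows or
#'   [ibd_scan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path) {
  cols <- c("sample1", "sample2", "L_ibd1_mb", "L_ibd2_mb", "theta", "degree")
  if (is.null(kin) || nrow(kin) == 0) {
    kin <- data.frame(sample1 = character(), sample2 = character(),
                      L_ibd1_mb = numeric(), L_ibd2_mb = numeric(),
                      theta = numeric(), degree = character())
  } else {
    stopifnot(all(cols %in% names(kin)))
    kin <- kin[order(kin$sample1, kin$sample2), cols, drop = FALSE]
  }
  utils::write.table(kin, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
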