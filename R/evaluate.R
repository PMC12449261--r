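# Benchmark metrics for reported segments against ground truth.
#
# Segments are matched within (unordered sample pair, chromosome); overlap
# is measured on bp intervals as end - start. Coverage always refers to a
# SINGLE best-matching segment, never to a union: a truth segment covered
# 40% + 40% by two reported segments is not recalled. Metrics with an empty
# denominator are NA (undefined), not zero.

.match_cols <- function(seg, type_sensitive) {
  key <- paste(.pair_key(seg$sample1, seg$sample2), seg$chromosome,
               sep = "\r")
  if (type_sensitive && !is.null(seg$type)) key <- paste(key, seg$type)
  key
}

# for each row of x, the best single-segment overlap (bp) with rows of y
.best_overlap <- function(x, y, type_sensitive = FALSE) {
  kx <- .match_cols(x, type_sensitive)
  ky <- .match_cols(y, type_sensitive)
  vapply(seq_len(nrow(x)), function(i) {
    j <- which(ky == kx[i])
    if (!length(j)) return(0)
    max(.olap1(x$start_bp[i], x$end_bp[i], y$start_bp[j], y$end_bp[j]))
  }, numeric(1))
}

#' Recall of ground-truth segments
#'
#' Fraction of ground-truth segments at least 50% of whose length is covered
#' by some one reported segment.
#'
#' @param truth,reported segment data.frames with columns `sample1`,
#'   `sample2`, `chromosome`, `start_bp`, `end_bp` (and optionally `type`).
#' @param min_cover coverage fraction required; default 0.5.
#' @param type_sensitive also require matching `type`; default FALSE.
#' @return fraction in `[0, 1]`, or `NA` when `truth` is empty.
#' @export
seg_recall <- function(truth, reported, min_cover = 0.5,
                       type_sensitive = FALSE) {
  if (is.null(truth) || nrow(truth) == 0) return(NA_real_)
  if (is.null(reported) || nrow(reported) == 0) return(0)
  best <- .best_overlap(truth, reported, type_sensitive)
  mean(best / (truth$end_bp - truth$start_bp) >= min_cover)
}

#' Power: covered fraction of ground-truth length
#'
#' Sum over ground-truth segments of the best single reported-segment
#' overlap, divided by the total ground-truth length.
#'
#' @inheritParams seg_recall
#' @return fraction in `[0, 1]`, or `NA` when `truth` is empty.
#' @export
seg_power <- function(truth, reported, type_sensitive = FALSE) {
  if (is.null(truth) || nrow(truth) == 0) return(NA_real_)
  if (is.null(reported) || nrow(reported) == 0) return(0)
  best <- .best_overlap(truth, reported, type_sensitive)
  sum(best) / sum(truth$end_bp - truth$start_bp)
}

#' Accuracy of reported segments
#'
#' Mirror of [seg_recall()] with the roles swapped: the fraction of reported
#' segments at least 50% covered by some one ground-truth segment.
#'
#' @inheritParams seg_recall
#' @return fraction in `[0, 1]`, or `NA` when `reported` is empty.
#' @export
seg_accuracy <- function(truth, reported, min_cover = 0.5,
                         type_sensitive = FALSE) {
  seg_recall(reported, truth, min_cover = min_cover,
             type_sensitive = type_sensitive)
}

#' Length accuracy of reported segments
#'
#' Sum over reported segments of the maximum single ground-truth overlap,
#' divided by the total reported length.
#'
#' @inheritParams seg_recall
#' @return fraction in `[0, 1]`, or `NA` when `reported` is empty.
#' @export
seg_len_accuracy <- function(truth, reported, type_sensitive = FALSE) {
  seg_power(reported, truth, type_sensitive = type_sensitive)
}

#' Breakpoint deviations between truth and best-matching reports
#'
#' Each ground-truth segment is matched to the reported segment with the
#' largest overlap (ties broken by order); unmatched truths (no overlapping
#' reported segment) are excluded. Deviations are `|reported - true|` in Mb
#' for the start and end positions.
#'
#' @inheritParams seg_recall
#' @return list with `median_start_dev_mb`, `median_end_dev_mb`, and the
#'   per-match vectors `start_dev_mb`, `end_dev_mb` (empty when nothing
#'   matches).
#' @export
breakpoint_deviation <- function(truth, reported, type_sensitive = FALSE) {
  empty <- list(median_start_dev_mb = NA_real_, median_end_dev_mb = NA_real_,
                start_dev_mb = numeric(), end_dev_mb = numeric())
  if (is.null(truth) || nrow(truth) == 0 ||
      is.null(reported) || nrow(reported) == 0) return(empty)
  kt <- .match_cols(truth, type_sensitive)
  kr <- .match_cols(reported, type_sensitive)
  sd_ <- ed_ <- numeric()
  for (i in seq_len(nrow(truth))) {
    j <- which(kr == kt[i])
    if (!length(j)) next
    ov <- .olap1(truth$start_bp[i], truth$end_bp[i],
                 reported$start_bp[j], reported$end_bp[j])
    if (max(ov) <= 0) next
    jb <- j[which.max(ov)]
    sd_ <- c(sd_, abs(reported$start_bp[jb] - truth$start_bp[i]) / 1e6)
    ed_ <- c(ed_, abs(reported$end_bp[jb] - truth$end_bp[i]) / 1e6)
  }
  if (!length(sd_)) return(empty)
  list(median_start_dev_mb = stats::median(sd_),
       median_end_dev_mb = stats::median(ed_),
       start_dev_mb = sd_, end_dev_mb = ed_)
}

#' All four benchmark metrics at once
#'
#' @inheritParams seg_recall
#' @return one-row data.frame with `recall`, `power`, `accuracy`,
#'   `len_accuracy`, `median_start_dev_mb`, `median_end_dev_mb`.
#' @export
ibd_metrics <- function(truth, reported, type_sensitive = FALSE) {
  bd <- breakpoint_deviation(truth, reported, type_sensitive)
  data.frame(recall = seg_recall(truth, reported,
                                 type_sensitive = type_sensitive),
             power = seg_power(truth, reported,
                               type_sensitive = type_sensitive),
             accuracy = seg_accuracy(truth, reported,
                                     type_sensitive = type_sensitive),
             len_accuracy = seg_len_accuracy(truth, reported,
                                             type_sensitive = type_sensitive),
             median_start_dev_mb = bd$median_start_dev_mb,
             median_end_dev_mb = bd$median_end_dev_mb)
}
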