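#' @keywords internal
"_PACKAGE"

# Interval helpers. All intervals are bp pairs (start, end) with start < end;
# lengths are measured as end - start (open length), so a 10,000,000-20,000,000
# segment is 10 Mb. Inputs are 2-column matrices or data.frames with columns
# start, end.

.as_interval_mat <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$start, x$end)
  m <- matrix(as.numeric(x), ncol = 2)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# union of possibly overlapping intervals -> disjoint sorted intervals
.merge_intervals <- function(x) {
  m <- .as_interval_mat(x)
  if (nrow(m) == 0) return(m)
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}

.interval_total_len <- function(x) {
  m <- .merge_intervals(x)
  if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])
}

# total length of intersection between one interval and a set of intervals
.overlap_len <- function(start, end, set) {
  if (length(set) == 0 || nrow(set) == 0) return(0)
  sum(pmax(0, pmin(end, set[, 2]) - pmax(start, set[, 1])))
}

# pairwise overlap length of two single intervals
.olap1 <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# canonical unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

.is_autosome <- function(chrom) {
  suppressWarnings(ch <- as.integer(as.character(chrom)))
  !is.na(ch) & ch >= 1L & ch <= 22L
}

# empty segment table with the canonical column layout
.empty_segments <- function() {
  data.frame(sample1 = character(), sample2 = character(),
             chromosome = character(), start_bp = numeric(),
             end_bp = numeric(), length_mb = numeric(),
             type = character(), n_windows = integer(),
             stringsAsFactors = FALSE)
}

.sort_segments <- function(seg) {
  if (nrow(seg) == 0) return(seg)
  o <- order(seg$sample1, seg$sample2,
             suppressWarnings(as.numeric(seg$chromosome)),
             seg$chromosome, seg$start_bp)
  seg <- seg[o, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}
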