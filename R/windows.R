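#' Tile markers into fixed-size windows
#'
#' Markers (already sorted by chromosome and position) are divided per
#' chromosome into consecutive non-overlapping blocks of `snps_per_window`
#' markers. A trailing block with fewer than `snps_per_window / 2` markers is
#' merged into the previous window, so no high-variance tiny window is
#' created; a chromosome with fewer than `snps_per_window` markers forms a
#' single short window with a warning. Windows never span chromosomes.
#'
#' @param markers marker data.frame with columns `chrom` and `pos` (e.g. the
#'   `markers` element of a [genotype_matrix()]).
#' @param snps_per_window markers per window; default 150.
#' @return data.frame with one row per window: `window` (1-based index),
#'   `chrom`, `marker_lo`, `marker_hi` (1-based inclusive row indices into
#'   `markers`), `start_bp`, `end_bp`, `n_markers`.
#' @export
build_windows <- function(markers, snps_per_window = 150) {
  stopifnot(snps_per_window >= 10)
  chroms <- unique(markers$chrom)
  out <- vector("list", length(chroms))
  offset <- 0L
  for (ci in seq_along(chroms)) {
    idx <- which(markers$chrom == chroms[ci])
    n <- length(idx)
    if (n < snps_per_window) {
      warning("chromosome ", chroms[ci], " has only ", n,
              " markers; forming a single short window")
      lo <- 1L
      hi <- n
    } else {
      k <- n %/% snps_per_window
      rem <- n - k * snps_per_window
      sizes <- rep.int(snps_per_window, k)
      if (rem > 0) {
        if (rem < snps_per_window / 2) sizes[k] <- sizes[k] + rem
        else sizes <- c(sizes, rem)
      }
      hi <- cumsum(sizes)
      lo <- c(1L, utils::head(hi, -1L) + 1L)
    }
    out[[ci]] <- data.frame(
      chrom = chroms[ci],
      marker_lo = idx[lo], marker_hi = idx[hi],
      start_bp = markers$pos[idx[lo]], end_bp = markers$pos[idx[hi]],
      n_markers = hi - lo + 1L, stringsAsFactors = FALSE)
    offset <- offset + length(lo)
  }
  res <- do.call(rbind, out)
  res <- cbind(window = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

# per-marker window index vector (NA for markers outside any window;
# cannot happen with build_windows output but kept defensive)
.window_index <- function(windows, n_markers) {
  win <- rep(NA_integer_, n_markers)
  for (i in seq_len(nrow(windows)))
    win[windows$marker_lo[i]:windows$marker_hi[i]] <- windows$window[i]
  win
}
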