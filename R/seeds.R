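# Seed finding, gap-filling / seed extension, and edge refinement.
#
# All three operate on one chromosome's windows. `below` is a logical vector
# aligned to those windows: TRUE when the window's rate is defined and
# strictly below the pair threshold, FALSE when defined and at/above it, NA
# when the window had no compared sites. NA windows are neither seeds nor
# gaps: they break runs, so segments are never called through no-data
# regions.

#' Find seed segments
#'
#' A seed is a maximal run of at least `min_seed_windows` consecutive
#' below-threshold windows. Isolated below-threshold windows occur by chance
#' in the background, but long runs are very unlikely outside true IBD.
#'
#' @param below logical vector (one element per window of one chromosome;
#'   `NA` allowed, breaks runs).
#' @param min_seed_windows minimum run length; default 3.
#' @return data.frame with columns `lo`, `hi` (1-based inclusive window
#'   offsets within `below`), zero rows when no seed exists.
#' @export
find_seeds <- function(below, min_seed_windows = 3) {
  b <- !is.na(below) & below
  r <- rle(b)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- r$values & r$lengths >= min_seed_windows
  data.frame(lo = lo[keep], hi = hi[keep])
}

#' Merge nearby seeds and extend across short gaps
#'
#' Two operations: (1) gap-filling, iterated to a fixpoint -- adjacent seeds
#' separated by at most `max_gap_windows` above-threshold windows are merged
#' together with the gap (two recombination events in a short region are
#' unlikely, so the interruption is attributed to noise); (2) seed
#' extension, one attempt per side per seed -- a flank of at most
#' `max_gap_windows` above-threshold windows immediately followed by one or
#' more below-threshold windows is skipped and the below-threshold run
#' appended to the seed. Extension is deliberately not iterated: a fraction
#' of background windows always falls below the threshold by chance, and
#' repeated extension would chain through the background and produce long
#' spurious segments (gap-filling alone cannot, because it requires a full
#' seed on both sides of every gap). A final gap-filling pass merges seeds
#' brought into contact by extension. `NA` windows in a gap or flank block
#' both operations. Seeds never shrink and the result is sorted and
#' disjoint.
#'
#' @param seeds data.frame from [find_seeds()] (columns `lo`, `hi`, sorted).
#' @param below the logical vector the seeds were found in.
#' @param max_gap_windows maximum gap width; default 2.
#' @return data.frame with columns `lo`, `hi`.
#' @export
fill_and_extend <- function(seeds, below, max_gap_windows = 2) {
  if (nrow(seeds) == 0) return(seeds)
  lo <- as.integer(seeds$lo)
  hi <- as.integer(seeds$hi)
  n <- length(below)
  def <- !is.na(below)
  b <- def & below

  gap_ok <- function(from, to) {       # windows strictly between two bounds
    if (to < from) return(TRUE)        # touching runs
    idx <- from:to
    all(def[idx]) && sum(!b[idx]) <= max_gap_windows
  }

  gap_fill <- function(lo, hi) {
    i <- 1L
    while (i < length(lo)) {
      if (lo[i + 1L] <= hi[i] || gap_ok(hi[i] + 1L, lo[i + 1L] - 1L)) {
        hi[i] <- max(hi[i], hi[i + 1L])
        lo <- lo[-(i + 1L)]
        hi <- hi[-(i + 1L)]
      } else i <- i + 1L
    }
    list(lo = lo, hi = hi)
  }

  s <- gap_fill(lo, hi)
  lo <- s$lo; hi <- s$hi

  # one extension attempt per side per seed
  for (i in seq_along(lo)) {
    j <- hi[i] + 1L
    k <- j
    while (k <= n && def[k] && !b[k] && (k - j + 1L) <= max_gap_windows)
      k <- k + 1L
    if (k <= n && def[k] && b[k]) {
      while (k <= n && def[k] && b[k]) k <- k + 1L
      hi[i] <- k - 1L
    }
    j <- lo[i] - 1L
    k <- j
    while (k >= 1L && def[k] && !b[k] && (j - k + 1L) <= max_gap_windows)
      k <- k - 1L
    if (k >= 1L && def[k] && b[k]) {
      while (k >= 1L && def[k] && b[k]) k <- k - 1L
      lo[i] <- k + 1L
    }
  }

  o <- order(lo)
  s <- gap_fill(lo[o], hi[o])
  data.frame(lo = s$lo, hi = s$hi)
}

#' Refine segment edges to flagged sites
#'
#' Window boundaries overshoot the true breakpoints because the first and
#' last windows of a called run are usually only partially IBD. The edges
#' are therefore reassigned site-wise: the final start position is the
#' position of the last flagged site (opposite-homozygote site for IBD1,
#' mismatch site for IBD2) within the first window, and the final end
#' position is the first flagged site within the last window. When a window
#' contains no flagged site, the window's first (respectively last) marker
#' position is used. A segment whose refined start is not strictly before
#' its refined end is dropped (`NULL`).
#'
#' @param seed one row of a seed table (`lo`, `hi` window offsets, within
#'   one chromosome).
#' @param windows_chrom the window table rows for that chromosome, in order.
#' @param site_flags logical vector over all markers (global indexing,
#'   matching `marker_lo`/`marker_hi` of the window table): TRUE at flagged
#'   sites.
#' @param pos global marker position vector.
#' @return `c(start_bp, end_bp)` or `NULL` when the segment degenerates.
#' @export
refine_edges <- function(seed, windows_chrom, site_flags, pos) {
  wf <- windows_chrom[seed$lo, ]
  wl <- windows_chrom[seed$hi, ]
  f_idx <- wf$marker_lo:wf$marker_hi
  l_idx <- wl$marker_lo:wl$marker_hi
  ff <- f_idx[which(site_flags[f_idx])]
  lf <- l_idx[which(site_flags[l_idx])]
  start_bp <- if (length(ff)) pos[ff[length(ff)]] else pos[f_idx[1]]
  end_bp <- if (length(lf)) pos[lf[1]] else pos[l_idx[length(l_idx)]]
  if (start_bp < end_bp) c(start_bp, end_bp) else NULL
}
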