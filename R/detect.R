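#' Detect IBD1 and IBD2 segments for one sample pair
#'
#' Runs the full windowed scan for a single pair: computes the per-window
#' opposite-homozygote and mismatch rate profile, selects the pair-specific
#' thresholds (see [pair_threshold()]), finds seed runs, applies
#' gap-filling/extension, refines the edges site-wise, and reports segments
#' of at least `min_length_mb`. IBD1 is called from the opposite-homozygote
#' rate against `max(t_valley or t_15th, t_universal)`; IBD2 from the
#' mismatch rate against `t_universal_2` alone, the bound below the expected
#' IBD1 mismatch level `2pq` (the interfering signal for IBD2 is IBD1, so a
#' pair-adaptive candidate that rises above that level would misclassify
#' IBD1 blocks as IBD2).
#'
#' @param g a [genotype_matrix()].
#' @param a,b sample identifiers.
#' @param windows window table from [build_windows()].
#' @param thresholds list with `t_universal` and `t_universal_2` (see
#'   [universal_thresholds()]).
#' @param min_seed_windows,max_gap_windows,min_length_mb tuning parameters;
#'   defaults 3, 2 and 7.
#' @param kde_args list of extra arguments for [kde_valley()].
#' @return segment data.frame (columns `sample1`, `sample2`, `chromosome`,
#'   `start_bp`, `end_bp`, `length_mb`, `type`, `n_windows`), with the
#'   per-pair threshold set attached as attribute `"thresholds"`.
#' @export
detect_pair <- function(g, a, b, windows, thresholds,
                        min_seed_windows = 3, max_gap_windows = 2,
                        min_length_mb = 7, kde_args = list()) {
  sites <- .pair_sites(g, a, b)
  win <- .window_index(windows, nrow(g$markers))
  inw <- !is.na(win)
  tab <- rowsum(cbind(cmp = as.integer(sites$cmp[inw]),
                      opp = as.integer(sites$opp[inw]),
                      mism = as.integer(sites$mism[inw])),
                group = win[inw], reorder = TRUE)
  full <- matrix(0L, nrow = nrow(windows), ncol = 3,
                 dimnames = list(NULL, c("cmp", "opp", "mism")))
  full[as.integer(rownames(tab)), ] <- tab
  ncmp <- full[, "cmp"]
  r_ohg <- ifelse(ncmp > 0, full[, "opp"] / ncmp, NA_real_)
  r_mism <- ifelse(ncmp > 0, full[, "mism"] / ncmp, NA_real_)

  th1 <- do.call(pair_threshold,
                 c(list(r_ohg, thresholds$t_universal), kde_args))
  # The IBD2 threshold is t_universal_2 itself. The interference to exclude
  # is IBD1, whose per-window mismatch rate sits at the heterozygosity level
  # 2pq; a pair's own mismatch-rate distribution is bimodal (IBD1 mode vs
  # background mode) whenever it carries IBD1, so valley/quantile candidates
  # combined by max would push the threshold above the IBD1 mode and call
  # whole IBD1 blocks (or background tails, for unrelated pairs) as IBD2.
  th2 <- list(t_final = thresholds$t_universal_2, t_valley = NA_real_,
              t_15th = NA_real_)

  pos <- g$markers$pos
  call_type <- function(rates, t_final, flags, type) {
    below <- ifelse(is.na(rates), NA, rates < t_final)
    res <- list()
    for (ch in unique(windows$chrom)) {
      wc <- windows[windows$chrom == ch, , drop = FALSE]
      idx <- match(wc$window, windows$window)
      seeds <- find_seeds(below[idx], min_seed_windows)
      seeds <- fill_and_extend(seeds, below[idx], max_gap_windows)
      for (i in seq_len(nrow(seeds))) {
        bp <- refine_edges(seeds[i, ], wc, flags, pos)
        if (is.null(bp)) next
        len <- (bp[2] - bp[1]) / 1e6
        if (len < min_length_mb) next
        res[[length(res) + 1L]] <- data.frame(
          sample1 = a, sample2 = b, chromosome = ch,
          start_bp = bp[1], end_bp = bp[2], length_mb = len, type = type,
          n_windows = seeds$hi[i] - seeds$lo[i] + 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else .empty_segments()
  }

  seg <- rbind(call_type(r_ohg, th1$t_final, sites$opp, "IBD1"),
               call_type(r_mism, th2$t_final, sites$mism, "IBD2"))
  seg <- .sort_segments(seg)
  attr(seg, "thresholds") <- data.frame(
    sample1 = a, sample2 = b,
    t_valley_ibd1 = th1$t_valley, t_15th_ibd1 = th1$t_15th,
    t_universal = thresholds$t_universal, t_final_ibd1 = th1$t_final,
    t_valley_ibd2 = th2$t_valley, t_15th_ibd2 = th2$t_15th,
    t_universal_2 = thresholds$t_universal_2, t_final_ibd2 = th2$t_final,
    stringsAsFactors = FALSE)
  attr(seg, "profile") <- data.frame(window = windows$window,
                                     chrom = windows$chrom,
                                     n_compared = ncmp, r_ohg = r_ohg,
                                     r_mismatch = r_mism,
                                     stringsAsFactors = FALSE)
  seg
}
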