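# Dynamic threshold selection.
#
# The scan distinguishes windows belonging to IBD segments (low rates) from
# background windows (rates set by allele frequencies) with a per-pair
# threshold chosen from three candidates:
#   t_valley : the KDE valley between the IBD and non-IBD modes of the
#              per-window rate distribution, when the distribution is bimodal;
#   t_15th   : the 15% quantile of the pair's rates, when it is unimodal
#              (the IBD mode is buried, as for distant relatives);
#   t_universal : a pair-independent floor derived from heterozygosity.
# The final threshold is the maximum of the applicable candidates, so pairs
# that are homogeneous across the genome (duplicates, parent-child) are still
# callable: their own quantiles collapse towards zero but t_universal keeps
# the genome above threshold. All quantiles use linear interpolation between
# order statistics (type 7).

#' Universal thresholds from pooled window heterozygosity
#'
#' For a background (non-IBD) window the expected per-site
#' opposite-homozygote rate is `2 p^2 q^2 = (2pq)^2 / 2`, i.e. half the
#' squared expected heterozygosity, while within an IBD1 region the expected
#' mismatch rate is `2pq` itself. The 15% quantile `q15` of per-window
#' heterozygosity values pooled from a few randomly chosen samples therefore
#' yields a pair-independent IBD1 threshold `q15^2 / 2` and an IBD2 threshold
#' `q15`.
#'
#' @param he_values pooled per-window heterozygosity values (`NA`s allowed,
#'   they are dropped).
#' @return list with elements `t_universal` (`= q15^2 / 2`), `t_universal_2`
#'   (`= q15`) and `q15`.
#' @export
universal_thresholds <- function(he_values) {
  he <- he_values[!is.na(he_values)]
  if (length(he) == 0)
    stop("no defined heterozygosity values; supply more samples or windows")
  q15 <- unname(stats::quantile(he, 0.15, type = 7))
  list(t_universal = q15^2 / 2, t_universal_2 = q15, q15 = q15)
}

#' Locate the valley of a bimodal rate distribution
#'
#' Estimates the density of per-window rates with a Gaussian kernel
#' (Silverman's rule-of-thumb bandwidth) on an evenly spaced grid over
#' `[0, max(rates)]`, then scans from the left for the leftmost local
#' maximum followed by the first strict local minimum. The rate at that
#' minimum separates the IBD mode (near zero) from the background mode.
#' Returns `NA` when the density is unimodal on the grid, when the rates
#' have zero variance, or when fewer than `min_n` defined rates are
#' available (too little data to resolve two modes).
#'
#' @param rates defined per-window rate values for one pair.
#' @param grid_points number of grid points for the density; default 512.
#' @param bandwidth_rule bandwidth selector passed to [stats::density()];
#'   default `"nrd0"` (Silverman).
#' @param min_n minimum number of rates to attempt valley detection;
#'   default 50.
#' @return the valley rate, or `NA_real_`.
#' @export
kde_valley <- function(rates, grid_points = 512, bandwidth_rule = "nrd0",
                       min_n = 50) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < min_n) return(NA_real_)
  if (stats::sd(rates) == 0 || max(rates) <= 0) return(NA_real_)
  d <- stats::density(rates, bw = bandwidth_rule, n = grid_points,
                      from = 0, to = max(rates))
  y <- d$y
  n <- length(y)
  # leftmost local maximum (the boundary counts when density falls from it)
  imax <- NA_integer_
  for (i in seq_len(n - 1)) {
    if (y[i] > y[i + 1] && (i == 1 || y[i] >= y[i - 1])) {
      imax <- i
      break
    }
  }
  if (is.na(imax) || imax + 1 > n - 1) return(NA_real_)
  # Rates are discrete (multiples of 1 / window size), so at these sample
  # sizes the KDE ripples at a scale comparable to the bandwidth; a strict
  # local minimum alone is not evidence of bimodality. A genuine valley must
  # be prominent: its density at most half of both the highest peak to its
  # left and the highest peak to its right, and both peaks must carry
  # appreciable mass (at least 5% of the global maximum) -- an IBD mode too
  # small to register is "buried" and handled by the quantile fallback.
  ymax <- max(y)
  for (j in seq.int(imax + 1, n - 1)) {
    if (y[j] < y[j - 1] && y[j] < y[j + 1]) {
      left_pk <- max(y[1:j])
      right_pk <- max(y[(j + 1):n])
      if (min(left_pk, right_pk) >= 0.05 * ymax &&
          y[j] <= 0.5 * min(left_pk, right_pk))
        return(d$x[j])
    }
  }
  NA_real_
}

#' Final per-pair threshold
#'
#' Applies the candidate rule: if [kde_valley()] finds a valley, the
#' candidates are `{t_valley, t_universal}`; otherwise `t_15th` (the 15%
#' quantile of the pair's defined rates) replaces it and the candidates are
#' `{t_15th, t_universal}`. The final threshold is the maximum of the
#' candidates, so it can never drop below the universal floor.
#'
#' @param rates per-window rate values for one pair (`NA`s allowed).
#' @param t_universal pair-independent threshold (for IBD1 pass
#'   `t_universal`, for IBD2 pass `t_universal_2`; see
#'   [universal_thresholds()]).
#' @param ... passed on to [kde_valley()].
#' @return list with `t_final`, `t_valley`, `t_15th`, `t_universal`.
#' @export
pair_threshold <- function(rates, t_universal, ...) {
  def <- rates[!is.na(rates)]
  if (length(def) == 0)
    stop("pair has no defined window rates")
  t_valley <- kde_valley(def, ...)
  if (!is.na(t_valley)) {
    t_15th <- NA_real_
    t_final <- max(t_valley, t_universal)
  } else {
    t_15th <- unname(stats::quantile(def, 0.15, type = 7))
    t_final <- max(t_15th, t_universal)
  }
  list(t_final = t_final, t_valley = t_valley, t_15th = t_15th,
       t_universal = t_universal)
}

# pooled He values from a random subset of samples (at most `n_samples`),
# used to compute the universal thresholds for a dataset
.he_pool <- function(g, windows, n_samples = 10) {
  pick <- g$samples
  if (length(pick) > n_samples) pick <- sample(pick, n_samples)
  unlist(lapply(pick, function(s) he_profile(g, s, windows)$he),
         use.names = FALSE)
}
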