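# Per-pair window rate profiles and per-sample heterozygosity profiles.

.sample_index <- function(g, s) {
  i <- match(s, g$samples)
  if (is.na(i)) stop("unknown sample identifier: ", s)
  i
}

# site-level comparison vectors for one pair, over all markers
.pair_sites <- function(g, a, b) {
  va <- g$codes[, .sample_index(g, a)]
  vb <- g$codes[, .sample_index(g, b)]
  cmp <- !is.na(va) & !is.na(vb)
  opp <- cmp & ((va == 0L & vb == 2L) | (va == 2L & vb == 0L))
  mism <- cmp
  mism[cmp] <- va[cmp] != vb[cmp]
  list(cmp = cmp, opp = opp, mism = mism)
}

#' Windowed opposite-homozygote and mismatch rates for a sample pair
#'
#' For every window, the opposite-homozygote rate `r_ohg` is the fraction of
#' doubly non-missing sites where one sample is homozygous for one allele and
#' the other homozygous for the other (codes 0 vs 2) -- impossible inside an
#' error-free IBD1 region. The mismatch rate `r_mismatch` is the fraction of
#' doubly non-missing sites with unequal genotype codes, the IBD2 analogue.
#' Windows with no doubly non-missing site get `NA` rates. Self-comparison
#' (`a == b`) is permitted (used for duplicate detection).
#'
#' @param g a [genotype_matrix()].
#' @param a,b sample identifiers.
#' @param windows window table from [build_windows()].
#' @return data.frame with one row per window: `window`, `chrom`,
#'   `n_compared`, `r_ohg`, `r_mismatch`.
#' @export
pair_window_profile <- function(g, a, b, windows) {
  s <- .pair_sites(g, a, b)
  win <- .window_index(windows, nrow(g$markers))
  inw <- !is.na(win)
  tab <- rowsum(cbind(cmp = as.integer(s$cmp[inw]),
                      opp = as.integer(s$opp[inw]),
                      mism = as.integer(s$mism[inw])),
                group = win[inw], reorder = TRUE)
  full <- matrix(0L, nrow = nrow(windows), ncol = 3,
                 dimnames = list(NULL, c("cmp", "opp", "mism")))
  full[as.integer(rownames(tab)), ] <- tab
  n <- full[, "cmp"]
  data.frame(window = windows$window, chrom = windows$chrom,
             n_compared = n,
             r_ohg = ifelse(n > 0, full[, "opp"] / n, NA_real_),
             r_mismatch = ifelse(n > 0, full[, "mism"] / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Windowed heterozygosity profile for one sample
#'
#' Per window, the fraction of non-missing sites with a heterozygous
#' genotype (code 1). Under Hardy-Weinberg equilibrium the per-site
#' expectation is `2pq`; the pooled 15% quantile of these values drives the
#' universal thresholds (see [universal_thresholds()]).
#'
#' @param g a [genotype_matrix()].
#' @param sample a sample identifier.
#' @param windows window table from [build_windows()].
#' @return data.frame with one row per window: `window`, `n_sites`, `he`
#'   (`NA` where all sites are missing).
#' @export
he_profile <- function(g, sample, windows) {
  v <- g$codes[, .sample_index(g, sample)]
  ok <- !is.na(v)
  het <- ok & v == 1L
  win <- .window_index(windows, nrow(g$markers))
  inw <- !is.na(win)
  tab <- rowsum(cbind(ok = as.integer(ok[inw]), het = as.integer(het[inw])),
                group = win[inw], reorder = TRUE)
  full <- matrix(0L, nrow = nrow(windows), ncol = 2,
                 dimnames = list(NULL, c("ok", "het")))
  full[as.integer(rownames(tab)), ] <- tab
  n <- full[, "ok"]
  data.frame(window = windows$window, n_sites = n,
             he = ifelse(n > 0, full[, "het"] / n, NA_real_))
}
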