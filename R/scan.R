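# Top-level scan orchestrators and the ibd_scan S3 class.

.default_pairs <- function(samples) {
  if (length(samples) < 2) stop("need at least two samples")
  p <- utils::combn(samples, 2)
  data.frame(sample1 = p[1, ], sample2 = p[2, ], stringsAsFactors = FALSE)
}

#' Scan a genotype dataset for IBD segments and kinship (within-search)
#'
#' The main entry point. Filters markers (MAF strictly above `maf_min`,
#' autosomes only), tiles them into windows of `snps_per_window` markers,
#' derives the universal thresholds from the pooled window heterozygosity of
#' `he_samples` randomly chosen samples, then runs [detect_pair()] for every
#' requested pair and summarises each pair's segments into a kinship result.
#'
#' @param g a [genotype_matrix()] (e.g. from [read_plink()] or
#'   [as_genotypes()]).
#' @param pairs data.frame with columns `sample1`, `sample2`, or NULL
#'   (default) for all `n(n-1)/2` pairs.
#' @param snps_per_window markers per window; default 150. Larger windows
#'   are more robust to very noisy data at the cost of short-segment power.
#' @param min_seed_windows consecutive below-threshold windows needed to
#'   seed a segment; default 3.
#' @param max_gap_windows maximum above-threshold gap for merging and
#'   extension; default 2.
#' @param min_length_mb minimum reported segment length; default 7 (shorter
#'   calls are dominated by false positives).
#' @param maf_min MAF filter (exclusive); default 0.05.
#' @param min_spacing_bp marker thinning distance; 0 (default) disables.
#' @param he_samples number of randomly selected samples pooled for the
#'   universal thresholds; default 10.
#' @param seed RNG seed for the heterozygosity sample selection; identical
#'   inputs and seed give byte-identical reports.
#' @param kde_args list of overrides for [kde_valley()].
#' @return an object of class `ibd_scan` with elements `segments`,
#'   `kinship`, `thresholds` (one row per pair), `windows`, `params`,
#'   `l_genome_mb`, `samples`, plus stored per-pair profiles for plotting.
#' @export
ibd_scan <- function(g, pairs = NULL, snps_per_window = 150,
                     min_seed_windows = 3, max_gap_windows = 2,
                     min_length_mb = 7, maf_min = 0.05, min_spacing_bp = 0,
                     he_samples = 10, seed = NULL, kde_args = list()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  g <- filter_markers(g, maf_min = maf_min, autosomes_only = TRUE,
                      min_spacing_bp = min_spacing_bp)
  if (is.null(pairs)) pairs <- .default_pairs(g$samples)
  stopifnot(all(c("sample1", "sample2") %in% names(pairs)))

  windows <- build_windows(g$markers, snps_per_window)
  he_pool <- .he_pool(g, windows, he_samples)
  uni <- universal_thresholds(he_pool)

  seg_list <- vector("list", nrow(pairs))
  thr_list <- vector("list", nrow(pairs))
  kin_list <- vector("list", nrow(pairs))
  l_genome <- genome_length(g$markers)
  for (i in seq_len(nrow(pairs))) {
    seg <- detect_pair(g, pairs$sample1[i], pairs$sample2[i], windows, uni,
                       min_seed_windows = min_seed_windows,
                       max_gap_windows = max_gap_windows,
                       min_length_mb = min_length_mb, kde_args = kde_args)
    thr_list[[i]] <- attr(seg, "thresholds")
    kin <- pair_kinship(seg, l_genome_mb = l_genome)
    kin$sample1 <- pairs$sample1[i]
    kin$sample2 <- pairs$sample2[i]
    attr(seg, "thresholds") <- NULL
    attr(seg, "profile") <- NULL
    seg_list[[i]] <- seg
    kin_list[[i]] <- kin
  }
  segments <- .sort_segments(do.call(rbind, seg_list))
  structure(list(
    segments = segments,
    kinship = do.call(rbind, kin_list),
    thresholds = do.call(rbind, thr_list),
    windows = windows,
    l_genome_mb = l_genome,
    n_markers = nrow(g$markers),
    samples = g$samples,
    params = list(snps_per_window = snps_per_window,
                  min_seed_windows = min_seed_windows,
                  max_gap_windows = max_gap_windows,
                  min_length_mb = min_length_mb, maf_min = maf_min,
                  min_spacing_bp = min_spacing_bp, he_samples = he_samples,
                  seed = seed,
                  q15 = uni$q15, t_universal = uni$t_universal,
                  t_universal_2 = uni$t_universal_2)),
    class = "ibd_scan")
}

#' Scan pairs spanning two datasets (across-search)
#'
#' Matches the two filesets' markers by chromosome, position and allele pair
#' (a ref/alt swap is reconciled by flipping dosages; any other allele
#' combination is dropped with a message, never strand-guessed), then runs
#' [ibd_scan()] restricted to inter-dataset pairs on the marker
#' intersection. Typical use: one or a few query samples against a
#' database.
#'
#' @param g1,g2 two [genotype_matrix()] objects (query, database).
#' @param ... passed to [ibd_scan()].
#' @return an `ibd_scan` object covering only inter-dataset pairs.
#' @export
ibd_scan_across <- function(g1, g2, ...) {
  stopifnot(inherits(g1, "genotype_matrix"), inherits(g2, "genotype_matrix"))
  k1 <- paste(g1$markers$chrom, g1$markers$pos)
  k2 <- paste(g2$markers$chrom, g2$markers$pos)
  j <- match(k1, k2)
  keep1 <- which(!is.na(j))
  if (!length(keep1)) stop("the two filesets share no markers")
  keep2 <- j[keep1]
  m1 <- g1$markers[keep1, , drop = FALSE]
  m2 <- g2$markers[keep2, , drop = FALSE]
  same <- m1$a1 == m2$a1 & m1$a2 == m2$a2
  swap <- m1$a1 == m2$a2 & m1$a2 == m2$a1
  bad <- !(same | swap)
  if (any(bad))
    message(sum(bad), " shared position(s) with incompatible alleles ",
            "dropped (possible strand flips are not guessed)")
  keep1 <- keep1[!bad]
  keep2 <- keep2[!bad]
  swap <- swap[!bad]
  if (!length(keep1)) stop("the two filesets share no markers")
  if (length(keep1) < 10000)
    warning("marker intersection below 10,000 markers (",
            length(keep1), "); results may be unreliable")
  dup <- intersect(g1$samples, g2$samples)
  s2 <- g2$samples
  if (length(dup)) s2[s2 %in% dup] <- paste0(s2[s2 %in% dup], ".db")
  c2 <- g2$codes[keep2, , drop = FALSE]
  if (any(swap)) c2[swap, ] <- 2L - c2[swap, , drop = FALSE]
  g <- genotype_matrix(cbind(g1$codes[keep1, , drop = FALSE], c2),
                       g1$markers[keep1, , drop = FALSE],
                       c(g1$samples, s2))
  pairs <- expand.grid(sample1 = g1$samples, sample2 = s2,
                       stringsAsFactors = FALSE)
  ibd_scan(g, pairs = pairs, ...)
}

#' @export
print.ibd_scan <- function(x, ...) {
  cat("ibd_scan:", length(x$samples), "samples,", nrow(x$kinship),
      "pair(s),", x$n_markers, "markers,", nrow(x$windows), "windows\n")
  cat(sprintf("  analysed genome: %.1f Mb; t_universal = %.4g, t_universal_2 = %.4g\n",
              x$l_genome_mb, x$params$t_universal, x$params$t_universal_2))
  cat("  segments called:", nrow(x$segments),
      sprintf("(IBD1: %d, IBD2: %d)\n",
              sum(x$segments$type == "IBD1"),
              sum(x$segments$type == "IBD2")))
  rel <- x$kinship$degree != "unrelated"
  cat("  related pairs:", sum(rel), "of", nrow(x$kinship), "\n")
  invisible(x)
}

#' @export
summary.ibd_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.ibd_scan")
}

#' @export
print.summary.ibd_scan <- function(x, ...) {
  print(x$scan)
  cat("\nKinship results:\n")
  print(x$scan$kinship, row.names = FALSE, digits = 4)
  if (nrow(x$scan$segments)) {
    cat("\nSegments:\n")
    print(x$scan$segments, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot a pair's windowed rate profile and called segments
#'
#' Shows the per-window opposite-homozygote rate (IBD1 channel) or mismatch
#' rate (IBD2 channel) along the genome, the pair's final threshold, and the
#' called segments as shaded bars.
#'
#' @param x an `ibd_scan` object.
#' @param g the [genotype_matrix()] the scan was run on (profiles are
#'   recomputed, not stored, to keep the object small).
#' @param sample1,sample2 the pair to plot; defaults to the first scanned
#'   pair.
#' @param channel `"IBD1"` (opposite-homozygote rates) or `"IBD2"`
#'   (mismatch rates).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted profile data.frame.
#' @export
plot.ibd_scan <- function(x, g, sample1 = NULL, sample2 = NULL,
                          channel = c("IBD1", "IBD2"), ...) {
  channel <- match.arg(channel)
  if (is.null(sample1)) {
    sample1 <- x$thresholds$sample1[1]
    sample2 <- x$thresholds$sample2[1]
  }
  g <- filter_markers(g, maf_min = x$params$maf_min, autosomes_only = TRUE,
                      min_spacing_bp = x$params$min_spacing_bp)
  prof <- pair_window_profile(g, sample1, sample2, x$windows)
  rate <- if (channel == "IBD1") prof$r_ohg else prof$r_mismatch
  thr_row <- x$thresholds[x$thresholds$sample1 == sample1 &
                            x$thresholds$sample2 == sample2, ]
  thr <- if (channel == "IBD1") thr_row$t_final_ibd1 else thr_row$t_final_ibd2
  graphics::plot(x$windows$window, rate, pch = 16, cex = 0.4,
                 col = ifelse(!is.na(rate) & rate < thr, "firebrick",
                              "grey40"),
                 xlab = "window", ylab = if (channel == "IBD1")
                   expression(R[ohg]) else expression(R[mismatch]),
                 main = paste(sample1, "vs", sample2, "-", channel), ...)
  graphics::abline(h = thr, col = "steelblue", lty = 2)
  seg <- x$segments[x$segments$sample1 == sample1 &
                      x$segments$sample2 == sample2 &
                      x$segments$type == channel, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    wc <- x$windows[x$windows$chrom == seg$chromosome[i], ]
    wsel <- wc$window[wc$end_bp >= seg$start_bp[i] &
                        wc$start_bp <= seg$end_bp[i]]
    graphics::rect(min(wsel), -0.02, max(wsel), 0,
                   col = "firebrick", border = NA)
  }
  invisible(prof)
}
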