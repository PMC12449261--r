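#' Construct a genotype matrix
#'
#' The central container for unphased diploid genotypes: an integer matrix of
#' alternative-allele dosage codes with markers in rows and samples in
#' columns, together with a marker table. Codes count copies of the marker's
#' `a1` allele (the first allele column of a PLINK bim file), so `0` is
#' homozygous `a2`, `1` heterozygous and `2` homozygous `a1`; missing
#' genotypes are `NA`. Opposite-homozygosity and mismatch rates are invariant
#' to this orientation.
#'
#' @param codes integer matrix, markers x samples, values in `{0, 1, 2, NA}`.
#' @param markers data.frame with columns `chrom`, `id`, `pos`, `a1`, `a2`
#'   (and optionally `maf`), one row per row of `codes`. Within each
#'   chromosome positions must be strictly increasing.
#' @param samples character vector of sample identifiers, one per column of
#'   `codes`.
#' @return An object of class `genotype_matrix`.
#' @seealso [read_plink()], [filter_markers()], [marker_maf()]
#' @export
genotype_matrix <- function(codes, markers, samples) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  samples <- as.character(samples)
  stopifnot(is.data.frame(markers),
            all(c("chrom", "id", "pos", "a1", "a2") %in% names(markers)))
  if (nrow(markers) != nrow(codes))
    stop("markers table and codes matrix disagree on marker count")
  if (length(samples) != ncol(codes))
    stop("sample vector and codes matrix disagree on sample count")
  if (anyDuplicated(samples))
    stop("duplicated sample identifiers")
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ",
           ch)
  }
  rownames(markers) <- NULL
  dimnames(codes) <- list(NULL, samples)
  structure(list(codes = codes, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$markers), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Minor allele frequencies estimated from the data
#'
#' The frequency of each marker's `a1` allele is estimated from non-missing
#' genotypes as `mean(code) / 2`; the MAF is the smaller of that frequency
#' and its complement. Markers with no non-missing genotypes get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of per-marker MAF values in `[0, 0.5]`.
#' @export
marker_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- rowMeans(g$codes, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Filter markers by frequency, chromosome and spacing
#'
#' Applies the standard marker filters for the opposite-homozygote scan:
#' bi-allelic autosomal SNPs with MAF strictly above `maf_min` (monomorphic
#' markers are removed regardless of `maf_min`), optionally thinned so that
#' consecutive retained markers are at least `min_spacing_bp` apart (greedy
#' left-to-right thinning per chromosome). Marker order is preserved. When
#' the marker table has no `maf` column, frequencies are estimated from the
#' data itself via [marker_maf()].
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (exclusive); default 0.05.
#' @param autosomes_only drop markers not on chromosomes 1-22; default TRUE.
#' @param min_spacing_bp minimum bp distance between consecutive retained
#'   markers; 0 (default) disables thinning.
#' @param use_stored_maf use the `maf` column of the marker table when
#'   present instead of re-estimating; default FALSE (dataset-estimated).
#' @return the filtered [genotype_matrix()].
#' @export
filter_markers <- function(g, maf_min = 0.05, autosomes_only = TRUE,
                           min_spacing_bp = 0, use_stored_maf = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  maf <- if (use_stored_maf && !is.null(g$markers$maf)) g$markers$maf
         else marker_maf(g)
  keep <- !is.na(maf) & maf > maf_min & maf > 0
  if (autosomes_only) keep <- keep & .is_autosome(g$markers$chrom)
  if (min_spacing_bp > 0) {
    idx <- which(keep)
    if (length(idx)) {
      ch <- g$markers$chrom[idx]
      pos <- g$markers$pos[idx]
      thin <- logical(length(idx))
      last_ch <- ""
      last_pos <- -Inf
      for (i in seq_along(idx)) {
        if (ch[i] != last_ch || pos[i] - last_pos >= min_spacing_bp) {
          thin[i] <- TRUE
          last_ch <- ch[i]
          last_pos <- pos[i]
        }
      }
      keep[idx[!thin]] <- FALSE
    }
  }
  if (!any(keep))
    stop("no markers left after filtering (empty panel)")
  out <- genotype_matrix(g$codes[keep, , drop = FALSE],
                         g$markers[keep, , drop = FALSE], g$samples)
  out$markers$maf <- maf[keep]
  out
}
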