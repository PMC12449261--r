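# Kinship coefficients and relationship-degree classification.
#
# theta = k2/2 + k1/4 with k1, k2 the proportions of the analysed genome
# shared IBD1 and IBD2. Reported IBD2 segments take precedence where they
# overlap IBD1 calls (the overlap counts once, as IBD2), so k1 + k2 <= 1.

.DEGREE_LABELS <- c("identical", "1st", "2nd", "3rd", "4th", "5th", "6th",
                    "7th", "unrelated")

#' Analysed genome length from a marker set
#'
#' Sum over autosomes of the spanned length (last minus first marker
#' position) in Mb. Only the marker-covered span is observable, so physical
#' chromosome lengths are not used. A chromosome carrying a single marker
#' contributes zero, with a warning.
#'
#' @param markers marker data.frame with columns `chrom` and `pos`.
#' @return genome length in Mb.
#' @export
genome_length <- function(markers) {
  if (is.null(markers) || nrow(markers) == 0)
    stop("empty marker set")
  spans <- vapply(split(markers$pos, markers$chrom), function(p) {
    if (length(p) < 2) {
      warning("chromosome with a single marker contributes zero length")
      return(0)
    }
    max(p) - min(p)
  }, numeric(1))
  sum(spans) / 1e6
}

#' Kinship coefficient from summed IBD lengths
#'
#' `theta = L_ibd2 / (2 L_genome) + L_ibd1 / (4 L_genome)`.
#'
#' @param l_ibd1_mb,l_ibd2_mb summed IBD1 / IBD2 lengths (Mb), already
#'   de-duplicated so their sum is at most `l_genome_mb`.
#' @param l_genome_mb analysed genome length (Mb), see [genome_length()].
#' @return theta in `[0, 0.5]`.
#' @export
kinship_coefficient <- function(l_ibd1_mb, l_ibd2_mb, l_genome_mb) {
  if (any(l_genome_mb <= 0)) stop("genome length must be positive")
  if (any(l_ibd1_mb < 0 | l_ibd2_mb < 0)) stop("negative IBD length")
  l_ibd2_mb / (2 * l_genome_mb) + l_ibd1_mb / (4 * l_genome_mb)
}

#' Classify the degree of relatedness from theta
#'
#' KING-style power-of-two cutoffs: identical (monozygotic twin or same
#' sample) when `theta >= 2^(-3/2)`; degree `d` (1..7) when `theta` lies in
#' the half-open interval `(2^(-(2d+3)/2), 2^(-(2d+1)/2)]`; unrelated when
#' `theta <= 2^(-17/2)`. Upper boundaries are inclusive so every value of
#' theta maps to exactly one label.
#'
#' @param theta kinship coefficient(s) in `[0, 1]`.
#' @return character vector of labels among `"identical"`, `"1st"` ..
#'   `"7th"`, `"unrelated"`.
#' @export
classify_degree <- function(theta) {
  if (any(is.na(theta)) || any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]")
  cuts <- 2^(-(2 * (1:8) + 1) / 2)     # 2^-3/2 ... 2^-17/2
  vapply(theta, function(t) {
    if (t >= cuts[1]) return("identical")
    for (d in 1:7) if (t > cuts[d + 1]) return(.DEGREE_LABELS[d + 1])
    "unrelated"
  }, character(1))
}

#' Kinship result for one pair from its segment list
#'
#' Sums IBD2 segment lengths, sums IBD1 lengths after subtracting any bp
#' overlapped by the pair's IBD2 calls (the overlap counts once, as IBD2),
#' computes `k1`, `k2`, theta and the degree label.
#'
#' @param segments segment data.frame for one pair (may be empty; columns as
#'   produced by [detect_pair()]).
#' @param markers marker data.frame defining the analysed genome (or pass
#'   `l_genome_mb` directly).
#' @param l_genome_mb analysed genome length in Mb; computed from `markers`
#'   when missing.
#' @return one-row data.frame: `sample1`, `sample2`, `L_ibd1_mb`,
#'   `L_ibd2_mb`, `k1`, `k2`, `theta`, `degree`.
#' @export
pair_kinship <- function(segments, markers = NULL, l_genome_mb = NULL) {
  if (is.null(l_genome_mb)) l_genome_mb <- genome_length(markers)
  s1 <- if (nrow(segments)) segments$sample1[1] else NA_character_
  s2 <- if (nrow(segments)) segments$sample2[1] else NA_character_
  l1 <- 0
  l2 <- 0
  for (ch in unique(segments$chromosome)) {
    sc <- segments[segments$chromosome == ch, , drop = FALSE]
    ibd1 <- sc[sc$type == "IBD1", c("start_bp", "end_bp"), drop = FALSE]
    ibd2 <- sc[sc$type == "IBD2", c("start_bp", "end_bp"), drop = FALSE]
    names(ibd1) <- names(ibd2) <- c("start", "end")
    u2 <- .merge_intervals(ibd2)
    l2 <- l2 + (if (nrow(u2)) sum(u2[, 2] - u2[, 1]) else 0)
    u1 <- .merge_intervals(ibd1)
    if (nrow(u1)) {
      raw <- sum(u1[, 2] - u1[, 1])
      cut <- sum(vapply(seq_len(nrow(u1)), function(i)
        .overlap_len(u1[i, 1], u1[i, 2], u2), numeric(1)))
      l1 <- l1 + raw - cut
    }
  }
  l1 <- l1 / 1e6
  l2 <- l2 / 1e6
  theta <- kinship_coefficient(l1, l2, l_genome_mb)
  data.frame(sample1 = s1, sample2 = s2,
             L_ibd1_mb = l1, L_ibd2_mb = l2,
             k1 = l1 / l_genome_mb, k2 = l2 / l_genome_mb,
             theta = theta, degree = classify_degree(min(theta, 1)),
             stringsAsFactors = FALSE)
}
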