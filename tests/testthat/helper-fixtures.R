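# Small in-code fixtures shared across test files.

# hand-built genotype matrix: m markers on one chromosome, n samples
tiny_genotypes <- function(codes, chrom = "1", pos = NULL) {
  codes <- as.matrix(codes)
  m <- nrow(codes)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  genotype_matrix(
    codes,
    data.frame(chrom = chrom, id = paste0("rs", seq_len(m)), pos = pos,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE),
    sprintf("S%02d", seq_len(ncol(codes))))
}

# random genotype matrix with missingness, for property tests
random_genotypes <- function(m, n, miss = 0.05) {
  codes <- matrix(sample(0:2, m * n, replace = TRUE), m, n)
  codes[runif(m * n) < miss] <- NA
  tiny_genotypes(codes)
}

# brute-force per-site profile oracle: direct loop over marker ranges
naive_pair_profile <- function(g, a, b, windows) {
  va <- g$codes[, match(a, g$samples)]
  vb <- g$codes[, match(b, g$samples)]
  t(vapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$marker_lo[i]:windows$marker_hi[i]
    ncmp <- 0; nopp <- 0; nmis <- 0
    for (k in idx) {
      if (is.na(va[k]) || is.na(vb[k])) next
      ncmp <- ncmp + 1
      if ((va[k] == 0 && vb[k] == 2) || (va[k] == 2 && vb[k] == 0))
        nopp <- nopp + 1
      if (va[k] != vb[k]) nmis <- nmis + 1
    }
    c(r_ohg = if (ncmp) nopp / ncmp else NA_real_,
      r_mismatch = if (ncmp) nmis / ncmp else NA_real_)
  }, numeric(2)))
}

# segment data.frame shorthand for metric tests
seg_df <- function(start_mb, end_mb, s1 = "A", s2 = "B", chrom = "1",
                   type = "IBD1") {
  data.frame(sample1 = s1, sample2 = s2, chromosome = chrom,
             start_bp = start_mb * 1e6, end_bp = end_mb * 1e6,
             length_mb = end_mb - start_mb, type = type,
             n_windows = NA_integer_, stringsAsFactors = FALSE)
}

# brute-force interval metrics oracle on bp intervals
oracle_metrics <- function(truth, reported) {
  olap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  key <- function(df) paste(pmin(df$sample1, df$sample2),
                            pmax(df$sample1, df$sample2), df$chromosome)
  kt <- key(truth); kr <- key(reported)
  best_t <- sapply(seq_len(nrow(truth)), function(i) {
    js <- which(kr == kt[i])
    if (!length(js)) return(0)
    max(sapply(js, function(j) olap(truth$start_bp[i], truth$end_bp[i],
                                    reported$start_bp[j], reported$end_bp[j])))
  })
  best_r <- sapply(seq_len(nrow(reported)), function(j) {
    is <- which(kt == kr[j])
    if (!length(is)) return(0)
    max(sapply(is, function(i) olap(truth$start_bp[i], truth$end_bp[i],
                                    reported$start_bp[j], reported$end_bp[j])))
  })
  lt <- truth$end_bp - truth$start_bp
  lr <- reported$end_bp - reported$start_bp
  c(recall = mean(best_t / lt >= 0.5), power = sum(best_t) / sum(lt),
    accuracy = mean(best_r / lr >= 0.5),
    len_accuracy = sum(best_r) / sum(lr))
}
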