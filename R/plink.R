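# PLINK 1 binary fileset codec (bed/bim/fam).
#
# bed layout: 3 header bytes (0x6c 0x1b, then 0x01 for SNP-major), followed
# by ceiling(n_samples / 4) bytes per marker. Each byte packs 4 samples,
# lowest-order bit pair first:
#   00 -> homozygous A1 (code 2)   10 -> heterozygous (code 1)
#   11 -> homozygous A2 (code 0)   01 -> missing      (NA)

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))

# 2-bit value -> dosage of the A1 allele
.bed_decode_tab <- c(2L, NA_integer_, 1L, 0L)
# dosage (0,1,2,NA) -> 2-bit value
.bed_encode <- function(code) {
  out <- integer(length(code))
  out[is.na(code)] <- 1L
  out[!is.na(code) & code == 0L] <- 3L
  out[!is.na(code) & code == 1L] <- 2L
  out[!is.na(code) & code == 2L] <- 0L
  out
}

#' Read a PLINK binary genotype fileset
#'
#' Reads `<prefix>.bed`, `<prefix>.bim` and `<prefix>.fam` (SNP-major bed
#' variant) into a [genotype_matrix()]. Genotype codes count copies of the
#' bim file's first (A1) allele; missing genotypes become `NA`. Samples are
#' identified by the fam IID column (prefixed with the FID when IIDs are not
#' unique).
#'
#' @param prefix path prefix of the fileset (no extension).
#' @return a [genotype_matrix()] with samples and markers in file order.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam) < 2) stop("malformed fam file: ", paths[3])
  samples <- as.character(fam[[2]])
  if (anyDuplicated(samples))
    samples <- paste(as.character(fam[[1]]), samples, sep = "_")

  n <- length(samples)
  m <- nrow(bim)
  bpm <- ceiling(n / 4)          # bytes per marker
  sz <- file.size(paths[1])
  raw <- readBin(paths[1], what = "raw", n = sz)
  if (length(raw) < 3 || raw[1] != .BED_MAGIC[1] || raw[2] != .BED_MAGIC[2])
    stop("not a PLINK bed file (bad magic bytes): ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", paths[1])
  if (length(raw) != 3 + bpm * m)
    stop("bed/bim/fam size mismatch: expected ", 3 + bpm * m,
         " bytes in ", paths[1], ", found ", length(raw))

  body <- as.integer(raw[-(1:3)])
  bytes <- matrix(body, nrow = bpm, ncol = m)
  codes <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bpm)
    rows <- rows[rows <= n]
    if (!length(rows)) break
    nb <- length(rows)
    two_bit <- (bytes[seq_len(nb), , drop = FALSE] %/% 4L^(k - 1L)) %% 4L
    codes[rows, ] <- .bed_decode_tab[two_bit + 1L]
  }
  genotype_matrix(t(codes), bim[, c("chrom", "id", "pos", "a1", "a2")],
                  samples)
}

#' Write a PLINK binary genotype fileset
#'
#' Writes a [genotype_matrix()] as `<prefix>.bed` (SNP-major), `.bim` and
#' `.fam`. The inverse of [read_plink()]; mainly used to materialise
#' simulated panels and test fixtures.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$samples)
  m <- nrow(g$markers)
  bpm <- ceiling(n / 4)

  two_bit <- matrix(1L, nrow = 4 * bpm, ncol = m)   # pad = missing
  two_bit[seq_len(n), ] <- matrix(.bed_encode(as.integer(t(g$codes))),
                                  nrow = n, ncol = m)
  w <- 4L^(0:3)
  bytes <- matrix(0L, nrow = bpm, ncol = m)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bpm)
    bytes <- bytes + two_bit[rows, , drop = FALSE] * w[k]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.BED_MAGIC, as.raw(0x01), as.raw(as.vector(bytes))), con)

  bim <- data.frame(chrom = g$markers$chrom, id = g$markers$id, cm = 0,
                    pos = format(g$markers$pos, scientific = FALSE,
                                 trim = TRUE),
                    a1 = g$markers$a1, a2 = g$markers$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$samples, iid = g$samples, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
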