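# End-to-end detection and the ibd_scan interface

test_that("an injected 20-Mb IBD1 segment is recovered at 1% error", {
  p <- sim_panel(12, default_chrom_spec(2, 100), 140, seed = 71)
  inj <- inject_ibd1(p, "S001", "S002", "1", 30e6, 50e6)
  g <- apply_errors(as_genotypes(inj$panel), 0.01, seed = 72)
  sc <- ibd_scan(g, pairs = data.frame(sample1 = "S001", sample2 = "S002"),
                 seed = 73)
  seg <- sc$segments[sc$segments$type == "IBD1", ]
  best <- max(0, pmin(seg$end_bp, 50e6) - pmax(seg$start_bp, 30e6))
  expect_gte(best / 20e6, 0.9)
})

test_that("a duplicate pair is called IBD2 over at least 90% of the genome", {
  p <- sim_panel(12, default_chrom_spec(2, 100), 140, seed = 74)
  p$h1[, 2] <- p$h1[, 1]
  p$h2[, 2] <- p$h2[, 1]
  g <- apply_errors(as_genotypes(p), 0.05, seed = 75)
  sc <- ibd_scan(g, pairs = data.frame(sample1 = "S001", sample2 = "S002"),
                 seed = 76)
  ibd2 <- sc$segments[sc$segments$type == "IBD2", ]
  expect_gte(sum(ibd2$length_mb), 0.9 * sc$l_genome_mb)
  expect_equal(sc$kinship$degree, "identical")
  # nearly all windows fall below the pair's final IBD1 threshold too
  prof <- pair_window_profile(
    filter_markers(g), "S001", "S002", sc$windows)
  expect_gte(mean(prof$r_ohg < sc$thresholds$t_final_ibd1, na.rm = TRUE),
             0.95)
})

test_that("within-search scans all pairs and is deterministic under seed", {
  p <- sim_panel(4, default_chrom_spec(2, 60), 140, seed = 77)
  g <- as_genotypes(p)
  sc1 <- ibd_scan(g, seed = 78)
  expect_equal(nrow(sc1$kinship), 6)   # 4 choose 2
  sc2 <- ibd_scan(g, seed = 78)
  expect_identical(sc1$segments, sc2$segments)
  expect_identical(sc1$kinship, sc2$kinship)
  # byte-identical reports
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_segments(sc1$segments, f1)
  write_segments(sc2$segments, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a simulated parent-child pair is classified first degree", {
  founders <- sim_panel(6, default_chrom_spec(4, 80), 140, seed = 79)
  ped <- data.frame(id = c("P1", "P2", "C"), father = c(NA, NA, "P1"),
                    mother = c(NA, NA, "P2"))
  sim <- sim_pedigree(founders, ped, seed = 80)
  # add unrelated founders so the heterozygosity pool is not family-biased
  extra <- founders
  extra$samples <- sprintf("U%02d", seq_along(extra$samples))
  panel <- sim$panel
  panel$h1 <- cbind(panel$h1, extra$h1)
  panel$h2 <- cbind(panel$h2, extra$h2)
  panel$samples <- c(sim$panel$samples, extra$samples)
  g <- apply_errors(as_genotypes(panel), 0.01, seed = 81)
  sc <- ibd_scan(g, pairs = data.frame(sample1 = "P1", sample2 = "C"),
                 seed = 82)
  expect_equal(sc$kinship$degree, "1st")
  expect_gt(sc$kinship$theta, 2^(-5 / 2))
})

test_that("across-search restricts to inter-file pairs on shared markers", {
  p <- sim_panel(8, default_chrom_spec(2, 60), 140, seed = 83)
  g <- as_genotypes(p)
  split_g <- function(g, idx) genotype_matrix(g$codes[, idx, drop = FALSE],
                                              g$markers, g$samples[idx])
  g1 <- split_g(g, 1)        # one query sample
  g2 <- split_g(g, 2:8)      # database of 7
  sc <- suppressWarnings(ibd_scan_across(g1, g2, seed = 84))
  expect_equal(nrow(sc$kinship), 7)
  expect_true(all(sc$kinship$sample1 == "S001"))
})

test_that("across-search reconciles allele swaps and rejects strand clashes", {
  codes <- matrix(sample(0:2, 400 * 4, replace = TRUE), 400, 4)
  g1 <- tiny_genotypes(codes, pos = seq(2e4, by = 2e4, length.out = 400))
  g2 <- g1
  g2$samples <- c("T01", "T02", "T03", "T04")
  colnames(g2$codes) <- g2$samples
  # swap alleles (and flip dosages) for half the markers
  swap <- seq_len(200)
  g2$markers$a1[swap] <- "B"; g2$markers$a2[swap] <- "A"
  g2$codes[swap, ] <- 2L - g2$codes[swap, ]
  # an incompatible allele pair at one marker must be dropped
  g2$markers$a1[300] <- "C"
  prof_direct <- suppressWarnings(ibd_scan_across(
    g1, g2, maf_min = 0, seed = 85,
    snps_per_window = 30, min_length_mb = 1))
  expect_message(
    suppressWarnings(ibd_scan_across(g1, g2, maf_min = 0, seed = 85,
                                     snps_per_window = 30)),
    "incompatible")
  # the swapped copy of the same individual is recognised as identical
  kin <- prof_direct$kinship
  self <- kin[kin$sample1 == "S01" & kin$sample2 == "T01", ]
  expect_equal(self$degree, "identical")
  expect_error(suppressWarnings(
    ibd_scan_across(g1, tiny_genotypes(codes, chrom = "2",
                                       pos = seq(2e4, by = 2e4,
                                                 length.out = 400)))),
    "share no markers")
})

test_that("plot method runs silently on a scanned pair", {
  p <- sim_panel(4, default_chrom_spec(1, 60), 140, seed = 86)
  g <- as_genotypes(p)
  sc <- ibd_scan(g, pairs = data.frame(sample1 = "S001", sample2 = "S002"),
                 seed = 87)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sc, g, channel = "IBD1"))
})
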