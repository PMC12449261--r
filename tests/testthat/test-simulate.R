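# Panel generation, IBD injection, error model, pedigree simulation

test_that("panels are deterministic under seed with the stated density", {
  spec <- default_chrom_spec(2, 50)
  p1 <- sim_panel(10, spec, 140, seed = 51)
  p2 <- sim_panel(10, spec, 140, seed = 51)
  expect_identical(p1$h1, p2$h1)
  expect_identical(p1$markers$pos, p2$markers$pos)
  expect_equal(nrow(p1$markers), 2 * 50 * 140)
  expect_true(all(p1$markers$maf > 0.05 & p1$markers$maf <= 0.5))
  # thinning respected
  for (ch in unique(p1$markers$chrom))
    expect_true(all(diff(p1$markers$pos[p1$markers$chrom == ch]) >= 2000))
  expect_error(sim_panel(2, data.frame(chrom = "1", span_bp = 1e5),
                         snps_per_mb = 1000, seed = 1),
               "too small")
})

test_that("collapsed genotypes are valid and match Hardy-Weinberg", {
  p <- sim_panel(60, default_chrom_spec(1, 30), 140, seed = 52)
  g <- as_genotypes(p)
  expect_s3_class(g, "genotype_matrix")
  expect_true(all(g$codes %in% 0:2))
  # per-site heterozygosity ~ 2pq within 3 binomial SEs (averaged over sites)
  het <- rowMeans(g$codes == 1L)
  exp_he <- 2 * p$markers$maf * (1 - p$markers$maf)
  z <- (het - exp_he) / sqrt(exp_he * (1 - exp_he) / 60)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 3)
  expect_gt(mean(abs(z) < 3), 0.99)
})

test_that("IBD1 injection shares one haplotype; opposite homozygotes vanish", {
  p <- sim_panel(4, default_chrom_spec(1, 40), 140, seed = 53)
  inj <- inject_ibd1(p, "S001", "S002", "1", 10e6, 30e6)
  g <- as_genotypes(inj$panel)
  idx <- which(g$markers$pos >= 10e6 & g$markers$pos <= 30e6)
  a <- g$codes[idx, 1]; b <- g$codes[idx, 2]
  expect_false(any((a == 0 & b == 2) | (a == 2 & b == 0)))
  expect_equal(inj$truth$type, "IBD1")
  # idempotent
  inj2 <- inject_ibd1(inj$panel, "S001", "S002", "1", 10e6, 30e6)
  expect_identical(inj2$panel$h1, inj$panel$h1)
  expect_error(inject_ibd1(p, "S001", "S002", "1", 39.9999e6, 39.99995e6),
               "no markers")
  expect_error(inject_ibd1(p, "S001", "S001", "1", 1e6, 2e6))
})

test_that("outside the injected region opposite homozygotes occur at 2p2q2", {
  p <- sim_panel(2, default_chrom_spec(1, 60), 140, seed = 54)
  inj <- inject_ibd1(p, "S001", "S002", "1", 1e6, 10e6)
  g <- as_genotypes(inj$panel)
  out <- which(g$markers$pos > 10e6)
  a <- g$codes[out, 1]; b <- g$codes[out, 2]
  opp <- (a == 0 & b == 2) | (a == 2 & b == 0)
  q <- g$markers$maf[out]
  expected <- mean(2 * q^2 * (1 - q)^2)
  se <- sqrt(expected / length(out))
  expect_lt(abs(mean(opp) - expected), 4 * se)
})

test_that("IBD2 injection makes genotypes identical over the region", {
  p <- sim_panel(4, default_chrom_spec(1, 40), 140, seed = 55)
  inj <- inject_ibd2(p, "S003", "S004", "1", 5e6, 25e6)
  g <- as_genotypes(inj$panel)
  idx <- which(g$markers$pos >= 5e6 & g$markers$pos <= 25e6)
  expect_identical(g$codes[idx, 3], g$codes[idx, 4])
  # heterozygosity of the recipient matches the donor in the region
  expect_identical(g$codes[idx, 3] == 1L, g$codes[idx, 4] == 1L)
})

test_that("error injection hits the requested rate and honours the mix", {
  p <- sim_panel(6, default_chrom_spec(1, 50), 140, seed = 56)
  g <- as_genotypes(p)
  expect_identical(apply_errors(g, 0, seed = 1)$codes, g$codes)
  # rate 1 with pure drop-in turns every homozygote heterozygous
  hom <- tiny_genotypes(matrix(c(0L, 2L, 0L, 2L), ncol = 1))
  e <- apply_errors(hom, 1, mix = c(1, 0, 0), seed = 2)
  expect_true(all(e$codes == 1L))
  # realised perturbation fraction within 3 binomial SEs of 5%
  e2 <- apply_errors(g, 0.05, seed = 3)
  n <- length(g$codes)
  frac <- mean(e2$codes != g$codes)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # determinism
  e3 <- apply_errors(g, 0.05, seed = 3)
  expect_identical(e3$codes, e2$codes)
  expect_error(apply_errors(g, 0.5, mix = c(0.5, 0.2, 0.2)), "mix")
})

test_that("error paths transform genotypes as defined", {
  het <- tiny_genotypes(matrix(rep(1L, 400), ncol = 1))
  e <- apply_errors(het, 1, mix = c(0, 1, 0), seed = 4)
  expect_true(all(e$codes %in% c(0L, 2L)))           # dropout: het -> hom
  expect_gt(mean(e$codes == 0L), 0.4)                # random hom choice
  hom <- tiny_genotypes(matrix(rep(c(0L, 2L), 200), ncol = 1))
  e2 <- apply_errors(hom, 1, mix = c(0, 0, 1), seed = 5)
  expect_identical(e2$codes, 2L - hom$codes)         # opposite homozygote
  # inapplicable-only mix leaves the genotype unchanged
  e3 <- apply_errors(hom, 1, mix = c(0, 1, 0), seed = 6)
  expect_identical(e3$codes, hom$codes)
})

test_that("parent-child pairs share an allele at every marker", {
  founders <- sim_panel(2, default_chrom_spec(2, 40), 140, seed = 57)
  ped <- data.frame(id = c("P1", "P2", "C"), father = c(NA, NA, "P1"),
                    mother = c(NA, NA, "P2"))
  sim <- sim_pedigree(founders, ped, seed = 58)
  g <- as_genotypes(sim$panel)
  a <- g$codes[, "P1"]; b <- g$codes[, "C"]
  expect_false(any((a == 0 & b == 2) | (a == 2 & b == 0)))
  expect_equal(sim$relationships$degree[
    sim$relationships$sample1 == "P1" & sim$relationships$sample2 == "C"],
    "1st")
})

test_that("sibling realised IBD proportions approach (1/4, 1/2, 1/4)", {
  # founders with labelled haplotypes (h1 all 0, h2 all 1) make the
  # transmitted gamete identity directly readable from the child alleles
  spec <- default_chrom_spec(5, 100)
  founders <- sim_panel(2, spec, 20, seed = 59)
  founders$h1[] <- 0L
  founders$h2[] <- 1L
  ped <- data.frame(id = c("P1", "P2", "C1", "C2"),
                    father = c(NA, NA, "P1", "P1"),
                    mother = c(NA, NA, "P2", "P2"))
  set.seed(60)
  k <- replicate(60, {
    sim <- sim_pedigree(founders, ped)
    pa_same <- sim$panel$h1[, 3] == sim$panel$h1[, 4]
    ma_same <- sim$panel$h2[, 3] == sim$panel$h2[, 4]
    c(k2 = mean(pa_same & ma_same), k1 = mean(xor(pa_same, ma_same)))
  })
  expect_lt(abs(mean(k["k2", ]) - 0.25), 0.05)
  expect_lt(abs(mean(k["k1", ]) - 0.50), 0.06)
})

test_that("pedigree expected kinship follows the classical values", {
  founders <- sim_panel(4, default_chrom_spec(1, 20), 50, seed = 61)
  ped <- data.frame(
    id = c("A", "B", "C", "D", "E", "F"),
    father = c(NA, NA, "A", "A", NA, "C"),
    mother = c(NA, NA, "B", "B", NA, "E"))
  sim <- sim_pedigree(founders, ped, seed = 62)
  rel <- sim$relationships
  th <- function(x, y) rel$expected_theta[
    (rel$sample1 == x & rel$sample2 == y) |
      (rel$sample1 == y & rel$sample2 == x)]
  expect_equal(th("A", "C"), 1 / 4)    # parent-child
  expect_equal(th("C", "D"), 1 / 4)    # full siblings
  expect_equal(th("A", "F"), 1 / 8)    # grandparent-grandchild
  expect_equal(th("D", "F"), 1 / 8)    # avuncular
  expect_equal(th("A", "E"), 0)        # unrelated founders
  expect_equal(rel$degree[rel$sample1 == "A" & rel$sample2 == "F"], "2nd")
  # cyclic / unordered pedigrees are rejected
  bad <- data.frame(id = c("X", "Y"), father = c("Y", NA), mother = c("Y", NA))
  expect_error(sim_pedigree(founders, bad))
})
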