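# Synthetic panels, IBD injection, genotyping-error injection and a
# simplified pedigree simulator.
#
# Panels are drawn in linkage equilibrium: marker MAFs from a stated law and
# haplotype alleles i.i.d. Bernoulli(maf) given the MAF. MAF values are
# spatially autocorrelated along each chromosome (Gaussian-copula AR field,
# rank-reassigned so the marginal law is exactly maf_law): real genomes have
# strongly heterogeneous regional diversity, and the universal threshold is
# a low quantile of per-window heterozygosity, which is only a low quantile
# of the background rate distribution when window heterozygosity genuinely
# varies. See the methods vignette for what the panel does and does not
# emulate.

#' Default chromosome layout for simulation experiments
#'
#' @param n_chrom number of autosome-like chromosomes; default 10.
#' @param span_mb span of each chromosome in Mb; default 100.
#' @return data.frame with columns `chrom` and `span_bp`.
#' @export
default_chrom_spec <- function(n_chrom = 10, span_mb = 100) {
  data.frame(chrom = as.character(seq_len(n_chrom)),
             span_bp = rep(span_mb * 1e6, n_chrom))
}

#' Generate a synthetic haplotype panel
#'
#' Marker positions are uniform within each chromosome span, sorted, and
#' thinned so consecutive markers are at least `min_spacing_bp` apart; the
#' per-marker alternative-allele frequency is drawn from `maf_law`; the two
#' haplotypes of every sample carry i.i.d. Bernoulli(maf) alleles (linkage
#' equilibrium, Hardy-Weinberg genotype proportions after collapse).
#' Deterministic under `seed`.
#'
#' @param n_samples number of diploid samples.
#' @param chrom_spec data.frame with `chrom` and `span_bp` columns; default
#'   [default_chrom_spec()].
#' @param snps_per_mb target marker density; default 140 (roughly a 400k
#'   genome-wide SNP panel).
#' @param maf_law function of one argument `n` returning `n` allele
#'   frequencies in `(0, 0.5]`; default `Uniform(0.05, 0.5)`. This is the
#'   marginal law; see `maf_corr_length_mb`.
#' @param min_spacing_bp minimum distance between adjacent markers;
#'   default 2000.
#' @param maf_corr_length_mb optional correlation length (Mb) for spatial
#'   MAF autocorrelation along each chromosome; default 0 (independent
#'   per-marker MAF). When positive, the drawn MAF values are reassigned
#'   along the ranks of a Gaussian AR field with site-to-site correlation
#'   `exp(-distance / length)`, so the marginal distribution is exactly
#'   `maf_law` while regional diversity varies, for studying the effect of
#'   diversity heterogeneity on threshold selection.
#' @param seed RNG seed (optional).
#' @return an object of class `sim_panel`: haplotype matrices `h1`, `h2`
#'   (markers x samples, values 0/1), `markers`, `samples`.
#' @export
sim_panel <- function(n_samples, chrom_spec = default_chrom_spec(),
                      snps_per_mb = 140,
                      maf_law = function(n) stats::runif(n, 0.05, 0.5),
                      min_spacing_bp = 2000, maf_corr_length_mb = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 1, snps_per_mb > 0)
  marker_list <- vector("list", nrow(chrom_spec))
  for (ci in seq_len(nrow(chrom_spec))) {
    span <- chrom_spec$span_bp[ci]
    target <- round(span / 1e6 * snps_per_mb)
    pos <- sort(unique(round(stats::runif(3 * target, 1, span))))
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= min_spacing_bp) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
    pos <- pos[keep]
    if (length(pos) < target)
      stop("chromosome span too small for requested density after thinning")
    pos <- sort(sample(pos, target))
    marker_list[[ci]] <- data.frame(
      chrom = chrom_spec$chrom[ci],
      id = paste0(chrom_spec$chrom[ci], ":", pos),
      pos = pos, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, marker_list)
  maf <- maf_law(nrow(markers))
  if (any(maf <= 0 | maf > 0.5))
    stop("maf_law must return frequencies in (0, 0.5]")
  if (maf_corr_length_mb > 0) {
    # impose spatial rank autocorrelation, preserving the marginal draws
    z <- numeric(nrow(markers))
    for (ci in seq_len(nrow(chrom_spec))) {
      idx <- which(markers$chrom == chrom_spec$chrom[ci])
      d <- diff(markers$pos[idx]) / (maf_corr_length_mb * 1e6)
      rho <- exp(-d)
      zc <- numeric(length(idx))
      zc[1] <- stats::rnorm(1)
      if (length(idx) > 1) {
        eps <- stats::rnorm(length(idx) - 1)
        for (i in seq_along(rho))
          zc[i + 1] <- rho[i] * zc[i] + sqrt(1 - rho[i]^2) * eps[i]
      }
      z[idx] <- zc
    }
    maf <- sort(maf)[rank(z, ties.method = "first")]
  }
  markers$maf <- maf
  m <- nrow(markers)
  samples <- sprintf("S%03d", seq_len(n_samples))
  h1 <- matrix(stats::rbinom(m * n_samples, 1L, markers$maf),
               nrow = m, ncol = n_samples)
  h2 <- matrix(stats::rbinom(m * n_samples, 1L, markers$maf),
               nrow = m, ncol = n_samples)
  storage.mode(h1) <- storage.mode(h2) <- "integer"
  structure(list(h1 = h1, h2 = h2, markers = markers, samples = samples),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$samples), "samples x", nrow(x$markers),
      "markers on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Collapse a haplotype panel to unphased genotypes
#'
#' @param panel a [sim_panel()].
#' @return a [genotype_matrix()] of dosage codes `h1 + h2`.
#' @export
as_genotypes <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  genotype_matrix(panel$h1 + panel$h2, panel$markers, panel$samples)
}

.panel_region <- function(panel, chromosome, start_bp, end_bp) {
  idx <- which(panel$markers$chrom == as.character(chromosome) &
                 panel$markers$pos >= start_bp & panel$markers$pos <= end_bp)
  if (length(idx) == 0)
    stop("injection region contains no markers")
  idx
}

#' Inject an artificial IBD1 segment
#'
#' Copies one haplotype of sample `a` over the region into one haplotype of
#' sample `b`, so the two samples share exactly one haplotype there. The
#' phase is subsequently discarded (all analysis uses collapsed genotypes).
#' Injection is idempotent.
#'
#' @param panel a [sim_panel()].
#' @param a,b distinct sample identifiers (donor, recipient).
#' @param chromosome,start_bp,end_bp region to share.
#' @return list with elements `panel` (modified) and `truth` (a one-row
#'   ground-truth data.frame: `sample1`, `sample2`, `chromosome`,
#'   `start_bp`, `end_bp`, `type`).
#' @export
inject_ibd1 <- function(panel, a, b, chromosome, start_bp, end_bp) {
  stopifnot(inherits(panel, "sim_panel"), a != b, start_bp < end_bp)
  ia <- match(a, panel$samples)
  ib <- match(b, panel$samples)
  if (is.na(ia) || is.na(ib)) stop("unknown sample identifier")
  idx <- .panel_region(panel, chromosome, start_bp, end_bp)
  panel$h1[idx, ib] <- panel$h1[idx, ia]
  list(panel = panel,
       truth = data.frame(sample1 = a, sample2 = b,
                          chromosome = as.character(chromosome),
                          start_bp = start_bp, end_bp = end_bp,
                          type = "IBD1", stringsAsFactors = FALSE))
}

#' Inject an artificial IBD2 segment
#'
#' As [inject_ibd1()] but both haplotypes are copied, so genotypes are
#' identical over the region.
#'
#' @inheritParams inject_ibd1
#' @return list with `panel` and `truth` (type `"IBD2"`).
#' @export
inject_ibd2 <- function(panel, a, b, chromosome, start_bp, end_bp) {
  stopifnot(inherits(panel, "sim_panel"), a != b, start_bp < end_bp)
  ia <- match(a, panel$samples)
  ib <- match(b, panel$samples)
  if (is.na(ia) || is.na(ib)) stop("unknown sample identifier")
  idx <- .panel_region(panel, chromosome, start_bp, end_bp)
  panel$h1[idx, ib] <- panel$h1[idx, ia]
  panel$h2[idx, ib] <- panel$h2[idx, ia]
  list(panel = panel,
       truth = data.frame(sample1 = a, sample2 = b,
                          chromosome = as.character(chromosome),
                          start_bp = start_bp, end_bp = end_bp,
                          type = "IBD2", stringsAsFactors = FALSE))
}

#' Named genotyping-error mixes
#'
#' `"default"` is an even split between drop-in and dropout with a small
#' opposite-homozygote component; `"low_input"` is dropout-dominated (as for
#' very low DNA input) and `"degraded"` drop-in-dominated (as for highly
#' fragmented DNA).
#'
#' @param name one of `"default"`, `"low_input"`, `"degraded"`.
#' @return named numeric vector `(p_dropin, p_dropout, p_opphom)`.
#' @export
error_mix <- function(name = c("default", "low_input", "degraded")) {
  switch(match.arg(name),
         default = c(p_dropin = 0.45, p_dropout = 0.45, p_opphom = 0.10),
         low_input = c(p_dropin = 0.15, p_dropout = 0.80, p_opphom = 0.05),
         degraded = c(p_dropin = 0.80, p_dropout = 0.15, p_opphom = 0.05))
}

#' Perturb genotypes with random genotyping errors
#'
#' Each non-missing genotype is independently perturbed with probability
#' `rate`. A perturbed genotype takes one of three error paths: drop-in
#' (homozygote reported as heterozygote), dropout (heterozygote reported as
#' a random homozygote) or opposite-homozygote (one homozygote reported as
#' the other), drawn from `mix` renormalised over the paths applicable to
#' the genotype (drop-in and opposite-homozygote apply to homozygotes,
#' dropout to heterozygotes). If no applicable path has positive weight the
#' genotype is left unchanged. Deterministic under `seed`.
#'
#' @param g a [genotype_matrix()].
#' @param rate per-genotype error probability in `[0, 1]`.
#' @param mix length-3 numeric `(p_dropin, p_dropout, p_opphom)`, summing
#'   to 1; default [error_mix()]`("default")`.
#' @param seed RNG seed (optional).
#' @return the perturbed [genotype_matrix()].
#' @export
apply_errors <- function(g, rate, mix = error_mix("default"), seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), rate >= 0, rate <= 1)
  if (length(mix) != 3 || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix must be three non-negative probabilities summing to 1")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(g)
  codes <- g$codes
  cand <- which(!is.na(codes))
  hit <- cand[stats::runif(length(cand)) < rate]
  if (length(hit)) {
    v <- codes[hit]
    hom <- v != 1L
    # homozygotes: drop-in vs opposite-homozygote, renormalised
    ph <- mix[1] + mix[3]
    if (any(hom) && ph > 0) {
      hidx <- hit[hom]
      dropin <- stats::runif(length(hidx)) < mix[1] / ph
      codes[hidx[dropin]] <- 1L
      flip <- hidx[!dropin]
      codes[flip] <- 2L - codes[flip]
    }
    # heterozygotes: dropout to a random homozygote
    if (any(!hom) && mix[2] > 0) {
      eidx <- hit[!hom]
      codes[eidx] <- 2L * stats::rbinom(length(eidx), 1L, 0.5)
    }
  }
  g$codes <- codes
  g
}

#' Simulate a pedigree from founder haplotypes
#'
#' Children are built by a simplified gamete model: each transmitted
#' haplotype is a mosaic of the parent's two haplotypes with crossover
#' points drawn as a Poisson process along physical position at a constant
#' rate (default 0.01 crossovers/Mb, approximately 1 cM/Mb) and a random
#' starting haplotype per chromosome. Relationship degrees come from the
#' pedigree itself (expected kinship by the tabular method), not from
#' realised sharing.
#'
#' @param founders a [sim_panel()] providing one sample per pedigree
#'   founder, in `pedigree$id` order of founders.
#' @param pedigree data.frame with columns `id`, `father`, `mother`
#'   (`NA` parents for founders); parents must be listed before children.
#' @param recomb_rate_per_mb crossover intensity; default 0.01.
#' @param seed RNG seed (optional).
#' @return list with `panel` (a [sim_panel()] holding every pedigree member,
#'   founders first) and `relationships` (data.frame `sample1`, `sample2`,
#'   `expected_theta`, `degree` for every pair).
#' @export
sim_pedigree <- function(founders, pedigree, recomb_rate_per_mb = 0.01,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(founders, "sim_panel"),
            all(c("id", "father", "mother") %in% names(pedigree)))
  ids <- as.character(pedigree$id)
  fa <- as.character(pedigree$father)
  mo <- as.character(pedigree$mother)
  is_founder <- is.na(fa) & is.na(mo)
  if (any(is.na(fa) != is.na(mo)))
    stop("individuals must have either both parents or neither")
  pi <- match(fa, ids)
  mi <- match(mo, ids)
  if (any(!is_founder & (is.na(pi) | is.na(mi))))
    stop("parent not found in pedigree")
  for (i in which(!is_founder))
    if (pi[i] >= i || mi[i] >= i)
      stop("pedigree must list parents before children (acyclic order)")
  nf <- sum(is_founder)
  if (length(founders$samples) < nf)
    stop("founder panel has fewer samples than pedigree founders")

  m <- nrow(founders$markers)
  n <- length(ids)
  h1 <- matrix(0L, m, n)
  h2 <- matrix(0L, m, n)
  h1[, is_founder] <- founders$h1[, seq_len(nf)]
  h2[, is_founder] <- founders$h2[, seq_len(nf)]

  chrom <- founders$markers$chrom
  pos <- founders$markers$pos
  chrom_idx <- split(seq_len(m), chrom)

  gamete <- function(p1, p2) {
    out <- integer(m)
    for (idx in chrom_idx) {
      span_mb <- (max(pos[idx]) - min(pos[idx])) / 1e6
      nx <- stats::rpois(1, recomb_rate_per_mb * span_mb)
      xo <- sort(stats::runif(nx, min(pos[idx]), max(pos[idx])))
      src <- (findInterval(pos[idx], xo) + stats::rbinom(1, 1, 0.5)) %% 2
      out[idx] <- ifelse(src == 0, p1[idx], p2[idx])
    }
    out
  }
  for (i in which(!is_founder)) {
    h1[, i] <- gamete(h1[, pi[i]], h2[, pi[i]])
    h2[, i] <- gamete(h1[, mi[i]], h2[, mi[i]])
  }

  panel <- structure(list(h1 = h1, h2 = h2, markers = founders$markers,
                          samples = ids), class = "sim_panel")

  # expected kinship by the tabular method (numerator relationship / 2)
  A <- diag(n)
  for (i in which(!is_founder)) {
    A[i, i] <- 1 + 0.5 * A[pi[i], mi[i]]
    for (j in seq_len(i - 1L)) {
      aij <- 0.5 * (A[pi[i], j] + A[mi[i], j])
      A[i, j] <- A[j, i] <- aij
    }
  }
  pairs <- utils::combn(n, 2)
  theta <- A[cbind(pairs[1, ], pairs[2, ])] / 2
  degree <- ifelse(theta <= 0, "unrelated", NA)
  nz <- theta > 0
  d <- round(-log2(theta[nz])) - 1
  degree[nz] <- ifelse(d < 1, "1st", ifelse(d > 7, "unrelated",
                                            .DEGREE_LABELS[d + 1]))
  rel <- data.frame(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
                    expected_theta = theta, degree = degree,
                    stringsAsFactors = FALSE)
  list(panel = panel, relationships = rel)
}
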