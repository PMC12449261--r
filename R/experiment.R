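#' Run a segment-injection benchmark experiment
#'
#' Reproduces the standard simulation design for benchmarking the detector:
#' generate a synthetic panel, inject one IBD1 segment of `len_mb` into each
#' of `n_pairs` disjoint unrelated pairs (random chromosome and start),
#' perturb genotypes at `error_rate` with the default error mix, scan the
#' injected pairs with the given detector settings, and score the reported
#' segments against the ground truth.
#'
#' @param n_pairs number of injected pairs (the panel holds `2 * n_pairs`
#'   samples).
#' @param len_mb injected segment length in Mb.
#' @param error_rate genotyping-error probability per genotype.
#' @param chrom_spec chromosome layout; default [default_chrom_spec()]
#'   (ten 100-Mb chromosomes).
#' @param snps_per_mb marker density; default 140.
#' @param seed RNG seed governing the panel, injection positions, errors and
#'   scan.
#' @param mix error mix; default [error_mix()]`("default")`.
#' @param ... detector overrides passed to [ibd_scan()].
#' @return list with `truth`, `segments`, `metrics` (see [ibd_metrics()]),
#'   `deviations` (see [breakpoint_deviation()]) and the `ibd_scan` object.
#' @export
injection_experiment <- function(n_pairs, len_mb, error_rate,
                                 chrom_spec = default_chrom_spec(),
                                 snps_per_mb = 140, seed = 1,
                                 mix = error_mix("default"), ...) {
  set.seed(seed)
  panel <- sim_panel(2 * n_pairs, chrom_spec, snps_per_mb,
                     seed = sample.int(2^31 - 1, 1))
  truths <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- panel$samples[2 * i - 1]
    b <- panel$samples[2 * i]
    ci <- sample.int(nrow(chrom_spec), 1)
    span <- chrom_spec$span_bp[ci]
    start <- round(stats::runif(1, 1e6, span - len_mb * 1e6 - 1e6))
    inj <- inject_ibd1(panel, a, b, chrom_spec$chrom[ci], start,
                       start + len_mb * 1e6)
    panel <- inj$panel
    truths[[i]] <- inj$truth
  }
  truth <- do.call(rbind, truths)
  g <- as_genotypes(panel)
  if (error_rate > 0)
    g <- apply_errors(g, error_rate, mix = mix,
                      seed = sample.int(2^31 - 1, 1))
  scan <- ibd_scan(g, pairs = truth[, c("sample1", "sample2")],
                   seed = sample.int(2^31 - 1, 1), ...)
  list(truth = truth, segments = scan$segments,
       metrics = ibd_metrics(truth, scan$segments),
       deviations = breakpoint_deviation(truth, scan$segments),
       scan = scan)
}
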