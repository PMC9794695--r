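#' Simulate low-coverage sequencing observations at markers
#'
#' Per marker, sequencing depth is Poisson with the configured mean; each
#' read picks one of the genome's haplotypes uniformly at random and reports
#' that haplotype's parental allele, flipped to the other parental allele
#' with probability `error_rate`. Reads are independent given depth, so the
#' count of P1-supporting reads is binomial given depth — sampled directly.
#'
#' An unrecombined tetraploid (two copies of each F1 haplotype) therefore
#' has the same expected 0.5/0.5 allelic signal at every marker as a diploid
#' clone: ploidy cannot be read off the landscape and must come from flow
#' cytometry.
#'
#' @param genome a `progeny_genome` with haplotypes defined at all markers.
#' @param markers marker map.
#' @param mean_depth Poisson mean reads per marker (study values: 1.9 for
#'   progeny, 14.3 for parents/F1).
#' @param error_rate probability a read reports the other parental allele,
#'   in `[0, 0.5)`; default 0.002.
#' @param seed optional RNG seed.
#' @return `data.frame` aligned to `markers`: `chrom`, `pos`, `depth`,
#'   `reads_P1`, `reads_P2`.
#' @export
simulate_reads <- function(genome, markers, mean_depth = 1.9,
                           error_rate = 0.002, seed = NULL) {
  assert_marker_map(markers)
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 0.5)
  set_seed_if(seed)
  n <- nrow(markers)
  if (length(genome$haplotypes[[1]]) != n) {
    stop("genome haplotypes are not aligned to the marker map", call. = FALSE)
  }
  # fraction of haplotypes carrying the P1 allele at each marker
  f_p1 <- Reduce(`+`, lapply(genome$haplotypes, function(h) h == 1L)) /
    genome$ploidy
  depth <- stats::rpois(n, mean_depth)
  p_read_p1 <- f_p1 * (1 - error_rate) + (1 - f_p1) * error_rate
  reads_p1 <- stats::rbinom(n, depth, p_read_p1)
  data.frame(chrom = markers$chrom, pos = markers$pos,
             depth = depth, reads_P1 = reads_p1,
             reads_P2 = depth - reads_p1,
             stringsAsFactors = FALSE)
}

#' Closed-form probability of observing both alleles at a heterozygous site
#'
#' Under Poisson(`lambda`) depth, error-free reads, and equal haplotype
#' sampling, the P1- and P2-read counts are independent Poisson(lambda/2),
#' so both alleles are seen with probability
#' `1 - 2 exp(-lambda/2) + exp(-lambda)` (~0.376 at lambda = 1.9).
#'
#' @param lambda mean depth.
#' @return probability both parental alleles are observed.
#' @export
prob_both_alleles_observed <- function(lambda) {
  1 - 2 * exp(-lambda / 2) + exp(-lambda)
}
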