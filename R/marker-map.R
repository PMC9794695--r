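#' Generate a marker map of parent-differentiating SNP positions
#'
#' Draws marker positions uniformly (without replacement) along each
#' chromosome and assigns a distinct single-nucleotide allele to each parent
#' at every marker. Positions are 1-based and strictly increasing within a
#' chromosome.
#'
#' @param cm chromosome map (see [chrom_map()]).
#' @param n_markers_per_chrom integer scalar or vector (one per chromosome):
#'   number of markers to place on each chromosome.
#' @param seed optional RNG seed.
#' @return A marker map: `data.frame` with columns `chrom`, `pos`,
#'   `allele_P1`, `allele_P2`.
#' @examples
#' mk <- make_marker_map(chrom_map("chr1", 1e5), 50, seed = 1)
#' @export
make_marker_map <- function(cm, n_markers_per_chrom, seed = NULL) {
  assert_chrom_map(cm)
  set_seed_if(seed)
  n <- rep_len(as.integer(n_markers_per_chrom), nrow(cm))
  if (any(n < 1)) stop("n_markers_per_chrom must be >= 1", call. = FALSE)
  if (any(n > cm$length)) {
    stop("more markers requested than positions available on a chromosome",
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  per_chrom <- lapply(seq_len(nrow(cm)), function(i) {
    pos <- sort(sample.int(cm$length[i], n[i], replace = FALSE))
    a1 <- sample(bases, n[i], replace = TRUE)
    # second allele drawn from the three remaining bases
    shift <- sample.int(3L, n[i], replace = TRUE)
    a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
    data.frame(chrom = cm$chrom[i], pos = pos,
               allele_P1 = a1, allele_P2 = a2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_chrom)
}

assert_marker_map <- function(markers) {
  stop_if_not_cols(markers, c("chrom", "pos"), "marker map")
  invisible(markers)
}
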