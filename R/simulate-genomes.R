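#' The fully heterozygous F1 hybrid genome
#'
#' Builds the diploid F1 genome over a marker map: one haplotype carrying
#' the P1 allele at every marker and one carrying the P2 allele. This is
#' the reference individual every reproduction mode starts from, and the
#' genotype clonal progeny are expected to retain genome-wide.
#'
#' @param markers marker map (see [make_marker_map()]).
#' @return A `progeny_genome` object: list with `ploidy`, `mode`,
#'   `haplotypes` (list of integer vectors over markers; 1 = P1 origin,
#'   2 = P2 origin) and `breakpoints` (data.frame `hap`, `chrom`, `pos`).
#' @export
f1_genome <- function(markers) {
  assert_marker_map(markers)
  n <- nrow(markers)
  new_genome(
    ploidy = 2L, mode = "F1",
    haplotypes = list(rep(1L, n), rep(2L, n)),
    breakpoints = empty_breakpoints()
  )
}

new_genome <- function(ploidy, mode, haplotypes, breakpoints) {
  structure(
    list(ploidy = as.integer(ploidy), mode = mode,
         haplotypes = haplotypes, breakpoints = breakpoints),
    class = "progeny_genome"
  )
}

empty_breakpoints <- function() {
  data.frame(hap = integer(), chrom = character(), pos = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.progeny_genome <- function(x, ...) {
  cat(sprintf("<progeny_genome> ploidy=%d mode=%s markers=%d breakpoints=%d\n",
              x$ploidy, x$mode, length(x$haplotypes[[1]]),
              nrow(x$breakpoints)))
  invisible(x)
}

is_canonical_f1 <- function(genome) {
  genome$ploidy == 2L &&
    length(genome$haplotypes) == 2L &&
    all(genome$haplotypes[[1]] == 1L) &&
    all(genome$haplotypes[[2]] == 2L)
}

#' Simulate one meiotic gamete of the F1
#'
#' Draws, for each chromosome, an obligate number of crossovers plus a
#' Poisson-distributed number of extras, places them uniformly along the
#' chromosome (no interference), and returns the resulting recombinant
#' haploid haplotype: segments of alternating parental origin starting from
#' a random phase.
#'
#' @param f1 the fully heterozygous diploid F1 (see [f1_genome()]).
#' @param markers marker map the genome is defined over.
#' @param cm chromosome map.
#' @param obligate integer >= 0, crossovers guaranteed per chromosome
#'   (default 1, the obligate chiasma).
#' @param extra_mean mean of the Poisson count of additional crossovers per
#'   chromosome (default 0.5, giving ~1.5 crossovers/chromosome as typical
#'   for rice).
#' @param seed optional RNG seed.
#' @return list with `origin` (integer vector over markers, 1 = P1, 2 = P2)
#'   and `breakpoints` (data.frame `chrom`, `pos`).
#' @export
simulate_meiotic_gamete <- function(f1, markers, cm, obligate = 1,
                                    extra_mean = 0.5, seed = NULL) {
  if (!inherits(f1, "progeny_genome") || f1$ploidy != 2L) {
    stop("meiosis requires a diploid genome", call. = FALSE)
  }
  if (!is_canonical_f1(f1)) {
    stop("input must be the fully heterozygous F1 (all-P1 + all-P2 haplotypes)",
         call. = FALSE)
  }
  assert_marker_map(markers)
  assert_chrom_map(cm)
  stopifnot(obligate >= 0, extra_mean >= 0)
  set_seed_if(seed)

  origin <- integer(nrow(markers))
  bp_list <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    idx <- which(markers$chrom == cm$chrom[i])
    n_co <- obligate + stats::rpois(1L, extra_mean)
    x <- sort(stats::runif(n_co, min = 0, max = cm$length[i]))
    phase <- sample(c(1L, 2L), 1L)
    if (length(idx)) {
      k <- findInterval(markers$pos[idx], x)
      origin[idx] <- ((phase - 1L + k) %% 2L) + 1L
    }
    bp_list[[i]] <- data.frame(chrom = rep(cm$chrom[i], length(x)), pos = x,
                               stringsAsFactors = FALSE)
  }
  list(origin = origin, breakpoints = do.call(rbind, bp_list))
}

#' Simulate progeny genomes under a reproduction mode
#'
#' The three modes of reproduction of the engineered hybrid:
#' \describe{
#'   \item{SEXUAL}{self-fertilisation of the F1: each progeny is the fusion
#'     of two independent meiotic gametes (diploid, recombinant) — the F2.}
#'   \item{MIME_ONLY}{apomeiosis without parthenogenesis: male and female
#'     gametes are unreduced and unrecombined, so every progeny is an
#'     unrecombined tetraploid carrying two copies of each F1 haplotype.}
#'   \item{MIME_BBM1}{apomeiosis plus egg-cell parthenogenesis: with
#'     probability `p` the unreduced egg develops without a paternal genome
#'     into a diploid clone of the F1; otherwise fertilisation proceeds and
#'     the progeny is tetraploid as in MIME_ONLY.}
#' }
#'
#' @param f1 the fully heterozygous F1 genome.
#' @param markers,cm marker and chromosome maps.
#' @param mode `"SEXUAL"`, `"MIME_ONLY"` or `"MIME_BBM1"`.
#' @param n number of progeny (>= 1).
#' @param p parthenogenesis rate in `[0, 1]`; used only for `MIME_BBM1`.
#' @param obligate,extra_mean crossover model for sexual meiosis (see
#'   [simulate_meiotic_gamete()]).
#' @param seed optional RNG seed.
#' @return list of `progeny_genome` objects of length `n`. Each carries its
#'   `mode` ("SEXUAL", "MIME_SELF" or "PARTHENOGENESIS"), ploidy, haplotype
#'   origin vectors and crossover breakpoints.
#' @export
simulate_progeny <- function(f1, markers, cm,
                             mode = c("SEXUAL", "MIME_ONLY", "MIME_BBM1"),
                             n, p = 0.95, obligate = 1, extra_mean = 0.5,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is_canonical_f1(f1)) {
    stop("progeny simulation starts from the fully heterozygous F1",
         call. = FALSE)
  }
  stopifnot(p >= 0, p <= 1)
  set_seed_if(seed)
  n <- as.integer(n)
  n_mark <- nrow(markers)

  clone_genome <- function() {
    new_genome(2L, "PARTHENOGENESIS",
               list(rep(1L, n_mark), rep(2L, n_mark)),
               empty_breakpoints())
  }
  tetra_genome <- function() {
    new_genome(4L, "MIME_SELF",
               list(rep(1L, n_mark), rep(1L, n_mark),
                    rep(2L, n_mark), rep(2L, n_mark)),
               empty_breakpoints())
  }
  sexual_genome <- function() {
    g1 <- simulate_meiotic_gamete(f1, markers, cm, obligate, extra_mean)
    g2 <- simulate_meiotic_gamete(f1, markers, cm, obligate, extra_mean)
    bp <- rbind(
      cbind(hap = 1L, g1$breakpoints),
      cbind(hap = 2L, g2$breakpoints)
    )
    new_genome(2L, "SEXUAL", list(g1$origin, g2$origin), bp)
  }

  switch(mode,
    SEXUAL = replicate(n, sexual_genome(), simplify = FALSE),
    MIME_ONLY = replicate(n, tetra_genome(), simplify = FALSE),
    MIME_BBM1 = {
      is_clone <- stats::runif(n) < p
      lapply(is_clone, function(cl) if (cl) clone_genome() else tetra_genome())
    }
  )
}

#' Initial endosperm C-value for a reproduction mode
#'
#' Sexual endosperm arises from two haploid central-cell nuclei fused with a
#' haploid sperm nucleus (3C). Under apomeiosis (with or without the
#' parthenogenesis trigger) the central-cell nuclei and the sperm are
#' diploid, so the endosperm starts at 6C.
#'
#' @param mode `"SEXUAL"`, `"MIME_ONLY"` or `"MIME_BBM1"`.
#' @return integer C-value: 3 for sexual, 6 for the MiMe modes.
#' @export
endosperm_initial_cvalue <- function(mode = c("SEXUAL", "MIME_ONLY",
                                              "MIME_BBM1")) {
  mode <- match.arg(mode)
  if (mode == "SEXUAL") 3L else 6L
}

#' Genotype of a genome at given marker indices
#'
#' Error-free genotype classes from the haplotype truth, used e.g. for the
#' diagnostic SSR-style panel test. A marker is `HET` when both parental
#' origins are present among the haplotypes.
#'
#' @param genome a `progeny_genome`.
#' @param idx integer marker row indices (default: all markers).
#' @return character vector in `HOM_P1` / `HET` / `HOM_P2`.
#' @export
genotype_at <- function(genome, idx = NULL) {
  idx <- idx %||% seq_along(genome$haplotypes[[1]])
  mat <- vapply(genome$haplotypes, function(h) h[idx],
                numeric(length(idx)))
  mat <- matrix(mat, nrow = length(idx))
  has_p1 <- rowSums(mat == 1L) > 0
  has_p2 <- rowSums(mat == 2L) > 0
  ifelse(has_p1 & has_p2, "HET", ifelse(has_p1, "HOM_P1", "HOM_P2"))
}
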