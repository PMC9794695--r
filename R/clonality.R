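#' Classify a sample as clonal or recombinant
#'
#' A clonal plant retains the F1's heterozygous genotype genome-wide: its
#' landscape is HET in (essentially) every called window and shows no
#' heterozygous-to-homozygous transition. A recombinant (sexual F2) plant
#' shows at least one such transition.
#'
#' @param landscape one sample's landscape from [build_landscape()].
#' @param events crossover events from [detect_crossovers()] for the same
#'   sample.
#' @param clonal_min_het minimum HET fraction over called windows for a
#'   CLONAL call (default 0.99; tolerates rare noise windows).
#' @return one-row `data.frame`: `sample_id`, `called_windows`,
#'   `het_fraction`, `n_crossover_events`, `classification`
#'   (`CLONAL` / `RECOMBINANT` / `AMBIGUOUS`).
#' @export
assess_clonality <- function(landscape, events, clonal_min_het = 0.99) {
  called <- landscape$class != "NO_CALL"
  if (!any(called)) {
    stop("no called windows: clonality cannot be assessed", call. = FALSE)
  }
  het_fraction <- mean(landscape$class[called] == "HET")
  n_events <- nrow(events)
  classification <- if (het_fraction >= clonal_min_het && n_events == 0) {
    "CLONAL"
  } else if (n_events >= 1) {
    "RECOMBINANT"
  } else {
    "AMBIGUOUS"
  }
  data.frame(sample_id = landscape$sample_id[1],
             called_windows = sum(called),
             het_fraction = het_fraction,
             n_crossover_events = n_events,
             classification = classification,
             stringsAsFactors = FALSE)
}

#' Diagnostic k-marker panel test of clonality
#'
#' With k unlinked markers heterozygous in the F1, a sexual (selfed)
#' progeny is heterozygous at all k loci with probability (1/2)^k, while an
#' error-free clone always is. The test reports the all-heterozygous count
#' and the log10 likelihood ratio of clonal vs sexual reproduction for the
#' observed count (point mass at n under clonal; Binomial(n, (1/2)^k) under
#' sexual).
#'
#' @param het matrix or data.frame of n plants x k markers, logical
#'   (heterozygous?) or character genotype classes (`"HET"` counts as
#'   heterozygous).
#' @return list: `k`, `n`, `all_het_count`, `prob_sexual` (per-plant
#'   all-het probability), `log10_lr` (clonal vs sexual; `-Inf` when any
#'   plant fails a locus).
#' @export
panel_test <- function(het) {
  het <- as.matrix(het)
  if (is.character(het)) het <- het == "HET"
  stopifnot(is.logical(het), ncol(het) >= 1)
  n <- nrow(het)
  k <- ncol(het)
  all_het_count <- sum(rowSums(het) == k)
  prob_sexual <- 0.5^k
  log10_lr <- if (all_het_count == n) {
    -stats::dbinom(n, n, prob_sexual, log = TRUE) / log(10)
  } else {
    -Inf
  }
  list(k = k, n = n, all_het_count = all_het_count,
       prob_sexual = prob_sexual, log10_lr = log10_lr)
}
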