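#' Flow-cytometry simulation configuration
#'
#' Parameters of the simulated DAPI flow histogram: Gaussian peaks centred
#' at a channel proportional to DNA content (C-value), a stated coefficient
#' of variation, and a uniform debris floor.
#'
#' @param cv coefficient of variation of each peak (sd/mean), default 0.05.
#' @param n_nuclei nuclei recorded (debris included), default 20000.
#' @param debris_frac fraction of events that are uniform debris, default 0.1.
#' @param channel_per_C fluorescence channels per C unit; the 2C leaf
#'   control peak sits at `2 * channel_per_C` (default 50 -> channel 100).
#' @param n_channels number of channels on the axis, default 1024.
#' @return list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(cv = 0.05, n_nuclei = 20000, debris_frac = 0.1,
                            channel_per_C = 50, n_channels = 1024) {
  stopifnot(cv > 0, n_nuclei >= 1, debris_frac >= 0, debris_frac < 1,
            channel_per_C > 0, n_channels >= 16)
  structure(list(cv = cv, n_nuclei = as.integer(n_nuclei),
                 debris_frac = debris_frac, channel_per_C = channel_per_C,
                 n_channels = as.integer(n_channels)),
            class = "flow_sim_config")
}

#' Simulate a flow-cytometry histogram for a mixture of C-values
#'
#' Nuclei are assigned to mixture components by their fractions; each
#' contributes a Gaussian-distributed channel value centred at
#' `C * channel_per_C` with sd `cv * mean`. Debris events are uniform over
#' the axis. Tissue mixtures cover leaf samples (e.g. a single 2C or 4C G1
#' peak, or a 2C+4C chimera) and endosperm endoreduplication series
#' (3C/6C/12C or 6C/12C/24C).
#'
#' @param ploidy_mix `data.frame` with columns `C` (DNA content in C units)
#'   and `fraction` (nonnegative, summing to 1).
#' @param fc a [flow_sim_config()].
#' @param seed optional RNG seed.
#' @return `data.frame` with columns `channel` (1..n_channels) and `count`.
#' @export
simulate_flow_histogram <- function(ploidy_mix, fc = flow_sim_config(),
                                    seed = NULL) {
  if (is.null(ploidy_mix) || nrow(ploidy_mix) == 0) {
    stop("ploidy mixture must contain at least one component", call. = FALSE)
  }
  stop_if_not_cols(ploidy_mix, c("C", "fraction"), "ploidy_mix")
  if (any(ploidy_mix$fraction < 0) ||
      abs(sum(ploidy_mix$fraction) - 1) > 1e-6) {
    stop("component fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  set_seed_if(seed)
  n_debris <- round(fc$n_nuclei * fc$debris_frac)
  n_signal <- fc$n_nuclei - n_debris
  comp <- sample.int(nrow(ploidy_mix), n_signal, replace = TRUE,
                     prob = ploidy_mix$fraction)
  mu <- ploidy_mix$C[comp] * fc$channel_per_C
  values <- stats::rnorm(n_signal, mean = mu, sd = fc$cv * mu)
  values <- c(values, stats::runif(n_debris, min = 1, max = fc$n_channels))
  ch <- pmin(pmax(round(values), 1L), fc$n_channels)
  data.frame(channel = seq_len(fc$n_channels),
             count = tabulate(ch, nbins = fc$n_channels))
}
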