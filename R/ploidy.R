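#' Detect peaks in a flow-cytometry histogram
#'
#' Smooths the counts with a moving average and reports local maxima above
#' a prominence floor expressed as a fraction of the tallest smoothed
#' count. Each peak's share of events is estimated from the raw counts
#' within +/-15% of the peak channel.
#'
#' @param hist `data.frame` with `channel` and `count`.
#' @param smooth_width moving-average width in channels (default 5).
#' @param prominence_frac minimum smoothed height relative to the maximum
#'   (default 0.05).
#' @return `data.frame` with `channel`, `height` (smoothed), `fraction`
#'   (share of events attributed to the peak), ordered by channel.
#' @export
find_histogram_peaks <- function(hist, smooth_width = 5,
                                 prominence_frac = 0.05) {
  stop_if_not_cols(hist, c("channel", "count"), "histogram")
  counts <- hist$count
  sm <- as.numeric(stats::filter(counts, rep(1 / smooth_width, smooth_width),
                                 sides = 2))
  sm[is.na(sm)] <- 0
  floor_h <- prominence_frac * max(sm)
  pk <- pracma::findpeaks(sm, minpeakheight = floor_h,
                          minpeakdistance = max(2L, smooth_width),
                          peakpat = "[+]{1,}[0]*[-]{1,}")  # allow plateaus
  if (is.null(pk)) {
    return(data.frame(channel = numeric(), height = numeric(),
                      fraction = numeric()))
  }
  idx <- pk[, 2]
  # non-maximum suppression: local maxima within 25% of an already accepted
  # (taller) peak's channel belong to the same mode — distinct biological
  # peaks (C-value doublings, 2C vs 4C) differ by a factor of 2
  idx <- idx[order(sm[idx], decreasing = TRUE)]
  accepted <- integer()
  for (i in idx) {
    ch <- hist$channel[i]
    if (!length(accepted) ||
        all(abs(ch - hist$channel[accepted]) > 0.25 *
              pmax(ch, hist$channel[accepted]))) {
      accepted <- c(accepted, i)
    }
  }
  idx <- sort(accepted)
  chan <- hist$channel[idx]
  weight <- vapply(chan, function(ch) {
    sum(counts[hist$channel >= 0.85 * ch & hist$channel <= 1.15 * ch])
  }, numeric(1))
  out <- data.frame(channel = chan, height = sm[idx],
                    fraction = weight / sum(weight))
  out[order(out$channel), , drop = FALSE]
}

#' Call leaf ploidy from a flow-cytometry histogram
#'
#' The primary G1 peak is the smallest-channel peak holding at least
#' `minor_fraction` of events. Its ratio to the diploid 2C control channel
#' determines the call: DIPLOID in `[0.8, 1.2]`, TETRAPLOID in
#' `[1.7, 2.3]`. When peaks near ratio 1 and ratio 2 each hold at least
#' `minor_fraction` of events the plant is called a 2n/4n chimera.
#'
#' @param hist flow histogram (`channel`, `count`).
#' @param control_2C_channel G1 channel of the diploid leaf control (> 0).
#' @param sample_id optional label.
#' @param minor_fraction minimum event share for a peak to support a
#'   (chimeric) call, default 0.1.
#' @param smooth_width,prominence_frac see [find_histogram_peaks()].
#' @return one-row `data.frame`: `sample_id`, `call` (`DIPLOID` /
#'   `TETRAPLOID` / `CHIMERIC_2N_4N` / `UNCALLED`), `primary_ratio`,
#'   `n_peaks`, plus the detected peak ratios collapsed into a string.
#' @export
call_ploidy <- function(hist, control_2C_channel, sample_id = NA_character_,
                        minor_fraction = 0.1, smooth_width = 5,
                        prominence_frac = 0.05) {
  stopifnot(control_2C_channel > 0)
  peaks <- find_histogram_peaks(hist, smooth_width, prominence_frac)
  peaks <- peaks[peaks$fraction >= minor_fraction, , drop = FALSE]
  result <- function(call, ratio) {
    data.frame(sample_id = sample_id, call = call,
               primary_ratio = ratio, n_peaks = nrow(peaks),
               peak_ratios = paste(round(peaks$channel /
                                           control_2C_channel, 3),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (nrow(peaks) == 0) return(result("UNCALLED", NA_real_))
  ratios <- peaks$channel / control_2C_channel
  in_2n <- ratios >= 0.8 & ratios <= 1.2
  in_4n <- ratios >= 1.7 & ratios <= 2.3
  if (any(in_2n) && any(in_4n)) {
    return(result("CHIMERIC_2N_4N", ratios[which(in_2n)[1]]))
  }
  primary <- which.min(ratios)
  r <- ratios[primary]
  call <- if (in_2n[primary]) "DIPLOID" else if (in_4n[primary]) {
    "TETRAPLOID"
  } else "UNCALLED"
  result(call, r)
}

#' Endosperm C-value profile from a flow histogram
#'
#' Converts detected peak channels to C-values via the diploid leaf 2C
#' control, snaps the smallest peak to the expected base (3C for sexual
#' endosperm — two maternal plus one paternal genome — or 6C under
#' apomeiosis) and reports the endoreduplication series: successive
#' doublings of the base that match a detected peak.
#'
#' @param hist flow histogram.
#' @param control_2C_channel diploid leaf control G1 channel.
#' @param rel_tol relative tolerance for matching a peak to a C-value
#'   (default 0.2).
#' @param ... passed to [find_histogram_peaks()].
#' @return list: `base_C` (3 or 6) and `series` (detected C-values,
#'   base included).
#' @export
endosperm_profile <- function(hist, control_2C_channel, rel_tol = 0.2, ...) {
  stopifnot(control_2C_channel > 0)
  peaks <- find_histogram_peaks(hist, ...)
  if (nrow(peaks) == 0) {
    stop("no peaks detected in the endosperm histogram", call. = FALSE)
  }
  cvals <- 2 * peaks$channel / control_2C_channel
  base_raw <- min(cvals)
  base_C <- if (abs(base_raw - 3) / 3 <= rel_tol) {
    3
  } else if (abs(base_raw - 6) / 6 <= rel_tol) {
    6
  } else {
    stop(sprintf("smallest endosperm peak at %.2fC matches neither 3C nor 6C",
                 base_raw), call. = FALSE)
  }
  series <- numeric()
  level <- base_C
  while (level <= max(cvals) * (1 + rel_tol)) {
    if (any(abs(cvals - level) / level <= rel_tol)) {
      series <- c(series, level)
    }
    level <- level * 2
  }
  list(base_C = base_C, series = series)
}

#' Summarise ploidy calls for one transformation event
#'
#' Counts diploid and tetraploid progeny, computes the percent diploid
#' (rounded half-up to the nearest integer, the convention of the printed
#' event tables) and attaches an exact Clopper-Pearson 95% CI on the
#' diploid fraction. Chimeric 2n/4n plants are counted in the tetraploid
#' column by default (matching the printed tables, where the chimera
#' footnote hangs on the 4n count); set `chimeric_as` to change the
#' convention. UNCALLED samples are excluded from `n_analyzed`.
#'
#' @param calls character vector of ploidy calls (`DIPLOID`, `TETRAPLOID`,
#'   `CHIMERIC_2N_4N`, `UNCALLED`) or a `data.frame` with a `call` column
#'   (e.g. rbind-ed rows from [call_ploidy()]).
#' @param event_id event label.
#' @param chimeric_as `"tetraploid"` (default), `"diploid"` or `"exclude"`.
#' @param conf_level confidence level for the exact binomial CI.
#' @return one-row `data.frame`: `event_id`, `n_analyzed`, `n_diploid`,
#'   `n_tetraploid`, `percent_diploid`, `ci_low`, `ci_high` (CI on the
#'   diploid fraction, percent scale).
#' @export
summarize_event <- function(calls, event_id = NA_character_,
                            chimeric_as = c("tetraploid", "diploid",
                                            "exclude"),
                            conf_level = 0.95) {
  chimeric_as <- match.arg(chimeric_as)
  if (is.data.frame(calls)) calls <- calls$call
  if (!length(calls)) stop("at least one ploidy call is required",
                           call. = FALSE)
  calls <- calls[calls != "UNCALLED"]
  if (!length(calls)) {
    stop("all samples are UNCALLED: nothing to summarise", call. = FALSE)
  }
  n2 <- sum(calls == "DIPLOID")
  n4 <- sum(calls == "TETRAPLOID")
  nc <- sum(calls == "CHIMERIC_2N_4N")
  if (chimeric_as == "diploid") n2 <- n2 + nc
  if (chimeric_as == "tetraploid") n4 <- n4 + nc
  n <- n2 + n4
  ci <- stats::binom.test(n2, n, conf.level = conf_level)$conf.int
  data.frame(event_id = event_id, n_analyzed = n, n_diploid = n2,
             n_tetraploid = n4,
             percent_diploid = round_half_up(100 * n2 / n),
             ci_low = 100 * ci[1], ci_high = 100 * ci[2],
             stringsAsFactors = FALSE)
}

#' Event summary directly from diploid/tetraploid counts
#'
#' Convenience wrapper around [summarize_event()] for printed count data.
#'
#' @param n_diploid,n_tetraploid counts of 2n and 4n plants.
#' @param event_id event label.
#' @param ... passed to [summarize_event()].
#' @return see [summarize_event()].
#' @export
event_summary <- function(n_diploid, n_tetraploid, event_id = NA_character_,
                          ...) {
  summarize_event(c(rep("DIPLOID", n_diploid),
                    rep("TETRAPLOID", n_tetraploid)),
                  event_id = event_id, ...)
}
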