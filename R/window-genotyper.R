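#' Sliding windows along each chromosome
#'
#' Windows of `window` bp sliding by `step` bp, 0-based half-open, starting
#' at 0. Only full windows are laid down; the trailing remainder (shorter
#' than `step`) is merged into the final window, whose end is the
#' chromosome length. A chromosome shorter than `window` gets one window
#' covering it entirely.
#'
#' @param cm chromosome map.
#' @param window window size in bp (default 200 kb).
#' @param step slide in bp (default 100 kb); must satisfy
#'   `1 <= step <= window` so consecutive windows overlap or abut (a step
#'   larger than the window would leave gaps that break transition
#'   detection).
#' @return `data.frame` with `chrom`, `start`, `end`, `index` (1-based
#'   window index within chromosome).
#' @export
make_windows <- function(cm, window = 200000, step = 100000) {
  assert_chrom_map(cm)
  if (step < 1 || step > window) {
    stop("step must satisfy 1 <= step <= window", call. = FALSE)
  }
  per_chrom <- lapply(seq_len(nrow(cm)), function(i) {
    len <- cm$length[i]
    if (len <= window) {
      starts <- 0
      ends <- len
    } else {
      starts <- seq(0, len - window, by = step)
      ends <- starts + window
      ends[length(ends)] <- len  # absorb trailing remainder
    }
    data.frame(chrom = cm$chrom[i], start = starts, end = ends,
               index = seq_along(starts), stringsAsFactors = FALSE)
  })
  do.call(rbind, per_chrom)
}

#' Window genotype thresholds
#'
#' @param min_reads minimum informative reads for a call (default 5;
#'   fewer gives `NO_CALL`).
#' @param hom_threshold P1-read fraction at or above which a window is
#'   `HOM_P1` (and at or below `1 - hom_threshold`, `HOM_P2`); default 0.9.
#' @return list of class `window_thresholds`.
#' @export
window_thresholds <- function(min_reads = 5, hom_threshold = 0.9) {
  stopifnot(min_reads >= 1, hom_threshold > 0.5, hom_threshold <= 1)
  structure(list(min_reads = as.integer(min_reads),
                 hom_threshold = hom_threshold),
            class = "window_thresholds")
}

classify_window <- function(reads_p1, reads_p2, th) {
  total <- reads_p1 + reads_p2
  f <- ifelse(total > 0, reads_p1 / total, NA_real_)
  cls <- rep("HET", length(total))
  cls[!is.na(f) & f >= th$hom_threshold] <- "HOM_P1"
  cls[!is.na(f) & f <= 1 - th$hom_threshold] <- "HOM_P2"
  cls[total < th$min_reads] <- "NO_CALL"
  cls
}

#' Build a per-sample genotype landscape over sliding windows
#'
#' Pools P1/P2 read counts over the markers inside each window (read-count
#' pooling rather than per-marker genotype votes, which is the robust
#' choice at ~2x coverage) and classifies each window: `NO_CALL` below
#' `min_reads` informative reads, `HOM_P1` at P1-fraction >=
#' `hom_threshold`, `HOM_P2` at <= `1 - hom_threshold`, `HET` otherwise.
#'
#' @param obs observation row as returned by [simulate_reads()] or
#'   [read_observations_vcf()]: `data.frame` aligned to `markers` with
#'   `reads_P1`, `reads_P2`.
#' @param markers marker map the observations are aligned to.
#' @param windows windows from [make_windows()].
#' @param th thresholds from [window_thresholds()].
#' @param sample_id optional sample label carried into the output.
#' @return the landscape: `data.frame` with `sample_id`, `chrom`, `start`,
#'   `end`, `index`, `n_markers` (markers with at least one read),
#'   `reads_P1`, `reads_P2`, `f`, `class`.
#' @export
build_landscape <- function(obs, markers, windows,
                            th = window_thresholds(),
                            sample_id = NA_character_) {
  assert_marker_map(markers)
  if (nrow(obs) != nrow(markers)) {
    stop("observations are not aligned to the marker map", call. = FALSE)
  }
  out <- windows
  out$n_markers <- 0L
  out$reads_P1 <- 0
  out$reads_P2 <- 0
  for (ch in unique(windows$chrom)) {
    mi <- which(markers$chrom == ch)
    wi <- which(windows$chrom == ch)
    if (!length(mi)) next
    pos <- markers$pos[mi]
    c_p1 <- cumsum(obs$reads_P1[mi])
    c_p2 <- cumsum(obs$reads_P2[mi])
    c_inf <- cumsum((obs$reads_P1[mi] + obs$reads_P2[mi]) > 0)
    # marker at 1-based pos lies in [start, end) iff start < pos <= end
    lo <- findInterval(windows$start[wi], pos)      # markers with pos <= start
    hi <- findInterval(windows$end[wi], pos)        # markers with pos <= end
    sum_between <- function(cs) {
      c(0, cs)[hi + 1L] - c(0, cs)[lo + 1L]
    }
    out$reads_P1[wi] <- sum_between(c_p1)
    out$reads_P2[wi] <- sum_between(c_p2)
    out$n_markers[wi] <- sum_between(c_inf)
  }
  total <- out$reads_P1 + out$reads_P2
  out$f <- ifelse(total > 0, out$reads_P1 / total, NA_real_)
  out$class <- classify_window(out$reads_P1, out$reads_P2, th)
  out <- cbind(sample_id = sample_id, out, stringsAsFactors = FALSE)
  out
}

#' Consolidate a landscape into genotype segments
#'
#' Two passes over each chromosome's ordered window classes:
#' \enumerate{
#'   \item a single-pass width-3 majority filter — an isolated one-window
#'     class flip flanked by two identical called classes is reassigned to
#'     the flanking class (optional, `smooth = FALSE` disables it);
#'   \item maximal runs of identical classes are merged into segments;
#'     `NO_CALL` runs are absorbed when the called segments on both sides
#'     agree in class, otherwise they remain uncovered gaps.
#' }
#'
#' @param landscape one sample's landscape from [build_landscape()].
#' @param smooth apply the majority-of-3 filter (default TRUE).
#' @return segments: `data.frame` with `sample_id`, `chrom`, `start`,
#'   `end`, `class` (non-`NO_CALL`), `n_windows` (called windows in the
#'   segment; absorbed `NO_CALL` windows extend the span but are not
#'   counted).
#' @export
consolidate <- function(landscape, smooth = TRUE) {
  segs <- list()
  for (ch in unique(landscape$chrom)) {
    li <- which(landscape$chrom == ch)
    cls <- landscape$class[li]
    if (smooth && length(cls) >= 3) {
      orig <- cls
      for (i in 2:(length(cls) - 1)) {
        if (orig[i - 1] == orig[i + 1] && orig[i] != orig[i - 1] &&
            orig[i - 1] != "NO_CALL") {
          cls[i] <- orig[i - 1]
        }
      }
    }
    r <- rle(cls)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    last <- NULL       # last emitted segment (index into segs)
    gap_since_last <- FALSE
    for (k in seq_along(r$values)) {
      if (r$values[k] == "NO_CALL") {
        gap_since_last <- TRUE
        next
      }
      w_first <- li[run_start[k]]
      w_last <- li[run_end[k]]
      if (!is.null(last) && segs[[last]]$class == r$values[k] &&
          gap_since_last) {
        # absorb the NO_CALL gap: both neighbours agree
        segs[[last]]$end <- landscape$end[w_last]
        segs[[last]]$n_windows <- segs[[last]]$n_windows + r$lengths[k]
      } else if (!is.null(last) && segs[[last]]$class == r$values[k] &&
                 !gap_since_last) {
        segs[[last]]$end <- landscape$end[w_last]
        segs[[last]]$n_windows <- segs[[last]]$n_windows + r$lengths[k]
      } else {
        segs[[length(segs) + 1L]] <- data.frame(
          sample_id = landscape$sample_id[1], chrom = ch,
          start = landscape$start[w_first], end = landscape$end[w_last],
          class = r$values[k], n_windows = r$lengths[k],
          stringsAsFactors = FALSE)
        last <- length(segs)
      }
      gap_since_last <- FALSE
    }
  }
  if (!length(segs)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      class = character(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Detect crossover transitions between consolidated segments
#'
#' Emits one event per adjacent pair of differing-class segments on a
#' chromosome. The breakpoint interval is `[end of the old segment -
#' window, start of the new segment + window)`, clipped to the chromosome:
#' in the gap-free case this is `window + step` wide, the localisation
#' resolution of overlapping windows. The symmetric one-window margin is
#' needed because the homozygous-call threshold is asymmetric (0.9), which
#' shifts the observed class boundary up to `0.8 * window` into the
#' heterozygous side of the true breakpoint. Across an unresolved
#' `NO_CALL` gap the interval additionally covers the gap.
#'
#' @param segments consolidated segments from [consolidate()].
#' @param cm chromosome map (for clipping).
#' @param step the slide used to build the windows (default 100 kb).
#' @param window the window size used to build the windows (default 200 kb).
#' @return events: `data.frame` with `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open breakpoint interval), `class_left`, `class_right`,
#'   `single_dose` (TRUE for HET <-> HOM transitions, i.e. one crossover;
#'   FALSE for HOM_P1 <-> HOM_P2, which implies coincident crossovers on
#'   both haplotypes).
#' @export
detect_crossovers <- function(segments, cm, step = 100000, window = 200000) {
  assert_chrom_map(cm)
  ev <- list()
  for (ch in unique(segments$chrom)) {
    si <- which(segments$chrom == ch)
    if (length(si) < 2) next
    len <- cm$length[match(ch, cm$chrom)]
    for (k in seq_len(length(si) - 1)) {
      a <- segments[si[k], ]
      b <- segments[si[k + 1], ]
      if (a$class == b$class) next
      lo <- max(0, a$end - window)
      hi <- min(len, b$start + window)
      ev[[length(ev) + 1L]] <- data.frame(
        sample_id = a$sample_id, chrom = ch, start = lo, end = hi,
        class_left = a$class, class_right = b$class,
        single_dose = xor(a$class == "HET", b$class == "HET"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      class_left = character(), class_right = character(),
                      single_dose = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}
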