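# shared fixtures built in code

# small single-chromosome genome for fast unit tests
toy_cm <- function(len = 10e6, name = "chr1") chrom_map(name, len)

toy_markers <- function(cm = toy_cm(), density_per_kb = 0.72, seed = 42) {
  make_marker_map(cm, pmax(5L, round(cm$length / 1000 * density_per_kb)),
                  seed = seed)
}

# replicate-call data.frame helper for marker-selection tests
rc <- function(ref, alt) data.frame(ref_count = ref, alt_count = alt)

# independent brute-force consolidation oracle: enumerate maximal constant
# runs after the same width-3 majority smoothing, written as a plain loop
brute_force_segments <- function(classes, smooth = TRUE) {
  cls <- classes
  if (smooth && length(cls) >= 3) {
    for (i in 2:(length(cls) - 1)) {
      if (classes[i - 1] == classes[i + 1] && classes[i] != classes[i - 1] &&
          classes[i - 1] != "NO_CALL") {
        cls[i] <- classes[i - 1]
      }
    }
  }
  segs <- list()
  cur_class <- NULL
  cur_start <- NULL
  prev_called_class <- NULL
  for (i in seq_along(cls)) {
    c_i <- cls[i]
    if (identical(c_i, cur_class)) next
    if (!is.null(cur_class) && cur_class != "NO_CALL") {
      segs[[length(segs) + 1]] <- list(class = cur_class, start = cur_start,
                                       end = i - 1)
    }
    cur_class <- c_i
    cur_start <- i
  }
  if (!is.null(cur_class) && cur_class != "NO_CALL") {
    segs[[length(segs) + 1]] <- list(class = cur_class, start = cur_start,
                                     end = length(cls))
  }
  # absorb NO_CALL gaps whose neighbours agree
  merged <- list()
  for (s in segs) {
    n <- length(merged)
    if (n > 0 && merged[[n]]$class == s$class) {
      gap <- all(cls[(merged[[n]]$end + 1):(s$start - 1)] == "NO_CALL") ||
        merged[[n]]$end + 1 > s$start - 1
      if (gap) {
        merged[[n]]$end <- s$end
        next
      }
    }
    merged[[n + 1]] <- s
  }
  merged
}

# landscape data.frame from a plain class vector (unit-width windows)
landscape_from_classes <- function(classes, chrom = "chr1", width = 1) {
  n <- length(classes)
  data.frame(sample_id = "s", chrom = chrom,
             start = (seq_len(n) - 1) * width, end = seq_len(n) * width,
             index = seq_len(n), n_markers = 1L,
             reads_P1 = 0, reads_P2 = 0, f = NA_real_,
             class = classes, stringsAsFactors = FALSE)
}
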