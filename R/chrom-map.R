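#' Chromosome map
#'
#' An ordered table of chromosome names and lengths. The order is fixed and
#' reused by every downstream structure (marker maps, windows, landscapes).
#'
#' @param names character vector of unique chromosome identifiers.
#' @param lengths integer vector of chromosome lengths in base pairs (> 0).
#' @return A `data.frame` with columns `chrom` and `length`.
#' @examples
#' chrom_map(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
chrom_map <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) {
    stop("names and lengths must have equal length", call. = FALSE)
  }
  if (anyDuplicated(names)) stop("chromosome names must be unique", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("all chromosome lengths must be >= 1", call. = FALSE)
  }
  data.frame(chrom = names, length = floor(lengths),
             stringsAsFactors = FALSE)
}

#' Rice chromosome map
#'
#' The 12 rice chromosomes with approximate assembly lengths (Mb scale,
#' Nipponbare reference order). Used as the default genome for simulations
#' so marker densities and window counts are of realistic magnitude.
#'
#' @return A chromosome map (see [chrom_map()]) with 12 rows, ~373 Mb total.
#' @export
rice_chrom_map <- function() {
  chrom_map(
    paste0("chr", 1:12),
    c(43.3e6, 35.9e6, 36.4e6, 35.5e6, 29.9e6, 31.2e6,
      29.7e6, 28.4e6, 23.0e6, 23.2e6, 29.0e6, 27.5e6)
  )
}

assert_chrom_map <- function(cm) {
  stop_if_not_cols(cm, c("chrom", "length"), "chromosome map")
  invisible(cm)
}
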