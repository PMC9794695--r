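#' Write marker observations as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with biallelic SNP records and a per-sample
#' `AD` (allelic depth) FORMAT field, REF being the P1 allele and ALT the
#' P2 allele when written from simulated observations.
#'
#' @param obs_list named list (sample id -> observation `data.frame` with
#'   `reads_P1`, `reads_P2` aligned to `sites`).
#' @param sites `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @param path output file (plain-text `.vcf`).
#' @param provenance optional character vector written as `##` header lines.
#' @return `path`, invisibly.
#' @export
write_observations_vcf <- function(obs_list, sites, path,
                                   provenance = NULL) {
  stop_if_not_cols(sites, c("chrom", "pos", "ref", "alt"), "sites")
  stopifnot(length(names(obs_list)) == length(obs_list),
            all(nzchar(names(obs_list))))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=clonescan_%s",
            as.character(utils::packageVersion("clonescan"))),
    if (!is.null(provenance)) paste0("##", provenance),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(obs_list)), collapse = "\t")
  )
  sample_cols <- lapply(obs_list, function(o) {
    stopifnot(nrow(o) == nrow(sites))
    paste0(o$reads_P1, ",", o$reads_P2)
  })
  body <- do.call(paste, c(
    list(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
         ".", "AD"),
    sample_cols, list(sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read per-sample allele-depth observations from a VCF
#'
#' Keeps biallelic SNP records only (multi-allelic or indel records are
#' skipped with a message giving the count) and extracts the per-sample
#' `AD` field. When a marker map is supplied the counts are aligned to it
#' by exact chromosome/position match; markers absent from the VCF get
#' zero counts with a warning.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param markers optional marker map to align to; its `allele_P1` (when
#'   present) is checked against REF to orient the counts, so `reads_P1`
#'   always counts reads supporting the P1 allele.
#' @param samples optional character vector restricting/ordering samples.
#' @return list: `sites` (`chrom`, `pos`, `ref`, `alt`), `counts` (named
#'   list per sample of `data.frame(reads_P1, reads_P2)` aligned to
#'   `sites` or to `markers` when given), `n_skipped`.
#' @export
read_observations_vcf <- function(path, markers = NULL, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message(sprintf("skipped %d non-biallelic-SNP record(s)", n_skipped))
  }
  gt <- vcf@gt
  fmt <- gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(x) "AD" %in% x, logical(1)))) {
    stop(sprintf("VCF %s lacks the AD (allelic depth) FORMAT field",
                 basename(path)), call. = FALSE)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad <- ad[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  keep_samples <- samples %||% colnames(ad)
  missing_s <- setdiff(keep_samples, colnames(ad))
  if (length(missing_s)) {
    stop(sprintf("sample(s) not in VCF: %s",
                 paste(missing_s, collapse = ", ")), call. = FALSE)
  }
  ref_n <- vcfR::masplit(ad, record = 1, sort = FALSE, decreasing = FALSE)
  alt_n <- vcfR::masplit(ad, record = 2, sort = FALSE, decreasing = FALSE)
  ref_n[is.na(ref_n)] <- 0
  alt_n[is.na(alt_n)] <- 0

  align <- function(ref_col, alt_col) {
    if (is.null(markers)) {
      return(data.frame(reads_P1 = ref_col, reads_P2 = alt_col))
    }
    key_m <- paste(markers$chrom, markers$pos)
    key_s <- paste(sites$chrom, sites$pos)
    hit <- match(key_m, key_s)
    if (anyNA(hit)) {
      warning(sprintf("%d marker(s) absent from the VCF: zero counts used",
                      sum(is.na(hit))), call. = FALSE)
    }
    r1 <- ifelse(is.na(hit), 0, ref_col[hit])
    r2 <- ifelse(is.na(hit), 0, alt_col[hit])
    if (!is.null(markers$allele_P1)) {
      flip <- !is.na(hit) & sites$ref[hit] != markers$allele_P1
      tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    }
    data.frame(reads_P1 = r1, reads_P2 = r2)
  }
  counts <- lapply(keep_samples, function(s) {
    align(as.numeric(ref_n[, s]), as.numeric(alt_n[, s]))
  })
  names(counts) <- keep_samples
  list(sites = sites, counts = counts, n_skipped = n_skipped)
}

#' Read a sample-role manifest
#'
#' TSV with columns `sample_id`, `role` (P1/P2/F1/PROGENY), `replicate`
#' and optional `generation`.
#'
#' @param path manifest file.
#' @return validated `data.frame`.
#' @export
read_sample_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stop_if_not_cols(m, c("sample_id", "role", "replicate"), "manifest")
  if (anyDuplicated(m$sample_id)) {
    stop("manifest sample_ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(m$role), c("P1", "P2", "F1", "PROGENY"))
  if (length(bad)) {
    stop(sprintf("unknown role(s) in manifest: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m
}

#' Read a BED mask file
#'
#' 0-based half-open intervals; a `source` label (TANDEM_REPEAT, SV,
#' INDEL, ERROR_PRONE, ...) is attached from the BED name column when
#' present, else from `label`.
#'
#' @param path BED file (>= 3 columns, no header).
#' @param label fallback source label.
#' @return `data.frame` with `chrom`, `start`, `end`, `source`.
#' @export
read_mask_bed <- function(path, label = "MASK") {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(b) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  data.frame(chrom = b[[1]], start = as.numeric(b[[2]]),
             end = as.numeric(b[[3]]),
             source = if (ncol(b) >= 4) as.character(b[[4]]) else label,
             stringsAsFactors = FALSE)
}

#' Read a chromosome-length table
#'
#' TSV with columns `chrom` and `length`.
#' @param path file path.
#' @return a chromosome map (see [chrom_map()]).
#' @export
read_chrom_lengths <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stop_if_not_cols(t, c("chrom", "length"), "chromosome-length table")
  chrom_map(t$chrom, t$length)
}

#' Write a data frame as TSV with a provenance header
#'
#' Results tables (landscapes, segments, summaries, truth tables,
#' histograms) are written as TSV with `#`-prefixed provenance lines
#' (package version, seed, parameters) that [read_clonescan_tsv()] skips.
#'
#' @param df data frame.
#' @param path output file.
#' @param provenance optional named list recorded as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_clonescan_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# clonescan %s",
                     as.character(utils::packageVersion("clonescan"))), con)
  for (key in names(provenance)) {
    writeLines(sprintf("# %s: %s", key,
                       paste(format(provenance[[key]]), collapse = " ")), con)
  }
  # floats at 6 significant digits; integer-valued doubles (positions,
  # counts) are written exactly
  frac <- vapply(df, function(x) {
    is.double(x) && any(x != round(x), na.rm = TRUE)
  }, logical(1))
  df[frac] <- lapply(df[frac], signif, digits = 6)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_clonescan_tsv()]
#' @param path file path.
#' @return data frame (provenance comment lines skipped).
#' @export
read_clonescan_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write segments or crossover events as BED
#'
#' 0-based half-open intervals; the name column holds the segment class or
#' the flanking classes of a breakpoint interval.
#'
#' @param df segments (with `class`) or events (with `class_left`,
#'   `class_right`).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(df, path) {
  name <- if ("class" %in% names(df)) {
    df$class
  } else {
    paste0(df$class_left, ">", df$class_right)
  }
  bed <- data.frame(df$chrom, format(df$start, scientific = FALSE,
                                     trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' A run configuration bundles input paths and the per-stage parameter
#' blocks (marker filter, window thresholds, reproduction and sequencing
#' simulation settings) plus the global seed. Per-stage seeds are derived
#' from the global seed by fixed offsets so stages are independently
#' reproducible.
#'
#' @param path YAML file.
#' @return list with validated parameter blocks (`marker_filter` as
#'   [marker_filter_params()], `window` as [window_thresholds()], plus any
#'   further entries as given) and a `stage_seed(offset)` helper.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$marker_filter)) {
    cfg$marker_filter <- do.call(marker_filter_params, cfg$marker_filter)
  }
  if (!is.null(cfg$window)) {
    cfg$window <- do.call(window_thresholds, cfg$window)
  }
  for (p in cfg$paths) {
    if (!file.exists(p)) stop(sprintf("configured path not found: %s", p),
                              call. = FALSE)
  }
  seed <- cfg$seed %||% 1L
  cfg$stage_seed <- function(offset) as.integer(seed) + as.integer(offset)
  cfg
}
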