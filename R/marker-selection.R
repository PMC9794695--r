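#' Reference allelic ratio of a site call
#'
#' @param ref_count,alt_count reads supporting the reference / alternate
#'   allele (nonnegative integers; vectors recycle).
#' @return `ref_count / (ref_count + alt_count)`, in `[0, 1]`.
#' @export
allelic_ratio <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  if (any(depth == 0)) {
    stop("allelic ratio is undefined at depth 0", call. = FALSE)
  }
  ref_count / depth
}

#' Classify a per-sample site call from allele depths
#'
#' A replicate is homozygous when its minor-allele read count is zero or
#' its minor fraction is at most `hom_minor_frac` (low-depth tolerance);
#' it is `MISSING` at depth zero, otherwise `HET`.
#'
#' @param ref_count,alt_count allele-depth vectors.
#' @param hom_minor_frac maximum minor-allele fraction still called
#'   homozygous (default 0.05).
#' @return character vector in `HOM_REF` / `HET` / `HOM_ALT` / `MISSING`.
#' @export
classify_site_call <- function(ref_count, alt_count, hom_minor_frac = 0.05) {
  depth <- ref_count + alt_count
  minor <- pmin(ref_count, alt_count)
  out <- rep("HET", length(depth))
  out[depth == 0] <- "MISSING"
  hom <- depth > 0 & (minor == 0 | minor / depth <= hom_minor_frac)
  out[hom & ref_count >= alt_count] <- "HOM_REF"
  out[hom & alt_count > ref_count] <- "HOM_ALT"
  out
}

#' Marker filter parameters
#'
#' Defaults follow the high-confidence filter: every replicate of every
#' role needs sequencing depth larger than three (`min_depth = 4`), and the
#' F1 reference allelic ratio must lie strictly inside (0.3, 0.7).
#'
#' @param min_depth minimum depth per replicate (depth > 3 means 4).
#' @param ratio_low,ratio_high open-interval bounds on the F1 reference
#'   allelic ratio.
#' @param hom_minor_frac parental homozygosity tolerance (see
#'   [classify_site_call()]).
#' @param mask_flank base pairs excluded around masked intervals.
#' @return list of class `marker_filter_params`.
#' @export
marker_filter_params <- function(min_depth = 4, ratio_low = 0.3,
                                 ratio_high = 0.7, hom_minor_frac = 0.05,
                                 mask_flank = 0) {
  stopifnot(min_depth >= 1, ratio_low >= 0, ratio_high <= 1,
            ratio_low < ratio_high, mask_flank >= 0)
  structure(list(min_depth = as.integer(min_depth), ratio_low = ratio_low,
                 ratio_high = ratio_high, hom_minor_frac = hom_minor_frac,
                 mask_flank = mask_flank),
            class = "marker_filter_params")
}

#' Remove candidate sites overlapping repeat/SV masks
#'
#' Masks (tandem repeats, structural variants, indels, error-prone regions)
#' are 0-based half-open intervals; candidate sites are 1-based positions.
#' A site is removed when it falls inside any mask interval expanded by
#' `flank` on both sides.
#'
#' @param sites `data.frame` with `chrom` and `pos` (1-based), sorted by
#'   position within chromosome.
#' @param masks `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open); may be empty or NULL.
#' @param flank base pairs added to each side of every mask interval.
#' @return the subset of `sites` not overlapping any expanded mask.
#' @export
apply_masks <- function(sites, masks, flank = 0) {
  stop_if_not_cols(sites, c("chrom", "pos"), "sites")
  unsorted <- tapply(sites$pos, sites$chrom, is.unsorted)
  if (any(unsorted)) {
    stop("candidate sites must be sorted by position within chromosome",
         call. = FALSE)
  }
  if (is.null(masks) || nrow(masks) == 0) return(sites)
  stop_if_not_cols(masks, c("chrom", "start", "end"), "masks")
  drop <- rep(FALSE, nrow(sites))
  for (ch in unique(masks$chrom)) {
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    mi <- masks[masks$chrom == ch, , drop = FALSE]
    # convert 0-based half-open [start, end) to 1-based closed, plus flank
    q <- IRanges::IRanges(start = sites$pos[si], width = 1L)
    s <- IRanges::IRanges(start = pmax(1, mi$start + 1 - flank),
                          end = mi$end + flank)
    hit <- IRanges::overlapsAny(q, s)
    drop[si[hit]] <- TRUE
  }
  sites[!drop, , drop = FALSE]
}

#' Select high-confidence parent-differentiating SNP markers
#'
#' A candidate site is kept as a marker iff:
#' \itemize{
#'   \item every replicate of every role has depth >= `min_depth`
#'     (i.e. "larger than three" at the defaults) and no missing data;
#'   \item all P1 replicates are homozygous for one allele and all P2
#'     replicates homozygous for the other, the two parents fixed for
#'     different alleles;
#'   \item every F1 replicate is heterozygous with reference allelic ratio
#'     strictly inside `(ratio_low, ratio_high)`.
#' }
#' The kept site's `allele_P1`/`allele_P2` assignment follows the parental
#' genotypes.
#'
#' @param sites `data.frame` with `chrom`, `pos`, `ref`, `alt` describing
#'   the candidate biallelic SNPs, sorted by position within chromosome.
#' @param p1_reps,p2_reps,f1_reps lists (>= 1 per role) of `data.frame`s
#'   aligned to `sites`, each with `ref_count` and `alt_count`.
#' @param params a [marker_filter_params()].
#' @return list with `markers` (a marker map: `chrom`, `pos`, `allele_P1`,
#'   `allele_P2`) and `audit` (`chrom`, `pos`, `kept`, `reason`).
#' @export
select_informative_markers <- function(sites, p1_reps, p2_reps, f1_reps,
                                       params = marker_filter_params()) {
  stop_if_not_cols(sites, c("chrom", "pos", "ref", "alt"), "sites")
  roles <- list(P1 = p1_reps, P2 = p2_reps, F1 = f1_reps)
  for (role in names(roles)) {
    reps <- roles[[role]]
    if (length(reps) < 1) {
      stop(sprintf("at least one %s replicate is required", role),
           call. = FALSE)
    }
    for (r in reps) {
      stop_if_not_cols(r, c("ref_count", "alt_count"), "replicate calls")
      if (nrow(r) != nrow(sites)) {
        stop("replicate call vectors are not aligned to the candidate sites",
             call. = FALSE)
      }
    }
  }

  n <- nrow(sites)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }

  all_reps <- c(p1_reps, p2_reps, f1_reps)
  depth_ok <- Reduce(`&`, lapply(all_reps, function(r) {
    r$ref_count + r$alt_count >= params$min_depth
  }))
  note(!depth_ok, "low_depth_or_missing")

  geno <- function(reps) {
    lapply(reps, function(r) {
      classify_site_call(r$ref_count, r$alt_count, params$hom_minor_frac)
    })
  }
  g_p1 <- geno(p1_reps)
  g_p2 <- geno(p2_reps)

  hom_consistent <- function(g) {
    first <- g[[1]]
    ok <- first %in% c("HOM_REF", "HOM_ALT")
    for (gg in g[-1]) ok <- ok & (gg == first)
    ok
  }
  p1_hom <- hom_consistent(g_p1)
  p2_hom <- hom_consistent(g_p2)
  note(!p1_hom, "p1_not_homozygous")
  note(!p2_hom, "p2_not_homozygous")

  parents_differ <- p1_hom & p2_hom & (g_p1[[1]] != g_p2[[1]])
  note(p1_hom & p2_hom & !parents_differ, "parents_share_allele")

  f1_ok <- Reduce(`&`, lapply(f1_reps, function(r) {
    depth <- r$ref_count + r$alt_count
    ratio <- ifelse(depth > 0, r$ref_count / depth, NA_real_)
    !is.na(ratio) & ratio > params$ratio_low & ratio < params$ratio_high
  }))
  note(!f1_ok, "f1_ratio_out_of_bounds")

  keep <- depth_ok & parents_differ & f1_ok
  audit <- data.frame(chrom = sites$chrom, pos = sites$pos, kept = keep,
                      reason = ifelse(keep, "kept", reason),
                      stringsAsFactors = FALSE)

  if (!any(keep)) {
    warning("no candidate site survived the marker filter", call. = FALSE)
  }
  kept <- sites[keep, , drop = FALSE]
  p1_is_ref <- g_p1[[1]][keep] == "HOM_REF"
  markers <- data.frame(
    chrom = kept$chrom, pos = kept$pos,
    allele_P1 = ifelse(p1_is_ref, kept$ref, kept$alt),
    allele_P2 = ifelse(p1_is_ref, kept$alt, kept$ref),
    stringsAsFactors = FALSE
  )
  rownames(markers) <- NULL
  list(markers = markers, audit = audit)
}
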