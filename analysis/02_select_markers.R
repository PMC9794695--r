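#!/usr/bin/env Rscript
# Stage 2 — high-confidence marker selection.
#
# Reproduces the marker filter on the simulated cohort: candidate sites
# overlapping repeat/SV masks are removed, then a site is kept only when
# both parents are fixed for different alleles (two replicates each,
# homozygous), every F1 replicate is heterozygous with reference allelic
# ratio strictly inside (0.3, 0.7), and every replicate of every role has
# depth > 3.

suppressPackageStartupMessages(library(clonescan))

raw <- read_observations_vcf("results/cohort.vcf")
manifest <- read_sample_manifest("results/manifest.tsv")
masks <- read_mask_bed("results/masks.bed")

sites <- raw$sites
kept_sites <- apply_masks(sites, masks)
cat(sprintf("candidate sites: %d; after masking: %d (%d removed)\n",
            nrow(sites), nrow(kept_sites), nrow(sites) - nrow(kept_sites)))

keep_idx <- match(paste(kept_sites$chrom, kept_sites$pos),
                  paste(sites$chrom, sites$pos))
reps_of <- function(role) {
  ids <- manifest$sample_id[manifest$role == role]
  lapply(raw$counts[ids], function(x) {
    data.frame(ref_count = x$reads_P1[keep_idx],
               alt_count = x$reads_P2[keep_idx])
  })
}
res <- select_informative_markers(kept_sites, reps_of("P1"), reps_of("P2"),
                                  reps_of("F1"))
cat(sprintf("high-confidence markers kept: %d / %d (%.1f%%)\n",
            nrow(res$markers), nrow(kept_sites),
            100 * nrow(res$markers) / nrow(kept_sites)))
print(table(res$audit$reason))

write_clonescan_tsv(res$markers, "results/markers.tsv")
write_clonescan_tsv(res$audit, "results/marker_audit.tsv")
cat("wrote results/markers.tsv and results/marker_audit.tsv\n")
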