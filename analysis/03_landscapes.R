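#!/usr/bin/env Rscript
# Stage 3 — genotype landscapes and crossover detection.
#
# Rebuilds each progeny sample's genome-wide genotype landscape from its
# 1.9x allele depths pooled over 200 kb windows sliding by 100 kb,
# consolidates the windows into genotype segments, and locates
# heterozygous-to-homozygous transitions (crossover breakpoints).

suppressPackageStartupMessages(library(clonescan))

markers <- read_clonescan_tsv("results/markers.tsv")
manifest <- read_sample_manifest("results/manifest.tsv")
cm <- chrom_map(c("chr1", "chr8"), c(8e6, 6e6))
wins <- make_windows(cm)

progeny <- manifest$sample_id[manifest$role == "PROGENY"]
raw <- read_observations_vcf("results/cohort.vcf", markers = markers,
                             samples = progeny)

landscapes <- list()
segments <- list()
events <- list()
for (s in progeny) {
  ls <- build_landscape(raw$counts[[s]], markers, wins, sample_id = s)
  segs <- consolidate(ls)
  ev <- detect_crossovers(segs, cm)
  landscapes[[s]] <- ls
  segments[[s]] <- segs
  events[[s]] <- ev
  called <- ls$class != "NO_CALL"
  cat(sprintf("%-10s called windows %3d/%3d  HET %5.1f%%  crossover events %d\n",
              s, sum(called), nrow(ls),
              100 * mean(ls$class[called] == "HET"), nrow(ev)))
}

write_clonescan_tsv(do.call(rbind, landscapes), "results/landscape.tsv")
write_intervals_bed(do.call(rbind, segments), "results/segments.bed")
all_ev <- do.call(rbind, events)
if (nrow(all_ev)) write_intervals_bed(all_ev, "results/events.bed")
write_clonescan_tsv(all_ev, "results/events.tsv")
cat("wrote results/landscape.tsv, segments.bed, events.bed, events.tsv\n")
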