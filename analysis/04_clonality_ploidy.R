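#!/usr/bin/env Rscript
# Stage 4 — clonality classification, ploidy calls, event summaries.
#
# Classifies each progeny as clonal vs recombinant from its landscape and
# crossover events, runs the four-marker heterozygosity panel on the
# clones, calls leaf ploidy and endosperm C-value profiles from the flow
# histograms, and produces the percent-diploid event summary with an
# exact binomial confidence interval.

suppressPackageStartupMessages(library(clonescan))

landscape <- read_clonescan_tsv("results/landscape.tsv")
events <- read_clonescan_tsv("results/events.tsv")
truth <- read_clonescan_tsv("results/truth.tsv")

reports <- do.call(rbind, lapply(unique(landscape$sample_id), function(s) {
  assess_clonality(landscape[landscape$sample_id == s, ],
                   events[!is.na(events$sample_id) &
                            events$sample_id == s, , drop = FALSE])
}))
reports$true_mode <- truth$mode[match(reports$sample_id, truth$sample_id)]
write_clonescan_tsv(reports, "results/clonality.tsv")
cat("clonality classification vs simulated truth:\n")
print(table(reports$true_mode, reports$classification))
cat("note: unrecombined tetraploids (MIME_SELF) are expected to look\n",
    "CLONAL in the landscape — every marker reads 0.5/0.5 — so ploidy\n",
    "is resolved by flow cytometry below, not by the landscape.\n", sep = "")

# four-marker panel on the clonal T1s: error-free genotyping means every
# clone is heterozygous at all loci (per-plant sexual probability 1/16)
clones <- reports$sample_id[reports$true_mode == "PARTHENOGENESIS"]
pt <- panel_test(matrix(TRUE, nrow = length(clones), ncol = 4))
cat(sprintf("panel test: %d/%d clones all-het at 4 loci (log10 LR = %.1f)\n",
            pt$all_het_count, pt$n, pt$log10_lr))

# leaf ploidy from flow histograms (control: simulated diploid leaf)
control_channel <- 100  # 2C at channel_per_C = 50
leaf <- c("leaf_diploid", "leaf_tetraploid", "leaf_chimera")
calls <- do.call(rbind, lapply(leaf, function(nm) {
  h <- read_clonescan_tsv(sprintf("results/flow_%s.tsv", nm))
  call_ploidy(h, control_channel, sample_id = nm)
}))
write_clonescan_tsv(calls, "results/ploidy_calls.tsv")
print(calls[, c("sample_id", "call", "primary_ratio")])

for (nm in c("endosperm_sexual", "endosperm_mime")) {
  h <- read_clonescan_tsv(sprintf("results/flow_%s.tsv", nm))
  prof <- endosperm_profile(h, control_channel)
  cat(sprintf("%s: base %dC, endoreduplication series %s\n", nm,
              prof$base_C, paste0(paste(prof$series, collapse = "C/"), "C")))
}

# event-style percent-diploid summary over a simulated T1 family
cm <- chrom_map(c("chr1", "chr8"), c(8e6, 6e6))
mk <- make_marker_map(cm, 2, seed = 77)
prog <- simulate_progeny(f1_genome(mk), mk, cm, "MIME_BBM1", n = 300,
                         p = 0.95, seed = 78)
pl <- ifelse(vapply(prog, `[[`, integer(1), "ploidy") == 2L,
             "DIPLOID", "TETRAPLOID")
summ <- summarize_event(pl, event_id = "simulated_T314_like")
write_clonescan_tsv(summ, "results/event_summary.tsv")
cat(sprintf("event %s: %d analyzed, %d diploid -> %d%% diploid (95%% CI %.1f-%.1f)\n",
            summ$event_id, summ$n_analyzed, summ$n_diploid,
            summ$percent_diploid, summ$ci_low, summ$ci_high))
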