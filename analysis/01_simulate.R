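#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Forward-simulates a demonstration cohort from a two-chromosome subset of
# the rice genome: two homozygous parents differing at every marker, the
# fully heterozygous F1 hybrid, sexual F2 progeny, unrecombined tetraploids
# (apomeiosis only) and diploid clones (apomeiosis + parthenogenesis).
# Parents/F1 are "sequenced" at 14.3x, progeny at 1.9x. Writes a
# multi-sample VCF with allele depths, a truth table, and flow-cytometry
# histograms for leaf and endosperm samples.

suppressPackageStartupMessages(library(clonescan))
seed <- 42
set.seed(seed)
dir.create("results", showWarnings = FALSE)

# two demonstration chromosomes at the study's genome-wide marker density
# (~0.72 markers/kb), short enough to keep the demo instantaneous
cm <- chrom_map(c("chr1", "chr8"), c(8e6, 6e6))
mk <- make_marker_map(cm, round(cm$length * 0.00072), seed = seed)
f1 <- f1_genome(mk)
cat(sprintf("genome: %d chromosomes, %d markers\n", nrow(cm), nrow(mk)))

hom <- function(origin) {
  structure(list(ploidy = 2L, mode = "PARENT",
                 haplotypes = list(rep(origin, nrow(mk)),
                                   rep(origin, nrow(mk))),
                 breakpoints = NULL), class = "progeny_genome")
}

genomes <- c(
  setNames(lapply(1:2, function(i) hom(1L)), paste0("P1_", 1:2)),
  setNames(lapply(1:2, function(i) hom(2L)), paste0("P2_", 1:2)),
  setNames(lapply(1:2, function(i) f1), paste0("F1_", 1:2)),
  setNames(simulate_progeny(f1, mk, cm, "SEXUAL", n = 6, seed = seed + 1),
           paste0("F2_", 1:6)),
  setNames(simulate_progeny(f1, mk, cm, "MIME_ONLY", n = 2, seed = seed + 2),
           paste0("T313_", 1:2)),
  setNames(simulate_progeny(f1, mk, cm, "MIME_BBM1", n = 3, p = 1,
                            seed = seed + 3), paste0("T314_", 1:3))
)
roles <- c(rep("P1", 2), rep("P2", 2), rep("F1", 2), rep("PROGENY", 11))
depth <- ifelse(roles == "PROGENY", 1.9, 14.3)

obs <- Map(function(g, d, i) {
  simulate_reads(g, mk, mean_depth = d, error_rate = 0.002, seed = seed + 10 + i)
}, genomes, depth, seq_along(genomes))

sites <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$allele_P1,
                    alt = mk$allele_P2, stringsAsFactors = FALSE)
write_observations_vcf(obs, sites, "results/cohort.vcf",
                       provenance = sprintf("seed=%d", seed))

manifest <- data.frame(sample_id = names(genomes), role = roles,
                       replicate = ave(seq_along(roles), roles, FUN = seq_along),
                       generation = c(rep("parent", 4), rep("F1", 2),
                                      rep("F2", 6), rep("T1", 5)))
write.table(manifest, "results/manifest.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- data.frame(
  sample_id = names(genomes),
  ploidy = vapply(genomes, `[[`, integer(1), "ploidy"),
  mode = vapply(genomes, `[[`, character(1), "mode"),
  n_breakpoints = vapply(genomes, function(g) {
    if (is.null(g$breakpoints)) 0L else nrow(g$breakpoints)
  }, integer(1)))
write_clonescan_tsv(truth, "results/truth.tsv",
                    provenance = list(seed = seed))
cat(sprintf("cohort: %d samples (%d F2, 2 tetraploid, 3 clonal T1)\n",
            length(genomes), 6))
cat(sprintf("true crossovers in the F2s: %d\n",
            sum(truth$n_breakpoints[truth$mode == "SEXUAL"])))

# masks: two arbitrary repeat/SV exclusion zones per chromosome
masks <- data.frame(chrom = rep(cm$chrom, each = 2),
                    start = rep(c(2e6, 5e6), nrow(cm)),
                    end = rep(c(2.2e6, 5.05e6), nrow(cm)),
                    source = c("TANDEM_REPEAT", "SV"))
write.table(masks, "results/masks.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

# flow cytometry: leaf samples and developing endosperm
fc <- flow_sim_config()
hists <- list(
  leaf_diploid = data.frame(C = 2, fraction = 1),
  leaf_tetraploid = data.frame(C = 4, fraction = 1),
  leaf_chimera = data.frame(C = c(2, 4), fraction = c(0.3, 0.7)),
  endosperm_sexual = data.frame(C = c(3, 6, 12), fraction = c(0.5, 0.3, 0.2)),
  endosperm_mime = data.frame(C = c(6, 12, 24), fraction = c(0.5, 0.3, 0.2))
)
for (nm in names(hists)) {
  h <- simulate_flow_histogram(hists[[nm]], fc,
                               seed = seed + 100 + match(nm, names(hists)))
  write_clonescan_tsv(h, sprintf("results/flow_%s.tsv", nm),
                      provenance = list(seed = seed, sample = nm))
}
cat("wrote results/cohort.vcf, truth.tsv, manifest.tsv, masks.bed and",
    length(hists), "flow histograms\n")
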