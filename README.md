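# clonescan

Verification of clonal reproduction and ploidy in hybrid rice from
low-coverage sequencing.

## The problem

Synthetic apomixis — combining the *MiMe* triple mutation (which converts
meiosis into a mitosis-like division yielding unreduced, unrecombined
gametes) with egg-cell expression of the parthenogenesis trigger *BBM1* —
lets an F1 hybrid propagate clonally through seed. Checking that it worked
is a genomics problem: clonal progeny must retain the F1's heterozygous
genotype at every marker genome-wide and be diploid, while failures are
either recombinant (sexual F2, heterozygous→homozygous transitions at
crossovers) or unrecombined tetraploids (apomeiosis without
parthenogenesis). Progeny are sequenced at very low coverage (~1.9
reads/marker), so single markers are uninformative and genotypes must be
reconstructed in sliding windows. An unrecombined tetraploid looks exactly
like a diploid clone in the allelic signal, so ploidy is resolved
separately from flow-cytometry histograms.

`clonescan` is for analysts validating apomictic (or other clonal)
breeding material from low-pass resequencing plus flow cytometry, and for
methodologists who want a simulator with the matching statistical
structure to test such pipelines against known truth.

## What it computes

* **Simulator** — parental/F1/progeny genomes under sexual reproduction,
  apomeiosis (`MIME_ONLY`) and apomeiosis+parthenogenesis (`MIME_BBM1`,
  clone probability *p*); meiosis with 1 obligate + Poisson(0.5) extra
  crossovers per chromosome; Poisson-depth reads with error ε; endosperm
  C-values (3C sexual vs 6C MiMe) and flow histograms with
  endoreduplication series.
* **Marker selection** — the high-confidence filter: parents fixed for
  different alleles (replicated, homozygous), F1 replicates heterozygous
  with reference allelic ratio strictly in (0.3, 0.7), depth > 3
  everywhere, repeat/SV BED masks excluded.
* **Genotype landscape** — 200 kb windows sliding by 100 kb; pooled read
  counts per window classified HOM_P1 / HET / HOM_P2 / NO_CALL (f ≥ 0.9 /
  ≤ 0.1, ≥ 5 reads); majority-of-3 smoothing; segment consolidation;
  crossover breakpoint intervals at window+step (~300 kb) resolution.
* **Clonality & ploidy** — CLONAL = ≥ 99% HET called windows and zero
  crossover events; the 2^−k all-heterozygous panel test; G1-peak ploidy
  calls (diploid / tetraploid / 2n-4n chimera) from histograms; per-event
  percent-diploid summaries with exact Clopper–Pearson 95% CIs, matching
  the half-up rounding of the published event tables.

## Worked example

Simulate one selfed F2 on a two-chromosome genome at the study's marker
density, resequence it at 1.9×, and recover its crossovers:

```r
library(clonescan)
cm  <- chrom_map(c("chr1", "chr2"), c(8e6, 6e6))
mk  <- make_marker_map(cm, round(cm$length * 0.00072), seed = 1)
f1  <- f1_genome(mk)
f2  <- simulate_progeny(f1, mk, cm, "SEXUAL", n = 1, seed = 2)[[1]]
obs <- simulate_reads(f2, mk, mean_depth = 1.9, error_rate = 0.002, seed = 3)
ls  <- build_landscape(obs, mk, make_windows(cm), sample_id = "F2_1")
ev  <- detect_crossovers(consolidate(ls), cm)

f2$breakpoints                 # simulated truth
#>   hap chrom     pos
#> 1   1  chr1 5618992
#> 2   1  chr2 5663036
#> 3   2  chr1 6667591
#> 4   2  chr2 3316044
ev[, c("chrom", "start", "end", "class_left", "class_right")]
#>   chrom   start     end class_left class_right
#> 1  chr1 5500000 5800000        HET      HOM_P1
#> 2  chr1 6500000 6800000     HOM_P1         HET
#> 3  chr2 3200000 3500000        HET      HOM_P2
#> 4  chr2 5400000 5700000     HOM_P2         HET
```

All four simulated crossovers are detected, each breakpoint interval
(0-based, 300 kb wide) containing the true position. The sample is then
classified from the same objects:

```r
assess_clonality(ls, ev)
#>   sample_id called_windows het_fraction n_crossover_events classification
#> 1      F2_1            138    0.7681159                  4    RECOMBINANT
```

A clone instead shows `het_fraction` 1.0, zero events, `CLONAL`. Event
tables are summarised from ploidy calls or printed counts — e.g. 64
diploids and 1 tetraploid:

```r
event_summary(64, 1, event_id = "15.1")
#>   event_id n_analyzed n_diploid n_tetraploid percent_diploid   ci_low  ci_high
#> 1     15.1         65        64            1              98 91.72369 99.96106
```

i.e. 98% diploid progeny with an exact 95% CI of 91.7–99.96% on the
diploid fraction.

## The analysis workflow

`analysis/` holds the end-to-end demonstration, each stage a thin driver
over the package writing under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort VCF, truth, masks, flow histograms
Rscript analysis/02_select_markers.R    # high-confidence marker filter + audit
Rscript analysis/03_landscapes.R        # window landscapes, segments, crossovers
Rscript analysis/04_clonality_ploidy.R  # clonality, panel test, ploidy, event summary
```

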