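---
title: "Verifying clonal reproduction and ploidy in hybrid rice from low-coverage sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying clonal reproduction and ploidy in hybrid rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescan)
```

## The problem

Synthetic apomixis engineers asexual reproduction through seed into a
sexual crop. In rice this is done by combining the *MiMe* triple mutation
(*PAIR1*, *REC8*, *OSD1*), which turns meiosis into a mitosis-like
division that produces unreduced, unrecombined gametes, with egg-cell
expression of the *BABYBOOM1* (*BBM1*) transcription factor, which
triggers embryogenesis from the unfertilised egg. Applied to an F1 hybrid,
a successful event produces seed whose embryos are diploid clones of the
F1; failures of the parthenogenetic trigger instead give tetraploids from
the fusion of two unreduced gametes.

Verifying that a plant really is a clone has two independent parts:

* **genotype**: a clone retains the F1's heterozygous genotype at every
  marker genome-wide, whereas sexual (selfed F2) progeny show
  heterozygous-to-homozygous transitions at meiotic crossovers;
* **ploidy**: a clone is diploid; an apomeiotic-but-fertilised sibling is
  tetraploid. Crucially, an *unrecombined tetraploid is indistinguishable
  from a diploid clone in the sequencing signal* — both present a 0.5/0.5
  allelic ratio at every marker — so ploidy must come from flow cytometry,
  never from the genotype landscape.

`clonescan` implements both parts as a tested pipeline, together with a
forward simulator that generates data with exactly the statistical
structure the downstream stages assume, so every stage can be validated
against known truth.

## The simulator: what it emulates

`f1_genome()` defines the reference individual: one haplotype carrying
parent-1 (P1) alleles at every marker, one carrying parent-2 (P2) alleles.
Three reproduction modes are simulated by `simulate_progeny()`:

* `SEXUAL` — selfing: each progeny fuses two independent meiotic gametes
  of the same F1;
* `MIME_ONLY` — apomeiosis without parthenogenesis: every progeny is an
  unrecombined tetraploid (two copies of each F1 haplotype);
* `MIME_BBM1` — apomeiosis plus parthenogenesis at rate `p`: with
  probability `p` a diploid clone, otherwise a tetraploid as above.

**Crossover model.** Meiotic gametes receive one obligate crossover per
chromosome plus a Poisson(0.5) number of extras, placed uniformly with no
interference. Rice chromosomes typically experience ~1.5–2 crossovers, so
the default expectation of 1.5 is realistic; both parameters are
arguments. The true crossover count distribution underlying any given
dataset is unknown, so this model is a documented stand-in and every
downstream accuracy statement is conditional on it.

**Sequencing.** `simulate_reads()` draws Poisson depth per marker
(defaults: 1.9 reads/marker for progeny, 14.3 for parents and F1 — the
coverage regime of low-pass progeny resequencing), picks a haplotype
uniformly per read, and flips the reported allele with error probability
0.002. Reads are independent given depth, so allele counts are binomial —
sampled directly, which keeps a 268k-marker genome fast. At a heterozygous
site with depth mean λ the probability of observing both alleles is
`1 − 2·exp(−λ/2) + exp(−λ)` (`prob_both_alleles_observed()`), ≈ 0.376 at
λ = 1.9: most markers are individually uninformative, which is exactly why
the window method below exists.

**Endosperm and flow cytometry.** Sexual endosperm starts at 3C (two
maternal + one paternal genome); under apomeiosis both the central-cell
nuclei and the sperm are diploid, shifting the start to 6C
(`endosperm_initial_cvalue()`). Cereal endosperm endoreduplicates to
12C–24C during development, so observed histograms are mixtures over a
doubling series. `simulate_flow_histogram()` draws Gaussian peaks centred
at channels proportional to C-value (CV 0.05 by default, 1024 channels,
2C control at channel 100) over a uniform debris floor.

**What the simulator does not model** (and hence what passing tests do
not show about real data): alignment and variant-calling artefacts,
depth heterogeneity along the genome (GC, repeats), linked read errors,
segregation distortion, aneuploidy, and *osd1* meiosis-II leakage
(triads/tetrads). Real-data robustness rests on the marker filter and
masks, not on the simulator.

## Marker selection

`select_informative_markers()` reproduces the high-confidence filter from
replicate parental and F1 calls: parents fixed for different alleles
(every replicate homozygous), every F1 replicate heterozygous with
reference allelic ratio strictly inside (0.3, 0.7), and depth > 3 in
every replicate of every role. Choices the source description leaves
open, fixed here:

* the depth rule is applied to *every replicate of every role* — the
  strictest reading, chosen for reproducibility;
* parental homozygosity tolerates a minor-allele fraction ≤ 0.05
  (configurable); a hard zero would reject most true sites at 14×
  coverage with any sequencing error;
* the ratio bounds are strict inequalities: 0.3 and 0.7 exactly fail;
* sites with missing data in any required replicate are rejected — no
  imputation;
* "reference allelic ratio" is computed against the VCF reference allele,
  as stated.

Repeat/SV/indel masks are consumed as BED intervals (`apply_masks()`,
0-based half-open, optional flank); generating them is out of scope. The
filter is deliberately lossy: at 14× the F1 ratio window alone discards
roughly a quarter of true sites (Binomial(14, 0.5) mass outside
(0.3, 0.7) per replicate). That is the intended behaviour of a
*high-confidence* filter — marker density, not completeness, is what the
window genotyper needs.

## The genotype landscape

`make_windows()` lays 200 kb windows sliding by 100 kb from position 0;
only full windows are created and the trailing remainder is merged into
the final window (so the last window can be up to `window + step − 1` bp).
`build_landscape()` pools P1/P2 read counts over the markers in each
window — read-count pooling rather than per-marker genotype votes, because
at 1.9× most markers have 0–2 reads — and classifies:

| class | rule (defaults) |
|---|---|
| `NO_CALL` | fewer than 5 informative reads |
| `HOM_P1`  | P1 fraction ≥ 0.9 |
| `HOM_P2`  | P1 fraction ≤ 0.1 |
| `HET`     | otherwise |

At the study's marker density (~0.72/kb, ≈144 markers per window) a
window collects ~270 reads at 1.9×, so a heterozygous window is
essentially never misclassified; the thresholds matter only in sparse or
masked regions. All thresholds are arguments.

`consolidate()` turns the window sequence into segments: one pass of a
width-3 majority filter (an isolated one-window flip flanked by two
identical called classes is reassigned; disable with `smooth = FALSE`),
then maximal constant runs, with `NO_CALL` runs absorbed when both
neighbours agree and left as gaps otherwise. How overlapping windows are
best collapsed into blocks is a genuinely open design point; this
filter-then-merge rule is this package's choice and is checked against a
brute-force run enumeration in the tests.

`detect_crossovers()` emits one event between adjacent differing-class
segments. The breakpoint interval is `[old segment end − window,
new segment start + window)`, clipped to the chromosome: `window + step`
wide (≈300 kb), the localisation resolution of 50%-overlapping windows.
The symmetric one-window margin is required because the asymmetric 0.9
homozygosity threshold shifts the *observed* class boundary by up to
0.8·window into the heterozygous side of the true breakpoint; a
narrower, asymmetric interval would miss a majority of true breakpoints.
With the default simulation conditions (λ = 1.9, ε = 0.002, real rice
chromosome lengths, 17 F2 plants = 204 chromosomes) the tests require —
and the implementation achieves — ≥ 95% of true crossovers recovered with
the interval containing the truth, and ≤ 0.05 spurious events per clonal
chromosome. The residual misses are intrinsic to the resolution: pairs of
crossovers closer than ~300 kb whose effects cancel, and crossovers
within ~200 kb of a chromosome end.

## Clonality and ploidy

`assess_clonality()` calls a sample `CLONAL` when ≥ 99% of its called
windows are `HET` *and* no crossover event was detected; `RECOMBINANT`
with ≥ 1 event; `AMBIGUOUS` otherwise. The 0.99 default tolerates rare
noise windows on a genome-scale landscape (~3,700 windows) without
permitting real recombination; on very small demonstration genomes
(~100 windows) a single noisy window can push a true clone to
`AMBIGUOUS` — a resolution artefact, not an error.

`panel_test()` is the SSR-style shortcut: with k unlinked markers
heterozygous in the F1, a selfed plant stays heterozygous at all k with
probability 2^−k (0.0625 at k = 4), so observing hundreds of all-het
progeny gives an overwhelming likelihood ratio for clonality (reported as
log10 LR of a clonal point mass vs the binomial sexual null; the clonal
model is error-free, so a single failing plant sends the LR to −∞).

`call_ploidy()` smooths the histogram (moving average, width 5), finds
local maxima above 5% of the tallest smoothed count (plateau-tolerant),
and suppresses local maxima within 25% of a taller accepted peak —
legitimate neighbouring peaks differ by a factor of 2 in channel, so 25%
cannot merge distinct C-values but removes shoulder artefacts at high CV.
The primary G1 peak (smallest channel holding ≥ 10% of events) is
compared to the diploid 2C control: ratio in [0.8, 1.2] → `DIPLOID`,
[1.7, 2.3] → `TETRAPLOID`; peaks in both bands each holding ≥ 10% →
`CHIMERIC_2N_4N`. `endosperm_profile()` maps peaks to C-values via the
same control, snaps the smallest to 3C or 6C (±20%) and reports the
detected doubling series.

`summarize_event()` produces the per-event table: counts, percent diploid
rounded half-up (68.75 → 69, matching the printed tables' arithmetic,
which `round_half_up()` reproduces on every printed row used as a
fixture), and an exact Clopper–Pearson 95% CI — chosen over a normal
approximation because events with n < 20 occur. Chimeric plants are
counted in the tetraploid column by default; the printed 35/38 → 92% row
is only consistent with the chimera sitting in the 4n count, but the
convention is an argument (`"diploid"`, `"exclude"`).

## Numerical and interface conventions

* Marker positions are 1-based (VCF convention at ingest); all interval
  outputs — windows, segments, breakpoint intervals, masks — are 0-based
  half-open (BED convention).
* Every stochastic function takes `seed`; identical seeds give
  bit-identical output. The analysis scripts fan a global seed out by
  fixed offsets so stages are independently reproducible.
* Result TSVs carry `#` provenance headers; fractional floats are written
  at 6 significant digits, integer-valued columns exactly.
* Degenerate inputs fail loudly: zero-depth allelic ratios, landscapes
  with no called window, all-`UNCALLED` event summaries and empty flow
  mixtures are errors, not silent `NA`s.

## Problem sizes used in the tests

The validation suite simulates, per run: one 12-chromosome genome at real
rice chromosome lengths with ~268,560 markers (the published genome-wide
marker count is of the same order), 17 F2 plants and 17 clones at 1.9×
for crossover recovery; 100,000 heterozygous markers for the closed-form
read-sampling check; 1,000 flow histograms for the ploidy caller; 500
replicates of 300 progeny at p ∈ {0.80, 0.95} for parthenogenesis-rate
recovery; and 765 clones for the four-marker panel. The demonstration
workflow in `analysis/` uses a two-chromosome 14 Mb genome at the same
marker density so it runs in seconds.

## Known limitations

* Ploidy is invisible to the landscape by construction; a cohort without
  flow histograms cannot separate diploid clones from unrecombined
  tetraploids.
* Breakpoint localisation is bounded below by `window + step`; crossover
  pairs closer than that and crossovers in terminal windows can cancel or
  escape detection.
* The crossover model has no interference; if real interference matters
  for a downstream question, the obligate/extra parameters only shape the
  count, not the spacing law.
* Chimeric plants are modelled only as histogram mixtures; whether they
  arise pre- or post-zygotically is not represented.
* `MISSING` genotype data is rejected, never imputed.
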