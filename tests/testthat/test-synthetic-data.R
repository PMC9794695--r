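test_that("marker maps respect the chromosome contract and are deterministic", {
  cm <- chrom_map("chr1", 100)
  mk <- make_marker_map(cm, 5, seed = 7)
  expect_equal(nrow(mk), 5)
  expect_true(all(mk$pos >= 1 & mk$pos <= 100))
  expect_true(all(diff(mk$pos) > 0))
  expect_true(all(mk$allele_P1 != mk$allele_P2))

  expect_identical(mk, make_marker_map(cm, 5, seed = 7))

  cm12 <- chrom_map(paste0("c", 1:12), rep(1000, 12))
  expect_equal(nrow(make_marker_map(cm12, 1000, seed = 1)), 12000)

  expect_error(make_marker_map(chrom_map("chr1", 10), 11, seed = 1),
               "more markers")
})

test_that("meiotic gametes follow the obligate-plus-Poisson crossover model", {
  cm <- toy_cm(1e6)
  mk <- make_marker_map(cm, 200, seed = 3)
  f1 <- f1_genome(mk)

  # no-crossover limit: whole chromosome inherits a single parental origin
  g0 <- simulate_meiotic_gamete(f1, mk, cm, obligate = 0, extra_mean = 0,
                                seed = 11)
  expect_equal(nrow(g0$breakpoints), 0)
  expect_length(unique(g0$origin), 1)

  # forced single crossover
  g1 <- simulate_meiotic_gamete(f1, mk, cm, obligate = 1, extra_mean = 0,
                                seed = 12)
  expect_equal(nrow(g1$breakpoints), 1)
  # origin switches exactly at the breakpoint
  left <- mk$pos <= g1$breakpoints$pos
  expect_length(unique(g1$origin[left]), 1)
  expect_length(unique(g1$origin[!left]), 1)
  expect_true(g1$origin[left][1] != g1$origin[!left][1])

  # Monte-Carlo: mean breakpoints per chromosome ~ obligate + extra_mean
  set.seed(99)
  tiny_mk <- make_marker_map(cm, 5, seed = 4)
  n_bp <- replicate(10000, {
    nrow(simulate_meiotic_gamete(f1_genome(tiny_mk), tiny_mk, cm,
                                 obligate = 1, extra_mean = 0.5)$breakpoints)
  })
  se <- sd(n_bp) / sqrt(length(n_bp))
  expect_lt(abs(mean(n_bp) - 1.5), 3 * se)

  tetra <- simulate_progeny(f1, mk, cm, "MIME_ONLY", n = 1, seed = 1)[[1]]
  expect_error(simulate_meiotic_gamete(tetra, mk, cm), "diploid")
})

test_that("reproduction modes produce the expected ploidy and genotypes", {
  cm <- toy_cm(1e6)
  mk <- make_marker_map(cm, 50, seed = 5)
  f1 <- f1_genome(mk)

  sex <- simulate_progeny(f1, mk, cm, "SEXUAL", n = 5, seed = 21)
  expect_true(all(vapply(sex, `[[`, integer(1), "ploidy") == 2L))
  expect_true(all(vapply(sex, `[[`, character(1), "mode") == "SEXUAL"))

  mime <- simulate_progeny(f1, mk, cm, "MIME_ONLY", n = 10, seed = 22)
  expect_true(all(vapply(mime, `[[`, integer(1), "ploidy") == 4L))
  for (g in mime) {
    expect_equal(nrow(g$breakpoints), 0)
    origins <- vapply(g$haplotypes, function(h) h[1], integer(1))
    expect_equal(sort(origins), c(1L, 1L, 2L, 2L))
    expect_true(all(genotype_at(g) == "HET"))
  }

  # p = 1 limit: every progeny a diploid clone, heterozygous at all markers
  clones <- simulate_progeny(f1, mk, cm, "MIME_BBM1", n = 50, p = 1,
                             seed = 23)
  expect_true(all(vapply(clones, `[[`, integer(1), "ploidy") == 2L))
  expect_true(all(vapply(clones, `[[`, character(1), "mode") ==
                    "PARTHENOGENESIS"))
  expect_true(all(vapply(clones, function(g) all(genotype_at(g) == "HET"),
                         logical(1))))

  # diploid fraction ~ Binomial(n, p)
  mixed <- simulate_progeny(f1, mk, cm, "MIME_BBM1", n = 10000, p = 0.95,
                            seed = 24)
  frac2n <- mean(vapply(mixed, `[[`, integer(1), "ploidy") == 2L)
  se <- sqrt(0.95 * 0.05 / 10000)
  expect_lt(abs(frac2n - 0.95), 3 * se)

  expect_error(simulate_progeny(f1, mk, cm, "SEXUAL", n = 0), "n must be")
})

test_that("parthenogenetic clones conserve the F1 genotype over generations", {
  cm <- toy_cm(1e6)
  mk <- make_marker_map(cm, 100, seed = 6)
  mother <- f1_genome(mk)
  for (g in 1:3) {
    child <- simulate_progeny(mother, mk, cm, "MIME_BBM1", n = 1, p = 1,
                              seed = 30 + g)[[1]]
    expect_identical(child$haplotypes, mother$haplotypes)
    expect_equal(mean(genotype_at(child) == "HET"), 1)  # 100% retention
    # the clone becomes the next generation's mother
    mother <- structure(list(ploidy = 2L, mode = "F1",
                             haplotypes = child$haplotypes,
                             breakpoints = child$breakpoints),
                        class = "progeny_genome")
  }
})

test_that("endosperm initial C-value reflects the reproduction mode", {
  expect_identical(endosperm_initial_cvalue("SEXUAL"), 3L)
  expect_identical(endosperm_initial_cvalue("MIME_ONLY"), 6L)
  expect_identical(endosperm_initial_cvalue("MIME_BBM1"), 6L)
})

test_that("read simulation follows the Poisson-depth binomial-allele model", {
  cm <- toy_cm(1e6)
  mk <- make_marker_map(cm, 500, seed = 8)
  f1 <- f1_genome(mk)
  hom <- structure(list(ploidy = 2L, mode = "F1",
                        haplotypes = list(rep(1L, 500), rep(1L, 500)),
                        breakpoints = NULL), class = "progeny_genome")

  r_hom <- simulate_reads(hom, mk, mean_depth = 5, error_rate = 0, seed = 41)
  expect_true(all(r_hom$reads_P2 == 0))
  expect_equal(r_hom$reads_P1, r_hom$depth)

  r0 <- simulate_reads(f1, mk, mean_depth = 0, error_rate = 0, seed = 42)
  expect_true(all(r0$depth == 0))

  # closed form for both-alleles-observed at het sites (reduced n here;
  # the full-scale check lives in the acceptance suite)
  mk_big <- make_marker_map(chrom_map("chr1", 2e8), 20000, seed = 9)
  f1_big <- f1_genome(mk_big)
  r <- simulate_reads(f1_big, mk_big, mean_depth = 1.9, error_rate = 0,
                      seed = 43)
  frac <- mean(r$reads_P1 > 0 & r$reads_P2 > 0)
  p0 <- prob_both_alleles_observed(1.9)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 20000))

  # identical seeds give bit-identical observations
  expect_identical(simulate_reads(f1, mk, 1.9, 0.002, seed = 44),
                   simulate_reads(f1, mk, 1.9, 0.002, seed = 44))
})

test_that("flow histograms place modes at channels proportional to C-value", {
  fc <- flow_sim_config(cv = 0.05, n_nuclei = 20000, debris_frac = 0.05,
                        channel_per_C = 50)
  mode_channel <- function(h) h$channel[which.max(h$count)]

  h2 <- simulate_flow_histogram(data.frame(C = 2, fraction = 1), fc, seed = 51)
  expect_lt(abs(mode_channel(h2) - 100) / 100, 0.1)

  # tetraploid leaf: dominant mode at twice the 2C control channel
  h4 <- simulate_flow_histogram(data.frame(C = 4, fraction = 1), fc, seed = 52)
  expect_lt(abs(mode_channel(h4) - 2 * mode_channel(h2)) /
              (2 * mode_channel(h2)), 0.1)

  # MiMe endosperm endoreduplication series at ratios 3:6:12 vs 2C control
  h_end <- simulate_flow_histogram(
    data.frame(C = c(6, 12, 24), fraction = c(0.5, 0.3, 0.2)), fc, seed = 53)
  pk <- find_histogram_peaks(h_end)
  ratios <- sort(pk$channel / 100)
  expect_equal(length(ratios), 3)
  expect_equal(ratios, c(3, 6, 12), tolerance = 0.1)

  expect_error(simulate_flow_histogram(data.frame(C = numeric(),
                                                  fraction = numeric()), fc),
               "at least one component")
})
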