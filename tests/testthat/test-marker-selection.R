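test_that("allelic ratio is ref/depth with strict open-interval semantics", {
  expect_equal(allelic_ratio(5, 5), 0.5)
  expect_equal(allelic_ratio(3, 7), 0.3)
  expect_equal(allelic_ratio(7, 3), 0.7)
  expect_error(allelic_ratio(0, 0), "depth 0")
  p <- marker_filter_params()
  # the printed bounds are strict: exactly 0.3 / 0.7 fail
  expect_false(allelic_ratio(3, 7) > p$ratio_low &
                 allelic_ratio(3, 7) < p$ratio_high &&
                 allelic_ratio(7, 3) > p$ratio_low &
                 allelic_ratio(7, 3) < p$ratio_high)
})

test_that("mask filtering removes exactly the covered sites", {
  sites <- data.frame(chrom = "chr1", pos = c(10, 50, 100, 150, 199, 200,
                                              250, 300, 350, 400),
                      stringsAsFactors = FALSE)
  expect_identical(apply_masks(sites, NULL), sites)
  expect_identical(apply_masks(sites, data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric())), sites)

  # 1-based site 150 is inside 0-based half-open [100, 200); 200 is not in
  # [100,200) but 1-based 200 occupies 0-based base 199 -> masked too
  m1 <- data.frame(chrom = "chr1", start = 100, end = 200)
  kept <- apply_masks(data.frame(chrom = "chr1", pos = 150), m1)
  expect_equal(nrow(kept), 0)

  # hand enumeration: masks [100,200) and [340,360) cover 100? no: site
  # pos 100 is 0-based 99 -> outside; covered sites are 150, 199, 200, 350
  # -> wait, enumerate precisely below
  m <- data.frame(chrom = "chr1", start = c(100, 340), end = c(200, 360))
  out <- apply_masks(sites, m)
  # mask [100,200) covers 1-based 101..200 -> drops 150, 199, 200
  # mask [340,360) covers 1-based 341..360 -> drops 350
  expect_equal(out$pos, c(10, 50, 100, 250, 300, 400))

  # flank expansion pulls in neighbouring sites
  out_flank <- apply_masks(sites, m, flank = 20)
  expect_equal(out_flank$pos, c(10, 50, 250, 300, 400))

  expect_error(apply_masks(data.frame(chrom = "chr1", pos = c(5, 2)), m1),
               "sorted")
})

test_that("the high-confidence filter keeps only informative, deep, balanced sites", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                      ref = c("A", "C", "G", "T"),
                      alt = c("G", "T", "A", "C"),
                      stringsAsFactors = FALSE)
  p1 <- list(rc(c(10, 0, 9, 10), c(0, 11, 0, 0)),
             rc(c(8, 0, 10, 9), c(0, 9, 0, 0)))
  p2 <- list(rc(c(0, 10, 0, 0), c(12, 0, 8, 10)),
             rc(c(0, 12, 0, 0), c(9, 0, 10, 9)))
  f1 <- list(rc(c(5, 6, 2, 7), c(5, 5, 6, 3)),    # site3 ratio .25, site4 .7
             rc(c(6, 7, 5, 5), c(6, 7, 5, 6)))
  res <- select_informative_markers(sites, p1, p2, f1)
  expect_equal(res$markers$pos, c(100, 200))
  # allele orientation follows the parental genotypes
  expect_equal(res$markers$allele_P1, c("A", "T"))
  expect_equal(res$markers$allele_P2, c("G", "C"))
  expect_equal(res$audit$reason,
               c("kept", "kept", "f1_ratio_out_of_bounds",
                 "f1_ratio_out_of_bounds"))

  # any replicate at depth exactly 3 kills the site ("larger than three")
  p1_shallow <- list(rc(c(10, 0, 9, 10), c(0, 11, 0, 0)),
                     rc(c(3, 0, 10, 9), c(0, 9, 0, 0)))
  res2 <- select_informative_markers(sites, p1_shallow, p2, f1)
  expect_false(100 %in% res2$markers$pos)
  expect_equal(res2$audit$reason[1], "low_depth_or_missing")

  # zero survivors warns and returns an empty marker map
  f1_hom <- list(rc(c(10, 12, 8, 10), c(0, 0, 0, 0)),
                 rc(c(11, 13, 9, 10), c(0, 0, 0, 0)))
  expect_warning(res3 <- select_informative_markers(sites, p1, p2, f1_hom),
                 "no candidate site")
  expect_equal(nrow(res3$markers), 0)

  # misaligned replicate vectors are an error
  expect_error(select_informative_markers(sites, list(rc(1:3, 1:3)), p2, f1),
               "not aligned")
})

test_that("tightening filter parameters never adds markers (monotonicity)", {
  set.seed(1234)
  n <- 400
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  noisy <- function() {
    d <- rpois(n, 8)
    r <- rbinom(n, d, runif(n))
    rc(r, d - r)
  }
  p1 <- list(noisy(), noisy())
  p2 <- list(noisy(), noisy())
  f1 <- list(noisy(), noisy())

  base <- suppressWarnings(select_informative_markers(
    sites, p1, p2, f1, marker_filter_params(min_depth = 4,
                                            ratio_low = 0.2,
                                            ratio_high = 0.8)))
  tighter_ratio <- suppressWarnings(select_informative_markers(
    sites, p1, p2, f1, marker_filter_params(min_depth = 4,
                                            ratio_low = 0.3,
                                            ratio_high = 0.7)))
  deeper <- suppressWarnings(select_informative_markers(
    sites, p1, p2, f1, marker_filter_params(min_depth = 8,
                                            ratio_low = 0.2,
                                            ratio_high = 0.8)))
  expect_true(all(tighter_ratio$markers$pos %in% base$markers$pos))
  expect_true(all(deeper$markers$pos %in% base$markers$pos))
  # order preservation
  expect_false(is.unsorted(base$markers$pos))
})

test_that("on simulated deep parental data the filter recovers true markers", {
  cm <- toy_cm(2e6)
  mk <- make_marker_map(cm, 300, seed = 61)
  n <- nrow(mk)
  hom_genome <- function(origin) {
    structure(list(ploidy = 2L, mode = "F1",
                   haplotypes = list(rep(origin, n), rep(origin, n)),
                   breakpoints = NULL), class = "progeny_genome")
  }
  f1 <- f1_genome(mk)
  sim_rc <- function(genome, seed) {
    r <- simulate_reads(genome, mk, mean_depth = 14.3, error_rate = 0,
                        seed = seed)
    rc(r$reads_P1, r$reads_P2)  # REF = P1 allele
  }
  p1 <- list(sim_rc(hom_genome(1L), 71), sim_rc(hom_genome(1L), 72))
  p2 <- list(sim_rc(hom_genome(2L), 73), sim_rc(hom_genome(2L), 74))
  f1r <- list(sim_rc(f1, 75), sim_rc(f1, 76))
  sites <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$allele_P1,
                      alt = mk$allele_P2, stringsAsFactors = FALSE)
  res <- select_informative_markers(sites, p1, p2, f1r)

  params <- marker_filter_params()
  depth_ok <- Reduce(`&`, lapply(c(p1, p2, f1r), function(r) {
    r$ref_count + r$alt_count >= params$min_depth
  }))
  ratio_ok <- Reduce(`&`, lapply(f1r, function(r) {
    rat <- r$ref_count / (r$ref_count + r$alt_count)
    !is.na(rat) & rat > 0.3 & rat < 0.7
  }))
  # every true parental-difference site passing depth and ratio is kept
  expect_setequal(res$markers$pos, mk$pos[depth_ok & ratio_ok])
  expect_equal(res$markers$allele_P1,
               mk$allele_P1[mk$pos %in% res$markers$pos])

  # and a site where the parents share an allele is never kept
  p1_shared <- p1
  p2_shared <- lapply(p2, function(r) rc(r$ref_count + r$alt_count,
                                         0 * r$alt_count))
  res_shared <- suppressWarnings(
    select_informative_markers(sites, p1_shared, p2_shared, f1r))
  expect_equal(nrow(res_shared$markers), 0)
})
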