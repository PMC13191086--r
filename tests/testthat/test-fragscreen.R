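test_that("fragments map back exactly, strand-aware, with multimap flags", {
  ref <- sim_reference(1000, seed = 1)
  fwd <- substring(ref, 101, 160)
  rc <- revcomp(substring(ref, 11, 50))
  absent <- strrep("ACGT", 10)
  m <- map_fragments(c(fwd, rc, absent), ref)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start[m$element == fwd], 100L)
  expect_equal(m$end[m$element == fwd], 160L)
  expect_equal(m$strand[m$element == fwd], "+")
  expect_equal(m$start[m$element == rc], 10L)
  expect_equal(m$end[m$element == rc], 50L)
  expect_equal(m$strand[m$element == rc], "-")
  expect_equal(attr(m, "unmapped"), absent)

  # a duplicated locus flags multimapping and reports the first occurrence
  dup <- paste0(substring(ref, 1, 500), substring(ref, 101, 160),
                substring(ref, 501, 1000))
  m2 <- map_fragments(fwd, c(ref2 = dup))
  expect_true(m2$multimapped)
  expect_equal(m2$start, 100L)
})

test_that("mapping then slicing the reference reproduces every fragment", {
  ref <- sim_reference(4000, seed = 2)
  frags <- sim_fragment_library(ref, 800, 30, 100, seed = 3)
  m <- map_fragments(frags$element, ref)
  expect_equal(length(attr(m, "unmapped")), 0L)
  sl <- substring(ref[[1]], m$start + 1L, m$end)
  sl[m$strand == "-"] <- revcomp(sl[m$strand == "-"])
  expect_equal(sl, m$element)
})

test_that("coverage track counts overlapping fragments per position", {
  ref <- c(r = paste0(strrep("A", 50), strrep("C", 50)))
  one <- tibble::tibble(element = "x", ref_id = "r", start = 0L, end = 30L,
                        strand = "+", multimapped = FALSE)
  cov <- coverage_track(one, ref)
  expect_equal(cov$value, rep(c(1, 0), c(30, 70)))
  two <- dplyr::bind_rows(one, one)
  expect_equal(coverage_track(two, ref)$value, rep(c(2, 0), c(30, 70)))

  expect_equal(covered_fraction(cov, 0), 0.3)
  uniform <- tibble::tibble(ref_id = "r", pos = 0:99, value = 20)
  expect_equal(covered_fraction(uniform, 10), 1)
  half <- tibble::tibble(ref_id = "r", pos = 0:99,
                         value = rep(c(20, 0), each = 50))
  expect_equal(covered_fraction(half, 10), 0.5)
  boundary <- tibble::tibble(ref_id = "r", pos = 0:99, value = 10)
  expect_equal(covered_fraction(boundary, 10), 0)  # strictly greater
})

test_that("NRS track averages covering fragments and masks uncovered positions", {
  ref <- c(r = strrep("ACGT", 25))
  mapped <- tibble::tibble(
    element = c("a", "b"), ref_id = "r", start = c(0L, 20L),
    end = c(40L, 60L), strand = "+", multimapped = FALSE)
  rec <- tibble::tibble(element = c("a", "b"), nrs = c(1, 0))
  tr <- nrs_track(mapped, rec, ref)
  expect_equal(tr$value[1:20], rep(1, 20))
  expect_equal(tr$value[21:40], rep(0.5, 20))  # overlap averages 1 and 0
  expect_equal(tr$value[41:60], rep(0, 20))
  expect_false(any(tr$covered[61:100]))
  expect_equal(tr$value[61:100], rep(0, 40))
})

test_that("enriched region calling finds threshold runs and planted regions", {
  cov <- tibble::tibble(ref_id = "r", pos = 0:99, value = 20)
  flat <- tibble::tibble(ref_id = "r", pos = 0:99, value = 1)
  er <- enriched_regions(flat, cov, nrs_cut = 0.5, min_cov = 10)
  expect_equal(nrow(er), 1L)
  expect_equal(c(er$start, er$end), c(0L, 100L))
  expect_equal(er$class, "nuclear")

  low <- tibble::tibble(ref_id = "r", pos = 0:99, value = 0.2)
  expect_equal(nrow(enriched_regions(low, cov)), 0L)

  # planted recovery at effect 2 on a synthetic reference
  ref <- sim_reference(6000, seed = 11)
  regions <- tibble::tibble(start = c(1500, 4000), end = c(1900, 4450))
  frags <- sim_fragment_library(ref, 12000, 30, 100,
                                nuclear_regions = regions, effect_log2 = 2,
                                seed = 12)
  ct <- sim_fraction_counts(frags, fraction_samples(3, depth = 2e6),
                            dispersion = 0.02, seed = 13)
  rec <- score_elements(ct)
  m <- map_fragments(rec$element, ref)
  ntr <- nrs_track(m, rec, ref)
  ctr <- coverage_track(m, ref)
  called <- dplyr::filter(enriched_regions(ntr, ctr, nrs_cut = 0.58,
                                           min_cov = 10),
                          class == "nuclear")
  for (k in seq_len(nrow(regions))) {
    best <- max(vapply(seq_len(nrow(called)), function(i) {
      jaccard(called$start[i], called$end[i], regions$start[k],
              regions$end[k])
    }, numeric(1)))
    expect_gte(best, 0.5)
  }
  # top-decile NRS positions co-locate with the planted intervals
  thr <- quantile(ntr$value, 0.9)
  top <- ntr$pos[ntr$value >= thr]
  inside <- (top >= regions$start[1] & top < regions$end[1]) |
    (top >= regions$start[2] & top < regions$end[2])
  expect_gte(mean(inside), 0.8)
  # fragments wholly inside recovered regions are themselves enriched
  rec_m <- dplyr::inner_join(m, rec, by = "element")
  for (i in seq_len(nrow(called))) {
    inner <- rec_m$start >= called$start[i] & rec_m$end <= called$end[i]
    if (any(inner)) expect_gte(mean(rec_m$nrs[inner]), 0.58)
  }
})

test_that("length distribution summarizes the fragment range", {
  lens <- rep(30:100, 2)
  elems <- strrep("A", lens)
  ld <- length_distribution(elems)
  expect_equal(attr(ld, "min"), 30L)
  expect_equal(attr(ld, "max"), 100L)
  expect_equal(sum(ld$n), length(elems))
  single <- length_distribution(strrep("C", rep(50, 5)))
  expect_equal(nrow(single), 1L)
  expect_equal(attr(single, "median"), 50)

  frags <- sim_fragment_library(sim_reference(5000, seed = 5), 3000,
                                30, 100, seed = 6)
  # dequantize the integer lengths so the KS null is exact
  withr::with_seed(4, {
    jittered <- frags$length + runif(nrow(frags), -0.5, 0.5)
  })
  ks <- stats::ks.test(jittered, "punif", 29.5, 100.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("tracks and regions round-trip through bedGraph and BED6", {
  ref <- sim_reference(300, seed = 7)
  withr::with_seed(8, {
    vals <- round(rnorm(300, 0, 1), 3)
  })
  tr <- tibble::tibble(ref_id = "ref", pos = 0:299, value = vals)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, ref)
  expect_equal(back$value, tr$value)

  regions <- tibble::tibble(ref_id = "ref", start = c(10L, 200L),
                            end = c(60L, 260L), class = c("nuclear", "cytoplasmic"),
                            mean_nrs = c(1.2, -0.8))
  fb <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, fb)
  gr <- rtracklayer::import(fb, format = "BED")
  expect_equal(GenomicRanges::start(gr) - 1L, regions$start)
  expect_equal(GenomicRanges::end(gr), regions$end)
  expect_equal(gr$name, regions$class)
  expect_equal(gr$score, c(1000, round(1000 * 0.8 / 1.2)))
})
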