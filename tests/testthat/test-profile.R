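test_that("sliding-window assignment matches the brute-force averaging oracle", {
  zero_tab <- nrs_table_with()
  p <- assign_nrs("ACGTACGTAC", zero_tab)  # L = 10
  expect_length(p$raw, 5L)
  expect_length(p$averaged, 10L)
  expect_true(all(p$raw == 0) && all(p$averaged == 0))

  expect_error(assign_nrs("ACGTA", zero_tab), "at least 6")
  expect_error(assign_nrs("ACGTACGTAC",
                          tibble::tibble(element = "ACGTAC", nrs = 1)[0, ]),
               "missing|named")

  # randomized tables over random sequences, checked against the oracle
  withr::with_seed(10, {
    for (rep in 1:25) {
      L <- sample(6:30, 1)
      s <- stringi::stri_rand_strings(1, L, "[ACGT]")
      tab <- nrs_table_with()
      tab$nrs <- rnorm(4096)
      p <- assign_nrs(s, tab)
      v <- setNames(tab$nrs, tab$element)
      raw_expected <- unname(v[substring(s, 1:(L - 5), 6:L)])
      expect_equal(p$raw, raw_expected)
      expect_equal(p$averaged, brute_window_average(raw_expected, L))
    }
  })
  # interior positions average exactly 6 windows, edges fewer
  tab <- nrs_table_with()
  tab$nrs <- seq_len(4096) / 4096
  s <- strrep("ACGT", 5)  # L = 20
  p <- assign_nrs(s, tab)
  expect_equal(p$averaged[1], p$raw[1])
  expect_equal(p$averaged[3], mean(p$raw[1:3]))
  expect_equal(p$averaged[10], mean(p$raw[5:10]))
})

test_that("windows containing non-ACGT score zero and are masked", {
  tab <- nrs_table_with(nuclear = "AAAAAA")
  p <- assign_nrs("AAAAAANAAAAAA", tab)
  expect_false(all(p$mask))
  expect_equal(p$raw[p$mask == FALSE], rep(0, sum(!p$mask)))
  expect_equal(p$raw[1], 1)
})

test_that("randomizing the NRS table permutes values reproducibly", {
  tab <- nrs_table_with()
  withr::with_seed(2, tab$nrs <- rnorm(4096))
  r1 <- randomize_nrs(tab, seed = 5)
  expect_equal(sort(r1$nrs), sort(tab$nrs))
  expect_identical(r1, randomize_nrs(tab, seed = 5))
  cors <- vapply(1:5, function(s) {
    cor(tab$nrs, randomize_nrs(tab, seed = s)$nrs)
  }, numeric(1))
  expect_true(all(abs(cors) < 0.06))
})

test_that("peak calling equals exhaustive run enumeration on short vectors", {
  tab <- nrs_table_with()
  base <- assign_nrs(strrep("ACGT", 8), tab)

  with_vector <- function(v) {
    p <- base
    p$averaged <- v
    p$raw <- v[seq_len(length(v) - 5L)]
    p
  }
  # trivial cases
  p <- with_vector(rep(0.6, 30))
  pk <- call_peaks(p, nrs_cut = 0.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(0L, 30L))
  expect_equal(pk$class, "nuclear")

  expect_equal(nrow(call_peaks(with_vector(rep(0.49, 30)), nrs_cut = 0.5)), 0L)
  expect_equal(nrow(call_peaks(with_vector(rep(0.5, 30)), nrs_cut = 0.5)), 1L)

  # two runs split by a 2-nt dip merge under max_gap = 3
  v <- c(rep(0.8, 10), rep(0.1, 2), rep(0.8, 10))
  pk <- call_peaks(with_vector(v), nrs_cut = 0.5, max_gap = 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(0L, 22L))

  # randomized vectors against the independent enumerator
  withr::with_seed(20, {
    for (rep in 1:60) {
      L <- sample(10:30, 1)
      v <- round(rnorm(L, 0, 0.6), 2)
      gap <- sample(0:4, 1)
      ml <- sample(1:6, 1)
      got <- call_peaks(with_vector(v), nrs_cut = 0.5, min_len = ml,
                        max_gap = gap)
      for (cl in c("nuclear", "cytoplasmic")) {
        mask <- if (cl == "nuclear") v >= 0.5 else v <= -0.5
        forbid <- if (cl == "nuclear") v <= -0.5 else v >= 0.5
        want <- brute_runs(mask, gap, ml, forbid)
        have <- dplyr::filter(got, class == cl)
        expect_equal(have$start, want$start)
        expect_equal(have$end, want$end)
      }
      # opposite-class peaks never overlap
      nucp <- dplyr::filter(got, class == "nuclear")
      cytp <- dplyr::filter(got, class == "cytoplasmic")
      for (i in seq_len(nrow(nucp))) for (j in seq_len(nrow(cytp))) {
        expect_equal(jaccard(nucp$start[i], nucp$end[i],
                             cytp$start[j], cytp$end[j]), 0)
      }
    }
  })
})

test_that("peak coordinates shift but do not change under sub-threshold flanks", {
  # both sequences keep the core away from the transcript ends (edge
  # positions average fewer windows, so only interior shifts are exact)
  tab <- nrs_table_with(nuclear = cg_family)
  core <- strrep("CG", 12)
  flank <- strrep("A", 20)  # AAAAAA is neutral under this table
  p1 <- call_peaks(assign_nrs(paste0(flank, core, flank), tab))
  p2 <- call_peaks(assign_nrs(paste0(flank, flank, core, flank), tab))
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p2$start - 20L, p1$start)
  expect_equal(p2$end - 20L, p1$end)
})

test_that("metagene profiles are flat for constant signal and centered on planted regions", {
  tab <- nrs_table_with()
  prof <- assign_nrs(strrep("ACGT", 10), tab)
  prof$averaged <- rep(0.7, 40)
  peaks <- tibble::tibble(transcript_id = "transcript", start = 10L,
                          end = 30L, mean_nrs = 0.7, class = "nuclear")
  mg <- metagene(list(transcript = prof), peaks, half_window = 8)
  expect_equal(mg$mean_nrs, rep(0.7, 17))

  expect_error(metagene(list(), peaks[0, ]), "no peaks")

  # planted clustered elements: center exceeds flanks
  tab2 <- nrs_table_with(nuclear = cg_family, cytoplasmic = at_family)
  tx <- sim_transcripts(20, 200, 300, cg_family, at_family,
                        copies_per_transcript = 5, placement = "clustered",
                        seed = 30)
  profs <- assign_nrs_all(tx, tab2)
  pks <- call_peaks_all(profs)
  expect_gt(nrow(pks), 0L)
  mg <- metagene(profs, pks, half_window = 40)
  nucmg <- dplyr::filter(mg, class == "nuclear")
  center <- nucmg$mean_nrs[nucmg$offset == 0]
  flanks <- mean(nucmg$mean_nrs[abs(nucmg$offset) == 40], na.rm = TRUE)
  expect_gte(center - flanks, 0.2)
})

test_that("a permuted table destroys the peak/label association", {
  tab <- nrs_table_with(nuclear = cg_family, cytoplasmic = at_family)
  tx <- sim_transcripts(15, 200, 300, cg_family, at_family,
                        copies_per_transcript = 5, placement = "clustered",
                        seed = 31)
  profs <- assign_nrs_all(tx, tab)
  n_true <- nrow(call_peaks_all(profs))
  profs_perm <- assign_nrs_all(tx, randomize_nrs(tab, seed = 8))
  n_perm <- nrow(call_peaks_all(profs_perm))
  expect_gte(n_true, nrow(tx))       # every planted block is found
  expect_lt(n_perm, 0.1 * n_true)    # background only
})

test_that("peak origin summary tallies classes by biotype", {
  peaks <- tibble::tibble(
    transcript_id = c("t1", "t1", "t2", "t3"),
    start = c(0L, 50L, 0L, 0L), end = c(10L, 60L, 10L, 10L),
    mean_nrs = c(1, 1, -1, 1),
    class = c("nuclear", "nuclear", "cytoplasmic", "nuclear"))
  biotypes <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                             biotype = c("ncRNA", "PCG", "PCG"))
  out <- peak_origin_summary(peaks, biotypes)
  expect_equal(out$n[out$class == "nuclear" & out$biotype == "ncRNA"], 2L)
  expect_equal(out$pct[out$class == "cytoplasmic" & out$biotype == "PCG"], 100)
  expect_equal(sum(out$n), 4L)
  empty <- peak_origin_summary(peaks[0, ], biotypes)
  expect_equal(nrow(empty), 0L)
})

test_that("profiles and peaks serialize to bedGraph, BED and FASTA", {
  tab <- nrs_table_with(nuclear = cg_family)
  tx <- tibble::tibble(transcript_id = "tx1",
                       sequence = paste0(strrep("A", 30), strrep("CG", 10),
                                         strrep("A", 30)))
  prof <- assign_nrs(tx$sequence, tab, "tx1")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_profile_bedgraph(prof, f)
  back <- read_bedgraph(f, setNames(tx$sequence, "tx1"))
  expect_equal(back$value, prof$averaged)

  peaks <- call_peaks(prof)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(peaks, fb)
  gr <- rtracklayer::import(fb, format = "BED")
  expect_equal(GenomicRanges::start(gr) - 1L, peaks$start)

  ff <- withr::local_tempfile(fileext = ".fasta")
  write_peak_fasta(peaks, tx, ff)
  seqs <- Biostrings::readDNAStringSet(ff)
  expect_equal(unname(as.character(seqs[1])),
               substr(tx$sequence, peaks$start[1] + 1L, peaks$end[1]))
})
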