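test_that("half-up rounding behaves commercially, not to even", {
  expect_equal(round_half_up(0.975, 2), 0.98)
  expect_equal(round_half_up(0.985, 2), 0.99)
  expect_equal(round_half_up(12.003, 1), 12.0)
  expect_equal(round_half_up(-0.975, 2), -0.98)
  # tolerant of binary representation error in sums
  expect_equal(round_half_up(sum(rep(0.0975, 10)), 2), 0.98)
})

test_that("map statistics match hand computation", {
  map <- data.frame(marker_id = c("a", "b", "c"), lg = 1,
                    position_cM = c(0, 5, 15))
  st <- map_stats(map)
  expect_equal(st$raw$total_cM, 15)
  expect_equal(st$raw$largest_gap_cM, 10)
  expect_equal(st$raw$avg_cM, 7.5)
  expect_equal(st$raw$pct_gap_le, 50)

  map2 <- data.frame(marker_id = c("a", "b"), lg = 1, position_cM = c(0, 3))
  st2 <- map_stats(map2)
  expect_equal(st2$raw$total_cM, 3)
  expect_equal(st2$raw$pct_gap_le, 100)

  # single-marker group reported as zero-length
  map3 <- rbind(map, data.frame(marker_id = "z", lg = 2, position_cM = 0))
  st3 <- map_stats(map3)
  expect_equal(st3$raw$total_cM[st3$raw$lg == 2], 0)
  expect_true(is.na(st3$raw$avg_cM[st3$raw$lg == 2]))
})

test_that("per-group average distance follows the (n-1)-interval rule", {
  # 315 markers spanning 300.4 cM print as 0.96 cM between adjacent markers
  expect_equal(round_half_up(300.4 / (315 - 1), 2), 0.96)
  expect_equal(round_half_up(238.7 / (200 - 1), 2), 1.20)
})

test_that("summary ratios round half-up at one decimal", {
  expect_equal(summary_ratios(6353, 52928), 12.0)
  expect_equal(summary_ratios(915, 2792), 32.8)
  expect_equal(summary_ratios(0, 77), 0.0)
  expect_warning(out <- summary_ratios(3, 0), "zero denominator")
  expect_true(is.na(out))
})

test_that("SDRs are maximal runs of consecutive distorted markers", {
  map <- data.frame(marker_id = sprintf("m%d", 1:5), lg = 1,
                    position_cM = 0:4 * 10,
                    distorted = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  sdr <- detect_sdr(map, min_run = 3)
  expect_identical(nrow(sdr), 1L)
  expect_identical(sdr$start_marker, "m1")
  expect_identical(sdr$end_marker, "m3")
  expect_identical(sdr$n_markers, 3L)
  # no distorted markers: empty set
  map$distorted <- FALSE
  expect_identical(nrow(detect_sdr(map)), 0L)
  # orientation reversal leaves the SDR set invariant
  map$distorted <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  rev_map <- map
  rev_map$position_cM <- max(map$position_cM) - map$position_cM
  sdr_rev <- detect_sdr(rev_map, min_run = 3)
  expect_identical(nrow(sdr_rev), 1L)
  expect_identical(sort(c(sdr_rev$start_marker, sdr_rev$end_marker)),
                   sort(c(sdr$start_marker, sdr$end_marker)))
  expect_identical(sdr_rev$n_markers, sdr$n_markers)
})

test_that("overall summary aggregates per-group rows as unweighted means", {
  per_lg <- data.frame(
    n_markers = c(200, 292, 250, 315, 218, 216, 217, 189, 123, 226),
    total_cM = c(238.7, 287.9, 286.7, 300.4, 183.7, 175.0, 266.3, 134.6,
                 152.2, 132.8),
    avg_cM = c(1.20, 0.99, 1.15, 0.96, 0.85, 0.81, 1.23, 0.72, 1.25, 0.59),
    largest_gap_cM = c(14.1, 8.5, 7.4, 13.7, 9.4, 10.7, 15.7, 8.6, 4.3, 9.7),
    pct_gap_le = c(97.5, 99.0, 98.4, 98.1, 97.2, 98.1, 96.3, 98.9, 100.0,
                   97.8))
  ov <- overall_map_summary(per_lg)
  expect_equal(ov$n_markers, 2246)
  expect_equal(ov$mean_markers, 224.6)
  expect_equal(ov$mean_avg_cM, 0.98)
  expect_equal(ov$mean_largest_gap_cM, 10.2)
  expect_equal(ov$mean_pct_gap_le, 98.1)
})

test_that("map outputs are deterministic tab-delimited files", {
  set.seed(173)
  pos1 <- seq(0, 60, length.out = 14)
  pos2 <- seq(0, 50, length.out = 12)
  g <- rbind(oracle_chrom_genotypes(pos1, 80), oracle_chrom_genotypes(pos2, 80))
  rownames(g) <- sprintf("m%02d", seq_len(nrow(g)))
  fit <- fit_linkage_map(g, rounds = 1, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_map_outputs(fit, d1, snp_type_counts = c(R = 10, Y = 12))
  p2 <- write_map_outputs(fit, d2, snp_type_counts = c(R = 10, Y = 12))
  expect_true(all(file.exists(p1)))
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  mp <- read.delim(p1[1])
  expect_identical(names(mp),
                   c("marker_id", "lg", "position_cM", "accessory",
                     "distorted"))
})
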