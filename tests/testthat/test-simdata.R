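test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(seq_error_rate = 1.2), "must be in")
  expect_error(sim_config(chrom_lengths_cM = c(-5, 100), n_chromosomes = 2,
                          distortion_loci = list()), "non-negative")
  expect_error(sim_config(distortion_loci = list(
    list(chrom = 1, pos_cM = 10, s = 1.5, allele = "a"))), "s must be in")
  expect_error(sim_config(distortion_loci = list(
    list(chrom = 99, pos_cM = 10, s = 0.5, allele = "a"))), "nonexistent")
})

test_that("a zero-length chromosome gives complete co-segregation", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 0,
                    markers_per_chrom = 2, n_individuals = 50,
                    distortion_loci = list(), polymorphic_fraction = 1,
                    seed = 3)
  tr <- simulate_meioses(cfg)
  expect_identical(tr$genotypes[1, ], tr$genotypes[2, ])
})

test_that("realized recombination at 20 cM matches the Haldane inverse", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 20,
                    markers_per_chrom = 2, marker_placement = "even",
                    n_individuals = 10000, distortion_loci = list(),
                    polymorphic_fraction = 1, seed = 5)
  tr <- simulate_meioses(cfg)
  r_hat <- estimate_r_em(pair_table(tr$genotypes[1, ], tr$genotypes[2, ]))$r_hat
  r_true <- (1 - exp(-0.4)) / 2                 # 0.16484
  se <- sqrt(r_true * (1 - r_true) / (2 * 10000))
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("complete gametic selection eliminates the disfavoured homozygote", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 50,
                    markers_per_chrom = 3, marker_placement = "even",
                    n_individuals = 200, polymorphic_fraction = 1,
                    distortion_loci = list(
                      list(chrom = 1, pos_cM = 25, s = 1, allele = "a")),
                    seed = 8)
  tr <- simulate_meioses(cfg)
  # middle marker sits exactly at the selected locus (even placement)
  expect_false(any(tr$genotypes[2, ] == 2L))    # no bb survives s = 1
  expect_false(any(tr$genotypes[2, ] == 1L))    # no gamete carries b at all
})

test_that("zygotic selection also skews the locus", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 50,
                    markers_per_chrom = 3, marker_placement = "even",
                    n_individuals = 300, polymorphic_fraction = 1,
                    distortion_mechanism = "zygotic",
                    distortion_loci = list(
                      list(chrom = 1, pos_cM = 25, s = 1, allele = "a")),
                    seed = 8)
  tr <- simulate_meioses(cfg)
  expect_true(all(tr$genotypes[2, ] == 0L))     # only aa zygotes viable
})

test_that("fixed seed reproduces the dataset exactly", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = c(60, 80),
                    markers_per_chrom = 5, n_individuals = 20,
                    distortion_loci = list(
                      list(chrom = 2, pos_cM = 10, s = 0.5, allele = "b")),
                    seed = 11)
  s1 <- simulate_slaf_population(cfg)
  s2 <- simulate_slaf_population(cfg)
  expect_identical(s1$counts_a, s2$counts_a)
  expect_identical(s1$counts_b, s2$counts_b)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)
  expect_identical(s1$loci, s2$loci)
})

test_that("read simulation honours depth and error parameters", {
  base <- list(n_chromosomes = 1, chrom_lengths_cM = 40,
               markers_per_chrom = 10, n_individuals = 60,
               distortion_loci = list(), polymorphic_fraction = 1,
               missing_extra_rate = 0, seed = 13)
  cfg0 <- do.call(sim_config, c(base, list(offspring_depth_mean = 0)))
  s0 <- simulate_slaf_population(cfg0)
  expect_true(all(s0$counts_a + s0$counts_b == 0))

  cfg <- do.call(sim_config, c(base, list(offspring_depth_mean = 6,
                                          seq_error_rate = 0)))
  s <- simulate_slaf_population(cfg)
  g <- s$truth$genotypes
  # error 0: aa individuals have zero B reads
  expect_true(all(s$counts_b[g == 0L] == 0))
  # heterozygotes draw each allele with probability 1/2
  depth_het <- (s$counts_a + s$counts_b)[g == 1L]
  frac_b <- sum(s$counts_b[g == 1L]) / sum(depth_het)
  se <- 0.5 / sqrt(sum(depth_het))
  expect_lt(abs(frac_b - 0.5), 3 * se)
})

test_that("realized recombination is monotone in map separation", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 120,
                    markers_per_chrom = 7, marker_placement = "even",
                    n_individuals = 4000, distortion_loci = list(),
                    polymorphic_fraction = 1, seed = 17)
  tr <- simulate_meioses(cfg)
  r_to_first <- vapply(2:7, function(k)
    estimate_r_em(pair_table(tr$genotypes[1, ], tr$genotypes[k, ]))$r_hat,
    numeric(1))
  # allow tiny sampling wiggle but require the overall increasing trend
  expect_true(all(diff(r_to_first) > -0.02))
  expect_lt(r_to_first[1], r_to_first[6])
})

test_that("simulator files round-trip as tab-delimited text", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 30,
                    markers_per_chrom = 4, n_individuals = 10,
                    distortion_loci = list(), seed = 19)
  sim <- simulate_slaf_population(cfg)
  d <- withr::local_tempdir()
  paths <- write_sim_files(sim, d)
  expect_true(all(file.exists(paths)))
  long <- read.delim(paths[1])
  expect_identical(nrow(long), 4L * 10L)
  expect_identical(sum(long$countA), sum(sim$counts_a))
})
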