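test_that("tag clustering groups by >95% identity with single linkage", {
  t100 <- function(...) {
    s <- strrep("ACGT", 25)
    chars <- strsplit(s, "")[[1]]
    for (sub in list(...)) chars[sub[[1]]] <- sub[[2]]
    paste(chars, collapse = "")
  }
  # identical tags share a locus
  expect_identical(cluster_tags(c(t100(), t100())), c(1L, 1L))
  # 6 differences in 100 bp = 94% identity: below the threshold
  six_off <- t100(list(1:6, c("T", "T", "T", "A", "A", "G")))
  expect_identical(cluster_tags(c(t100(), six_off)), c(1L, 2L))
  # single-linkage closure: A~B 96%, B~C 96%, A~C 92%
  A <- t100()
  B <- t100(list(1:4, c("T", "T", "T", "A")))
  C <- t100(list(5:8, c("T", "T", "A", "G")))
  expect_identical(cluster_tags(c(A, B, C)), c(1L, 1L, 1L))
  # input order cannot change the partition (up to labels)
  lab1 <- cluster_tags(c(A, B, C, six_off))
  lab2 <- cluster_tags(c(six_off, C, B, A))[c(4, 3, 2, 1)]
  expect_identical(outer(lab1, lab1, "=="), outer(lab2, lab2, "=="))
  expect_error(cluster_tags(c("ACGT", "ACGTA")), "equal length")
  expect_error(cluster_tags(c("ACGN", "ACGT")), "alphabet")
})

test_that("alleles are the two most frequent tags with MAF reported", {
  d <- define_alleles(c(T1 = 90, T2 = 60))
  expect_identical(d$alleles, c("T1", "T2"))
  expect_equal(d$maf, 0.4)
  expect_true(define_alleles(c(T1 = 100))$monomorphic)
  # top-2 rule with a minor third tag; ties break lexicographically
  d3 <- define_alleles(c(T1 = 50, T2 = 50, T3 = 2))
  expect_identical(sort(d3$alleles), c("T1", "T2"))
  expect_identical(d3$alleles[1], "T1")
})

test_that("locus status filters apply in the documented order", {
  expect_identical(classify_locus(5, 1, 30, TRUE), "repetitive")
  expect_identical(classify_locus(2, 4, 30, TRUE), "filtered_snp_excess")
  expect_identical(classify_locus(2, 1, 2.0, TRUE), "low_depth")
  expect_identical(classify_locus(2, 1, 2.21, TRUE), "polymorphic")
  expect_identical(classify_locus(2, 0, 30, FALSE), "non_polymorphic")
  expect_identical(classify_locus(1, NA, 30, FALSE), "non_polymorphic")
})

test_that("segregation pattern classification is total over parent combos", {
  cases <- list(
    list(c("A", "A"), c("B", "B"), "aa x bb"),
    list(c("A", "B"), c("C", "C"), "ab x cc"),
    list(c("C", "C"), c("A", "B"), "cc x ab"),
    list(c("A", "B"), c("C", "D"), "ab x cd"),
    list(c("A", "B"), c("A", "B"), "hk x hk"),
    list(c("A", "B"), c("A", "C"), "ef x eg"),
    list(c("A", "B"), c("A", "A"), "lm x ll"),
    list(c("A", "A"), c("A", "B"), "nn x np"),
    list(c("A", "A"), c("A", "A"), "undetermined"))
  for (cs in cases)
    expect_identical(classify_segregation_pattern(cs[[1]], cs[[2]]), cs[[3]])
  expect_identical(classify_segregation_pattern(c(NA, NA), c("A", "A")),
                   "undetermined")
})

test_that("variant classification types substitutions by IUPAC code", {
  v <- classify_variant("ACGTT", "ACATT")
  expect_identical(v$variant_class, "SNP_only")
  expect_identical(v$snp_types, "R")
  # all six unordered base pairs
  pairs <- list(c("G", "A", "R"), c("T", "C", "Y"), c("G", "C", "S"),
                c("A", "T", "W"), c("G", "T", "K"), c("A", "C", "M"))
  for (p in pairs) {
    v <- classify_variant(paste0("AAAA", p[1], "CCCC"),
                          paste0("AAAA", p[2], "CCCC"))
    expect_identical(v$snp_types, p[3])
  }
  # a pure 2-base deletion
  v <- classify_variant("AAAACCGGGG", "AAAAGGGG")
  expect_identical(v$variant_class, "InDel_only")
  expect_identical(v$n_snps, 0L)
  # substitution T/C plus a deletion
  v <- classify_variant("ATAACCGGGG", "ACAAGGGG")
  expect_identical(v$variant_class, "SNP_InDel")
  expect_identical(v$snp_types, "Y")
  expect_error(classify_variant("ACGN", "ACGT"), "alphabet")
})

test_that("SNP-type counts partition all substitutions and recover the
           configured transition fraction", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 100,
                    markers_per_chrom = 600, n_individuals = 4,
                    polymorphic_fraction = 1, transition_fraction = 0.655,
                    distortion_loci = list(), seed = 23)
  sim <- simulate_slaf_population(cfg)
  mk <- identify_markers(sim)
  types <- unlist(strsplit(mk$snp_types[mk$snp_types != ""], ","))
  expect_identical(length(types), sum(mk$n_snps))
  expect_true(all(types %in% c("R", "Y", "S", "W", "K", "M")))
  ts_frac <- mean(types %in% c("R", "Y"))
  se <- sqrt(0.655 * 0.345 / length(types))
  expect_lt(abs(ts_frac - 0.655), 4 * se)
})

test_that("marker identification flags only aa x bb polymorphic loci", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 50,
                    markers_per_chrom = 80, n_individuals = 30,
                    polymorphic_fraction = 0.5, offspring_depth_mean = 8,
                    distortion_loci = list(), seed = 29)
  sim <- simulate_slaf_population(cfg)
  mk <- identify_markers(sim)
  expect_identical(nrow(mk), 80L)
  expect_true(all(mk$map_eligible == (mk$status == "polymorphic" &
                                        mk$pattern == "aa x bb")))
  expect_true(all(mk$pattern[!sim$loci$polymorphic] == "undetermined"))
})
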