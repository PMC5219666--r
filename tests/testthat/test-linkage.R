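test_that("EM handles the degenerate and independent limits", {
  co <- diag(c(30, 60, 30))                        # perfect cosegregation
  fit <- estimate_r_em(co)
  expect_lt(fit$r_hat, 1e-6)
  expect_gt(fit$lod, 10)

  ind <- outer(c(25, 50, 25), c(25, 50, 25)) / 100 # exact independence
  expect_equal(estimate_r_em(ind)$r_hat, 0.5, tolerance = 1e-6)
  expect_equal(estimate_r_em(ind)$lod, 0, tolerance = 1e-8)

  empty <- matrix(0, 3, 3)
  expect_false(estimate_r_em(empty)$defined)
})

test_that("tables built from exact class probabilities return the
           generating r", {
  for (r in c(0.05, 0.2, 0.35)) {
    tab <- oracle_class_probs(r) * 10000
    expect_equal(estimate_r_em(tab)$r_hat, r, tolerance = 1e-6)
  }
  # sampled at n = 10,000 the estimate sits within 0.001 of r = 0.2
  set.seed(73)
  tab <- random_f2_table(10000, 0.2)
  fit <- estimate_r_em(tab)
  se <- sqrt(0.2 * 0.8 / (2 * 10000))
  expect_lt(abs(fit$r_hat - 0.2), 4 * se)
  expect_lt(abs(fit$r_hat - grid_r_oracle(tab)), 1e-4)
})

test_that("EM agrees with the grid-search oracle on random tables", {
  set.seed(79)
  for (i in 1:60) {
    tab <- random_f2_table(130, runif(1, 0.02, 0.48))
    expect_lt(abs(estimate_r_em(tab)$r_hat - grid_r_oracle(tab)), 1e-4)
  }
})

test_that("r is invariant to marker-label and allele-label swaps", {
  set.seed(83)
  for (i in 1:20) {
    tab <- random_f2_table(130, runif(1, 0.05, 0.45))
    base <- estimate_r_em(tab)$r_hat
    expect_equal(estimate_r_em(t(tab))$r_hat, base, tolerance = 1e-6)
    expect_equal(estimate_r_em(tab[, 3:1])$r_hat, base, tolerance = 1e-6)
    expect_equal(estimate_r_em(tab[3:1, ])$r_hat, base, tolerance = 1e-6)
  }
})

test_that("LOD is a likelihood ratio against free recombination", {
  expect_equal(lod_score(random_f2_table(100, 0.2), 0.5), 0)
  # fully linked, n = 130 at exact 1:2:1: brute-force evaluation
  tab <- diag(c(32.5, 65, 32.5))
  ll <- function(r) {
    pr <- oracle_class_probs(r)
    sum(tab[tab > 0] * log(pr[tab > 0]))
  }
  expect_equal(lod_score(tab, 1e-7), (ll(1e-7) - ll(0.5)) / log(10),
               tolerance = 1e-10)
  # at the MLE the LOD cannot be negative
  set.seed(89)
  for (i in 1:20) {
    tab <- random_f2_table(130, runif(1, 0.05, 0.5))
    expect_gte(estimate_r_em(tab)$lod, 0)
  }
})

test_that("independence LOD separates linkage from shared distortion", {
  set.seed(97)
  # two unlinked markers, both skewed toward opposite homozygotes
  g1 <- sample(0:2, 130, TRUE, prob = c(.69, .28, .03))
  g2 <- sample(0:2, 130, TRUE, prob = c(.03, .28, .69))
  tab <- pair_table(g1, g2)
  expect_lt(independence_lod(tab), 3)
  # a genuinely linked pair scores high on both statistics
  tab2 <- random_f2_table(130, 0.1)
  expect_gt(independence_lod(tab2), 5)
  expect_gt(estimate_r_em(tab2)$lod, 5)
})

test_that("grouping is a single-linkage closure with unlinked drop-out", {
  lod <- matrix(0, 10, 10)
  lod[1:5, 1:5] <- 8; lod[6:10, 6:10] <- 8
  diag(lod) <- 0
  gr <- group_markers(lod, 5)
  expect_length(gr$groups, 2)
  expect_identical(sort(unlist(gr$groups)), 1:10)
  # threshold above the global maximum: everything unlinked
  gr2 <- group_markers(lod, 100)
  expect_length(gr2$groups, 0)
  expect_identical(gr2$unlinked, 1:10)
  expect_length(group_markers(matrix(0, 0, 0), 5)$groups, 0)
  # closure through a chain: 5-6 link added
  lod[5, 6] <- lod[6, 5] <- 6
  expect_length(group_markers(lod, 5)$groups, 1)
})

test_that("ten simulated chromosomes recover exactly ten groups", {
  set.seed(101)
  gl <- list()
  for (ch in 1:10) {
    pos <- seq(0, 140, length.out = 20)
    g <- oracle_chrom_genotypes(pos, 130)
    rownames(g) <- sprintf("c%02d_%02d", ch, 1:20)
    gl[[ch]] <- g
  }
  g <- do.call(rbind, gl)
  pl <- pairwise_linkage(g)
  gr <- group_markers(pl$mlod, 5)
  expect_length(gr$groups, 10)
  expect_length(gr$unlinked, 0)
  chrom_of <- rep(1:10, each = 20)
  for (grp in gr$groups)
    expect_length(unique(chrom_of[grp]), 1)
})
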