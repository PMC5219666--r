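test_that("Kosambi function, inverse and domain checks", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))
  expect_equal(round(kosambi(0.25), 3), 27.465)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_equal(kosambi_inverse(kosambi(r)), r, tolerance = 1e-12)
  expect_error(kosambi(0.5), "requires r")
  expect_error(kosambi(-0.01), "requires r")
  expect_error(kosambi_inverse(-1), "non-negative")
})

test_that("SARF sums adjacent r and is reversal-invariant", {
  r <- matrix(0, 3, 3)
  r[1, 2] <- r[2, 1] <- 0.1
  r[2, 3] <- r[3, 2] <- 0.2
  r[1, 3] <- r[3, 1] <- 0.28
  expect_equal(sarf(1L, r), 0)
  expect_equal(sarf(c(1, 2, 3), r), 0.3)
  expect_equal(sarf(c(3, 2, 1), r), 0.3)
  rn <- r; rn[1, 2] <- rn[2, 1] <- NA
  expect_error(sarf(c(1, 2, 3), rn), "incomplete")
})

test_that("move deltas agree with full SARF recomputation", {
  set.seed(103)
  n <- 12
  pos <- sort(runif(n, 0, 100))
  r_mat <- outer(pos, pos, function(a, b) (1 - exp(-2 * abs(a - b) / 100)) / 2)
  for (rep in 1:50) {
    ord <- sample(n)
    ij <- sort(sample(n, 2))
    d <- slafmap:::delta_reverse(ord, r_mat, ij[1], ij[2])
    ord2 <- ord; ord2[ij[1]:ij[2]] <- rev(ord2[ij[1]:ij[2]])
    expect_equal(d, sarf(ord2, r_mat) - sarf(ord, r_mat), tolerance = 1e-12)
    p <- sample(n, 1); t <- sample(n, 1)
    rest <- ord[-p]
    d2 <- -slafmap:::delta_insert_slot(rest, r_mat, ord[p], p) +
      slafmap:::delta_insert_slot(rest, r_mat, ord[p], t)
    ord3 <- append(rest, ord[p], after = t - 1L)
    expect_equal(d2, sarf(ord3, r_mat) - sarf(ord, r_mat), tolerance = 1e-12)
  }
})

test_that("annealing attains the exhaustive SARF optimum on 8 markers", {
  set.seed(107)
  for (rep in 1:6) {
    pos <- sort(runif(8, 0, 80))
    g <- oracle_chrom_genotypes(pos, 130)
    pl <- pairwise_linkage(g)
    st <- order_sa(pl$r, pl$lod, seed = rep)
    expect_equal(st$sarf, exhaustive_sarf_min(pl$r), tolerance = 1e-9)
  }
})

test_that("an already-optimal order is a fixed point of the annealer", {
  pos <- seq(0, 70, by = 10)
  r_mat <- outer(pos, pos, function(a, b) (1 - exp(-2 * abs(a - b) / 100)) / 2)
  st <- order_sa(r_mat, seed = 1)
  expect_equal(st$sarf, sarf(seq_along(pos), r_mat), tolerance = 1e-12)
  # SARF of the returned order never exceeds the true order's SARF
  set.seed(109)
  for (rep in 1:5) {
    pos <- sort(runif(15, 0, 120))
    g <- oracle_chrom_genotypes(pos, 130)
    pl <- pairwise_linkage(g)
    st <- order_sa(pl$r, pl$lod, seed = rep)
    expect_lte(st$sarf, sarf(seq_along(pos), pl$r) + 1e-9)
  }
})

test_that("annealing with a fixed seed is bit-for-bit reproducible", {
  set.seed(113)
  pos <- sort(runif(20, 0, 150))
  g <- oracle_chrom_genotypes(pos, 130)
  pl <- pairwise_linkage(g)
  s1 <- order_sa(pl$r, pl$lod, seed = 99)
  s2 <- order_sa(pl$r, pl$lod, seed = 99)
  expect_identical(s1$order, s2$order)
  expect_identical(s1$sarf, s2$sarf)
})

test_that("20-marker order recovery reaches tau 0.95", {
  set.seed(127)
  taus <- replicate(5, {
    pos <- seq(0, 120, length.out = 20)
    g <- oracle_chrom_genotypes(pos, 130)
    pl <- pairwise_linkage(g)
    st <- order_sa(pl$r, pl$lod, seed = 5)
    kendall_abs(st$order, seq_len(20))
  })
  expect_true(all(taus >= 0.95))
})

test_that("order_sa rejects incomplete or disconnected groups", {
  r <- matrix(0.1, 4, 4); diag(r) <- 0
  r[1, 2] <- NA
  expect_error(order_sa(r), "incomplete")
  lod <- matrix(0, 4, 4)
  lod[1:2, 1:2] <- 10; lod[3:4, 3:4] <- 10
  r2 <- matrix(0.4, 4, 4); diag(r2) <- 0
  expect_error(order_sa(r2, lod, min_lod = 3), "disconnected")
})

test_that("multipoint estimates equal two-point values on complete data", {
  set.seed(131)
  pos <- seq(0, 60, by = 12)
  g <- oracle_chrom_genotypes(pos, 200)
  two_pt <- vapply(seq_len(nrow(g) - 1), function(k)
    estimate_r_em(pair_table(g[k, ], g[k + 1, ]))$r_hat, numeric(1))
  expect_equal(multipoint_adjacent_r(g), two_pt, tolerance = 1e-6)
})

test_that("multipoint beats complete-case two-point under missingness", {
  set.seed(137)
  pos <- seq(0, 90, by = 6)
  rmse_mp <- c(); rmse_tp <- c()
  for (rep in 1:5) {
    g <- oracle_chrom_genotypes(pos, 130)
    r_true <- (1 - exp(-2 * diff(pos) / 100)) / 2
    gm <- g; gm[matrix(runif(length(g)) < 0.3, nrow(g))] <- NA
    mp <- multipoint_adjacent_r(gm)
    tp <- vapply(seq_len(nrow(g) - 1), function(k)
      estimate_r_em(pair_table(gm[k, ], gm[k + 1, ]))$r_hat, numeric(1))
    rmse_mp <- c(rmse_mp, sqrt(mean((mp - r_true)^2)))
    rmse_tp <- c(rmse_tp, sqrt(mean((tp - r_true)^2)))
  }
  expect_lt(mean(rmse_mp), mean(rmse_tp))
})

test_that("posterior re-calling recovers undercalled heterozygotes", {
  set.seed(139)
  pos <- seq(0, 100, length.out = 26)
  g <- oracle_chrom_genotypes(pos, 130)
  reads <- oracle_reads(g, depth_mean = 3, eps = 0.01)
  gm <- call_genotypes(reads$a, reads$b)
  raw_conc <- mean(gm$genotypes == g, na.rm = TRUE)
  r_adj <- multipoint_adjacent_r(gm$genotypes, emission = gm$likelihood)
  rc <- hmm_recall_genotypes(gm$genotypes, r_adj, emission = gm$likelihood)
  expect_gt(mean(rc$genotypes == g), raw_conc + 0.05)
  expect_gt(mean(rc$genotypes == g), 0.93)
})

test_that("a planted singleton flip is removed, clean data untouched", {
  set.seed(149)
  pos <- seq(0, 25, by = 1)          # tight map: no true double recombinants
  g <- oracle_chrom_genotypes(pos, 80)
  clean <- smooth_correct(g, pos)
  expect_identical(clean$genotypes, g)
  expect_identical(nrow(clean$changes), 0L)
  # flip one genotype inside a non-recombinant block
  gi <- g
  stopifnot(g[10, 1] == g[9, 1], g[10, 1] == g[11, 1])
  gi[10, 1] <- (g[10, 1] + 1L) %% 3L
  fixed <- smooth_correct(gi, pos)
  expect_true(is.na(fixed$genotypes[10, 1]))
  expect_identical(nrow(fixed$changes), 1L)
  expect_error(smooth_correct(g, rev(pos)), "map order")
})

test_that("correction shortens maps inflated by planted errors", {
  set.seed(151)
  shrunk <- replicate(5, {
    pos <- seq(0, 100, length.out = 26)
    g <- oracle_chrom_genotypes(pos, 130)
    ge <- g
    err <- sample(length(g), round(0.01 * length(g)))
    ge[err] <- (ge[err] + sample(1:2, length(err), TRUE)) %% 3L
    len_of <- function(gg) {
      r <- multipoint_adjacent_r(gg)
      sum(kosambi(pmin(r, 0.49)))
    }
    before <- len_of(ge)
    sm <- smooth_correct(ge, pos, rise = sqrt(10), threshold_max = 0.05,
                         max_passes = 25)
    after <- len_of(knn_impute(sm$genotypes, pos))
    after < before
  })
  expect_true(all(shrunk))
})

test_that("kNN imputation follows the local majority", {
  g <- matrix(0L, 7, 3, dimnames = list(sprintf("m%d", 1:7), NULL))
  g[4, 1] <- NA                        # missing inside an aa block
  pos <- seq(0, 12, by = 2)
  out <- knn_impute(g, pos, k = 5)
  expect_identical(unname(out[4, 1]), 0L)
  g2 <- g; g2[, 2] <- NA               # fully missing individual
  out2 <- knn_impute(g2, pos)
  expect_true(all(is.na(out2[, 2])))
  expect_error(knn_impute(g, pos, k = 0), "at least 1")
})

test_that("kNN imputation is >90% accurate on a 4-cM map", {
  set.seed(157)
  pos <- seq(0, 100, by = 4)
  g <- oracle_chrom_genotypes(pos, 130)
  gm <- g
  drop <- sample(length(g), round(0.1 * length(g)))
  gm[drop] <- NA
  out <- knn_impute(gm, pos)
  expect_gt(mean(out[drop] == g[drop]), 0.9)
})

test_that("accessory insertion respects the framework contract", {
  set.seed(163)
  pos <- seq(0, 40, by = 10)
  g <- oracle_chrom_genotypes(pos, 130)
  fpos <- stats::setNames(pos, rownames(g))
  # a marker identical to a framework marker co-locates with it
  twin <- g[3, , drop = FALSE]
  rownames(twin) <- "twin"
  ext <- insert_skewed(fpos, g, twin)
  expect_equal(ext$position_cM[ext$marker_id == "twin"],
               ext$position_cM[ext$marker_id == rownames(g)[3]],
               tolerance = 1e-9)
  # framework order and spacing unchanged (up to a common shift)
  fw <- ext[!ext$accessory, ]
  expect_identical(fw$marker_id, rownames(g))
  expect_equal(diff(fw$position_cM), diff(pos), tolerance = 1e-9)
  # an unlinked marker stays unplaced
  noise <- matrix(sample(0:2, 130, TRUE, prob = c(.25, .5, .25)), 1,
                  dimnames = list("noise", NULL))
  ext2 <- insert_skewed(fpos, g, noise)
  expect_false(ext2$placed[ext2$marker_id == "noise"])
})

test_that("a midway accessory marker lands in the correct interval", {
  set.seed(167)
  hits <- replicate(200, {
    pos_all <- c(0, 10, 20, 25, 30, 40)    # accessory truly at 25 cM
    g <- oracle_chrom_genotypes(pos_all, 130)
    fw <- g[-4, , drop = FALSE]
    fpos <- stats::setNames(pos_all[-4], rownames(fw))
    acc <- g[4, , drop = FALSE]
    rownames(acc) <- "acc"
    ext <- insert_skewed(fpos, fw, acc, lod_threshold = 3)
    p <- ext$position_cM[ext$marker_id == "acc"]
    length(p) == 1 && !is.na(p) && p > 20 && p < 30
  })
  expect_gte(mean(hits), 0.95)
})
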