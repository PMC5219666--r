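# Shared oracles and fixtures, independent of the implementation paths they
# check.

# F2 two-locus class probabilities (coupling), written out independently of
# the package internals.
oracle_class_probs <- function(r) {
  p <- (1 - r) / 2; q <- r / 2
  matrix(c(p^2, 2 * p * q, q^2,
           2 * p * q, 2 * (p^2 + q^2), 2 * p * q,
           q^2, 2 * p * q, p^2), nrow = 3, byrow = TRUE)
}

# Grid-search maximum-likelihood oracle for the two-point recombination
# fraction (step 1e-4), evaluating the multinomial log-likelihood directly.
grid_r_oracle <- function(tab, step = 1e-4) {
  grid <- seq(1e-7, 0.5, by = step)
  counts <- as.vector(t(tab))
  # also evaluate the column-swapped (repulsion) coding, as the EM does
  counts_swap <- as.vector(t(tab[, 3:1]))
  ll_of <- function(cnt) {
    vapply(grid, function(r) {
      pr <- as.vector(t(oracle_class_probs(r)))
      sum(cnt[cnt > 0] * log(pr[cnt > 0]))
    }, numeric(1))
  }
  ll1 <- ll_of(counts); ll2 <- ll_of(counts_swap)
  if (max(ll2) > max(ll1)) grid[which.max(ll2)] else grid[which.max(ll1)]
}

# Random 3x3 genotype table from n F2 individuals at recombination r.
random_f2_table <- function(n, r) {
  p <- as.vector(oracle_class_probs(r))
  matrix(stats::rmultinom(1, n, p), 3, 3)
}

# All permutations of 1..n (n small), via recursion.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Exhaustive-search SARF minimum over all orders (up to reversal).
exhaustive_sarf_min <- function(r_mat) {
  n <- nrow(r_mat)
  perms <- all_perms(n)
  s <- rep(0, nrow(perms))
  for (k in seq_len(n - 1L))
    s <- s + r_mat[cbind(perms[, k], perms[, k + 1L])]
  min(s)
}

# Simulate true F2 genotypes for one chromosome with markers at pos_cM
# (Haldane model), independent of the package's simulator.
oracle_chrom_genotypes <- function(pos_cM, n_ind) {
  m <- length(pos_cM)
  g <- matrix(0L, m, n_ind)
  r_adj <- (1 - exp(-2 * diff(pos_cM) / 100)) / 2
  for (i in seq_len(n_ind)) {
    for (gam in 1:2) {
      a <- stats::rbinom(1, 1, 0.5)
      hap <- integer(m); hap[1] <- a
      for (k in seq_len(m - 1L))
        hap[k + 1L] <- if (stats::runif(1) < r_adj[k]) 1L - hap[k] else hap[k]
      g[, i] <- g[, i] + hap
    }
  }
  rownames(g) <- sprintf("m%02d", seq_len(m))
  g
}

# Read-count layer over a genotype matrix (Poisson depth, error eps).
oracle_reads <- function(g, depth_mean, eps = 0.01, mask_rate = 0) {
  m <- nrow(g); n <- ncol(g)
  depth <- matrix(stats::rpois(m * n, depth_mean), m, n)
  depth[matrix(stats::runif(m * n) < mask_rate, m, n)] <- 0L
  pb <- matrix(c(eps, 0.5, 1 - eps)[g + 1L], m, n)
  cb <- matrix(stats::rbinom(m * n, depth, pb), m, n)
  list(a = structure(depth - cb, dimnames = dimnames(g)),
       b = structure(cb, dimnames = dimnames(g)))
}

kendall_abs <- function(x, y) abs(stats::cor(x, y, method = "kendall"))
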