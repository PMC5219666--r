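# Two-point analysis for codominant F2 markers in coupling phase:
# EM estimation of the recombination fraction from the 3x3 joint genotype
# table, LOD scores, and single-linkage grouping at a LOD threshold.

# Class probabilities of the 3x3 F2 joint genotype table at recombination
# fraction r (rows/cols aa, ab, bb; coupling phase).  Gamete frequencies are
# (1-r)/2 for parental and r/2 for recombinant haplotypes; the double
# heterozygote is a mixture of parental- and recombinant-origin gamete pairs.
f2_class_probs <- function(r) {
  p <- (1 - r) / 2; q <- r / 2
  matrix(c(p^2,       2 * p * q,         q^2,
           2 * p * q, 2 * (p^2 + q^2),   2 * p * q,
           q^2,       2 * p * q,         p^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(GENO_CODES, GENO_CODES))
}

# Multinomial log-likelihood of a 3x3 table at r (constant terms dropped).
f2_loglik <- function(tab, r) {
  pr <- f2_class_probs(r)
  sum(tab[tab > 0] * log(pr[tab > 0]))
}

#' Two-point EM estimate of the recombination fraction
#'
#' Maximum-likelihood estimation of r from the joint 3x3 genotype table of
#' two codominant F2 markers (coupling-phase aa x bb parents; individuals
#' missing either genotype are excluded upstream).  Every table cell fixes
#' its count of recombinant gametes except the double heterozygote, which
#' mixes parental (probability proportional to \eqn{(1-r)^2/2}) and
#' recombinant (\eqn{r^2/2}) gamete pairs; EM resolves the mixture by its
#' expected recombinant count each iteration and updates r as expected
#' recombinant gametes over total gametes, to convergence
#' (`|delta r| < 1e-8`).  Both allele orientations of the second marker are
#' evaluated and the higher-likelihood phase is retained, so repulsion-coded
#' input is re-phased automatically.
#'
#' @param tab 3x3 numeric table of joint genotype counts (rows marker 1
#'   aa/ab/bb, columns marker 2); fractional counts are allowed.
#' @param tol convergence tolerance on r.
#' @param max_iter iteration cap.
#' @return a list of class `"two_point"`: `r_hat` (clamped to
#'   \[1e-7, 0.5\]), `lod`, `n_informative`, `phase` (`"coupling"` or
#'   `"repulsion"` relative to the input coding), `loglik`.
#'   `n_informative = 0` gives `r_hat = NA` flagged by `defined = FALSE`.
#' @examples
#' tab <- matrix(c(30, 3, 0, 4, 60, 3, 0, 4, 26), 3, 3, byrow = TRUE)
#' estimate_r_em(tab)
#' @export
estimate_r_em <- function(tab, tol = 1e-8, max_iter = 1000L) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3L, 3L)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0)
    return(structure(list(r_hat = NA_real_, lod = NA_real_,
                          n_informative = 0, phase = NA_character_,
                          loglik = NA_real_, defined = FALSE),
                     class = "two_point"))
  fit_one <- function(tt) {
    # recombinant gametes fixed by each cell (double het handled separately)
    rec <- matrix(c(0, 1, 2, 1, NA, 1, 2, 1, 0), 3, 3, byrow = TRUE)
    fixed <- sum(tt * ifelse(is.na(rec), 0, rec))
    n11 <- tt[2, 2]
    r <- 0.25
    for (it in seq_len(max_iter)) {
      w <- r^2 / ((1 - r)^2 + r^2)       # P(recombinant origin | double het)
      r_new <- (fixed + 2 * w * n11) / (2 * n)
      r_new <- min(max(r_new, 1e-7), 0.5)
      if (abs(r_new - r) < tol) { r <- r_new; break }
      r <- r_new
    }
    list(r = r, ll = f2_loglik(tt, r))
  }
  fit_c <- fit_one(tab)
  fit_r <- fit_one(tab[, 3:1])           # swap marker-2 alleles (repulsion)
  if (fit_r$ll > fit_c$ll) {
    fit <- fit_r; phase <- "repulsion"; use_tab <- tab[, 3:1]
  } else {
    fit <- fit_c; phase <- "coupling"; use_tab <- tab
  }
  lod <- (fit$ll - f2_loglik(use_tab, 0.5)) / log(10)
  structure(list(r_hat = fit$r, lod = max(lod, 0), n_informative = n,
                 phase = phase, loglik = fit$ll, defined = TRUE),
            class = "two_point")
}

#' LOD score of a two-point table at a given recombination fraction
#'
#' `log10 L(r) - log10 L(0.5)` under the multinomial F2 two-locus class
#' model.  At the MLE this is non-negative, and it is exactly 0 at r = 0.5.
#'
#' @param tab 3x3 joint genotype count table (coupling phase).
#' @param r_hat recombination fraction at which to evaluate.
#' @return the LOD score.
#' @export
lod_score <- function(tab, r_hat) {
  stopifnot(r_hat >= 0, r_hat <= 0.5)
  (f2_loglik(as.matrix(tab), r_hat) - f2_loglik(as.matrix(tab), 0.5)) / log(10)
}

#' Joint 3x3 genotype table for a marker pair
#'
#' @param g1,g2 integer genotype vectors (0/1/2/NA) over the same
#'   individuals; pairs with either missing are dropped.
#' @return 3x3 count matrix (rows `g1`, columns `g2`).
#' @export
pair_table <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- matrix(0, 3, 3, dimnames = list(GENO_CODES, GENO_CODES))
  if (any(ok)) {
    t0 <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
    tab[] <- as.numeric(t0)
  }
  tab
}

#' Independence LOD of a joint genotype table
#'
#' G-test of independence expressed on the log10 scale:
#' `sum(O log(O/E)) / ln 10` with expected counts from the observed
#' margins.  Unlike the likelihood-ratio LOD at the MLE, this statistic is
#' immune to pseudo-linkage between unlinked markers that are both
#' segregation-distorted (their skewed margins mimic coupling after a
#' phase flip), because the margins are conditioned on rather than
#' compared with 1:2:1.
#'
#' @param tab 3x3 joint genotype count table.
#' @return the independence LOD (0 for an empty table).
#' @export
independence_lod <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / n
  ok <- tab > 0
  max(sum(tab[ok] * log(tab[ok] / E[ok])) / log(10), 0)
}

#' All pairwise recombination fractions and LOD scores
#'
#' Runs [estimate_r_em()] on every marker pair of a genotype matrix.  The
#' `mlod` matrix holds the modified LOD used for grouping: the minimum of
#' the two-point LOD at the MLE and the [independence_lod()], so that a
#' pair must show both a likelihood gain over free recombination and
#' genuine association given its margins.
#'
#' @param genotypes markers x individuals matrix (0/1/2/NA).
#' @return list with symmetric matrices `r`, `lod` and `mlod`.
#' @export
pairwise_linkage <- function(genotypes) {
  m <- nrow(genotypes)
  ids <- rownames(genotypes)
  r_mat <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  lod_mat <- matrix(0, m, m, dimnames = list(ids, ids))
  mlod_mat <- matrix(0, m, m, dimnames = list(ids, ids))
  diag(r_mat) <- 0
  if (m < 2L) return(list(r = r_mat, lod = lod_mat, mlod = mlod_mat))
  # indicator matrices make the 3x3 cross-tab a 3x3 cross-product
  ind <- lapply(0:2, function(k) {
    x <- genotypes == k; x[is.na(x)] <- FALSE; x * 1
  })
  I3 <- array(unlist(ind), dim = c(m, ncol(genotypes), 3))
  for (i in seq_len(m - 1L)) {
    Ai <- I3[i, , ]                     # individuals x 3
    for (j in (i + 1L):m) {
      tab <- crossprod(Ai, I3[j, , ])
      fit <- estimate_r_em(tab)
      lod <- if (fit$defined) fit$lod else 0
      r_mat[i, j] <- r_mat[j, i] <- fit$r_hat
      lod_mat[i, j] <- lod_mat[j, i] <- lod
      mlod_mat[i, j] <- mlod_mat[j, i] <- min(lod, independence_lod(tab))
    }
  }
  list(r = r_mat, lod = lod_mat, mlod = mlod_mat)
}

#' Partition markers into linkage groups by LOD threshold
#'
#' Single-linkage transitive closure: two markers share a group when they
#' are connected by a path of pairs whose (M)LOD is at least `mlod_threshold`.
#' The grouping LOD used here is the two-point LOD at the maximum-likelihood
#' recombination fraction.  Markers with no partner at or above the
#' threshold are dropped as unlinked.
#'
#' @param lod_mat symmetric LOD matrix.
#' @param mlod_threshold grouping threshold (default 5).
#' @return a list of class `"grouping_result"`: `groups` (list of integer
#'   index vectors, largest first, deterministic), `unlinked` (indices),
#'   `threshold`.
#' @export
group_markers <- function(lod_mat, mlod_threshold = 5) {
  m <- nrow(lod_mat)
  if (is.null(m) || m == 0L)
    return(structure(list(groups = list(), unlinked = integer(0),
                          threshold = mlod_threshold),
                     class = "grouping_result"))
  stopifnot(isTRUE(all.equal(lod_mat, t(lod_mat), tolerance = 1e-8)))
  adj <- lod_mat >= mlod_threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (v in seq_len(m)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v; comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  groups <- split(seq_len(m), comp)
  unlinked <- unlist(groups[sizes == 1L], use.names = FALSE)
  groups <- groups[sizes > 1L]
  groups <- groups[order(-vapply(groups, length, integer(1)),
                         vapply(groups, min, integer(1)))]
  names(groups) <- NULL
  structure(list(groups = groups,
                 unlinked = sort(unlinked %||% integer(0)),
                 threshold = mlod_threshold),
            class = "grouping_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
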