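# Bayesian genotype scoring from per-allele read counts, and the iterative
# quality pruning of markers/individuals until the mean genotype quality of
# the matrix reaches a cutoff.

#' Posterior genotype call from allele read counts
#'
#' Reads are treated as independent Bernoulli draws.  Under genotype aa an
#' A-read occurs with probability `1 - error_rate`; under ab with 1/2;
#' under bb with `error_rate`.  The posterior over \{aa, ab, bb\} combines
#' these binomial likelihoods with the prior (default F2 expectation
#' 1:2:1); the call is the maximum a posteriori genotype and the quality
#' score is `-10 log10(1 - posterior)`, capped at `cap`.
#'
#' @param count_a,count_b non-negative integer read counts for the two
#'   alleles (vectorised).
#' @param error_rate per-read error probability, in (0, 0.5).
#' @param priors prior probabilities for (aa, ab, bb); default c(1,2,1)/4.
#' @param cap quality-score cap (default 60).
#' @return data.frame with `genotype` (0/1/2/NA), `posterior`, `quality`
#'   and `depth`, one row per input pair.  Zero depth gives a missing call
#'   with quality 0.
#' @examples
#' genotype_posterior(5, 0, error_rate = 0.01)
#' @export
genotype_posterior <- function(count_a, count_b, error_rate = 0.01,
                               priors = c(0.25, 0.5, 0.25), cap = 60) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("'error_rate' must be in (0, 0.5)")
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be non-negative")
  stopifnot(length(priors) == 3, all(priors > 0))
  priors <- priors / sum(priors)
  nA <- as.numeric(count_a); nB <- as.numeric(count_b)
  # log-likelihoods per genotype (binomial kernel; the choose() term cancels)
  ll <- cbind(aa = nA * log1p(-error_rate) + nB * log(error_rate),
              ab = (nA + nB) * log(0.5),
              bb = nA * log(error_rate) + nB * log1p(-error_rate))
  lp <- sweep(ll, 2, log(priors), `+`)
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  call <- max.col(post, ties.method = "first") - 1L
  pmax_post <- post[cbind(seq_len(nrow(post)), call + 1L)]
  quality <- pmin(-10 * log10(pmax(1 - pmax_post, 10^(-cap / 10))), cap)
  depth <- nA + nB
  miss <- depth == 0
  call[miss] <- NA_integer_
  pmax_post[miss] <- NA_real_
  quality[miss] <- 0
  data.frame(genotype = call, posterior = pmax_post, quality = quality,
             depth = depth)
}

#' Call a full genotype matrix from allele-count matrices
#'
#' @param counts_a,counts_b markers x individuals integer matrices of
#'   allele read counts.
#' @inheritParams genotype_posterior
#' @return a list of class `"genotype_matrix"`: `genotypes` (markers x
#'   individuals, 0/1/2/NA), `quality` and `depth` matrices of the same
#'   shape, `integrity` (per-marker fraction of non-missing calls), and
#'   `likelihood` (markers x individuals x 3 array of per-genotype read
#'   likelihoods, scaled to max 1 per call; flat rows for depth 0).  The
#'   likelihoods let downstream multipoint steps weigh uncertain
#'   low-coverage calls instead of trusting the hard call.
#' @export
call_genotypes <- function(counts_a, counts_b, error_rate = 0.01,
                           priors = c(0.25, 0.5, 0.25)) {
  stopifnot(identical(dim(counts_a), dim(counts_b)))
  calls <- genotype_posterior(as.vector(counts_a), as.vector(counts_b),
                              error_rate, priors)
  shape <- function(x) matrix(x, nrow(counts_a), ncol(counts_a),
                              dimnames = dimnames(counts_a))
  g <- shape(calls$genotype)
  nA <- as.numeric(counts_a); nB <- as.numeric(counts_b)
  ll <- cbind(nA * log1p(-error_rate) + nB * log(error_rate),
              (nA + nB) * log(0.5),
              nA * log(error_rate) + nB * log1p(-error_rate))
  lik <- exp(ll - apply(ll, 1, max))
  dn <- dimnames(counts_a)
  likelihood <- array(lik, dim = c(nrow(counts_a), ncol(counts_a), 3),
                      dimnames = list(dn[[1]], dn[[2]], GENO_CODES))
  structure(list(genotypes = g, quality = shape(calls$quality),
                 depth = shape(calls$depth),
                 integrity = rowMeans(!is.na(g)),
                 likelihood = likelihood),
            class = "genotype_matrix")
}

#' Iteratively prune low-quality markers or individuals
#'
#' While the mean genotype quality score over all remaining calls is below
#' `gq_cutoff`, the marker or individual with the lowest mean quality
#' (whichever is lower; missing calls count as quality 0) is removed.  The
#' process stops once the mean reaches the cutoff; if the matrix would
#' empty first, an error names the last state.
#'
#' @param gm a `"genotype_matrix"` from [call_genotypes()].
#' @param gq_cutoff target mean genotype quality.
#' @return the pruned `"genotype_matrix"` with a `removals` data.frame
#'   (`what`, `id`, `mean_quality`) attached.
#' @export
iterative_quality_prune <- function(gm, gq_cutoff = 30) {
  stopifnot(inherits(gm, "genotype_matrix"))
  q <- gm$quality
  removals <- list()
  while (mean(q) < gq_cutoff) {
    if (nrow(q) <= 1L || ncol(q) <= 1L)
      stop(sprintf(paste0("quality cutoff %.1f unreachable: matrix reduced ",
                          "to %d marker(s) x %d individual(s) at mean ",
                          "quality %.2f"),
                   gq_cutoff, nrow(q), ncol(q), mean(q)))
    mq <- rowMeans(q); iq <- colMeans(q)
    if (min(mq) <= min(iq)) {
      k <- which.min(mq)
      removals[[length(removals) + 1L]] <-
        data.frame(what = "marker", id = rownames(q)[k], mean_quality = mq[k])
      q <- q[-k, , drop = FALSE]
    } else {
      k <- which.min(iq)
      removals[[length(removals) + 1L]] <-
        data.frame(what = "individual", id = colnames(q)[k],
                   mean_quality = iq[k])
      q <- q[, -k, drop = FALSE]
    }
  }
  keep_m <- rownames(q); keep_i <- colnames(q)
  out <- list(genotypes = gm$genotypes[keep_m, keep_i, drop = FALSE],
              quality = gm$quality[keep_m, keep_i, drop = FALSE],
              depth = gm$depth[keep_m, keep_i, drop = FALSE])
  out$integrity <- rowMeans(!is.na(out$genotypes))
  out$removals <- if (length(removals)) do.call(rbind, removals)
                  else data.frame(what = character(0), id = character(0),
                                  mean_quality = numeric(0))
  class(out) <- "genotype_matrix"
  out
}
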