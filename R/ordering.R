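# Within-group map construction: simulated-annealing marker ordering on the
# SARF criterion, multipoint re-estimation of adjacent recombination
# fractions, SMOOTH-style error removal, kNN imputation, Kosambi distances
# and multipoint insertion of distorted accessory markers.

#' Kosambi map function and its inverse
#'
#' `kosambi(r)` converts a recombination fraction to map distance,
#' `d = 25 ln((1+2r)/(1-2r))` centimorgans; `kosambi_inverse(d)` converts
#' back, `r = (e^(d/25) - 1) / (2 (e^(d/25) + 1))`.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @return map distance in cM.
#' @examples
#' kosambi(0.25)            # 25 * log(3) = 27.465...
#' kosambi_inverse(kosambi(0.1))
#' @export
kosambi <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("kosambi() requires r in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @param d map distance(s) in cM, non-negative.
#' @export
kosambi_inverse <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("kosambi_inverse() requires non-negative finite distances")
  x <- exp(d / 25)
  (x - 1) / (2 * (x + 1))
}

#' Sum of adjacent recombination fractions of a marker order
#'
#' The ordering criterion: `sum_i r(order_i, order_{i+1})`.  Reversing the
#' order leaves it unchanged.
#'
#' @param order integer (or name) permutation of the group's markers.
#' @param r_mat symmetric recombination-fraction matrix; must be complete
#'   (no `NA`) over the group.
#' @return the SARF value (0 for a single marker).
#' @export
sarf <- function(order, r_mat) {
  n <- length(order)
  if (n < 2L) return(0)
  vals <- r_mat[cbind(order[-n], order[-1L])]
  if (anyNA(vals))
    stop("pairwise r matrix is incomplete within the group")
  sum(vals)
}

# SARF change from reversing positions i..j of ord (symmetric r: only the
# two boundary edges change).
delta_reverse <- function(ord, r_mat, i, j) {
  n <- length(ord)
  d <- 0
  if (i > 1L) d <- d + r_mat[ord[i - 1L], ord[j]] - r_mat[ord[i - 1L], ord[i]]
  if (j < n)  d <- d + r_mat[ord[i], ord[j + 1L]] - r_mat[ord[j], ord[j + 1L]]
  d
}

# Insert marker m into ord (which must not contain m) at slot t
# (t = 1 .. length(ord)+1); returns the SARF change.
delta_insert_slot <- function(ord, r_mat, m, t) {
  n <- length(ord)
  left <- if (t > 1L) ord[t - 1L] else NA
  right <- if (t <= n) ord[t] else NA
  d <- 0
  if (!is.na(left)) d <- d + r_mat[left, m]
  if (!is.na(right)) d <- d + r_mat[m, right]
  if (!is.na(left) && !is.na(right)) d <- d - r_mat[left, right]
  d
}

# Greedy nearest-neighbour seriation start for the annealer.
greedy_order <- function(r_mat) {
  n <- nrow(r_mat)
  start <- which.max(rowSums(r_mat))       # likely terminal marker
  ord <- start
  left <- setdiff(seq_len(n), start)
  while (length(left)) {
    nxt <- left[which.min(r_mat[ord[length(ord)], left])]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
  }
  ord
}

# Deterministic local search: best-improvement over all segment reversals
# and single-marker reinsertions until neither move type improves SARF.
polish_order <- function(ord, r_mat) {
  n <- length(ord)
  if (n < 3L) return(ord)
  repeat {
    best_d <- -1e-12; best <- NULL
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- delta_reverse(ord, r_mat, i, j)
      if (d < best_d) { best_d <- d; best <- c(1L, i, j) }
    }
    for (p in seq_len(n)) {
      m <- ord[p]
      rest <- ord[-p]
      base <- -delta_insert_slot(rest, r_mat, m, p)  # removal gain
      for (t in seq_len(n)) {
        if (t == p) next
        d <- base + delta_insert_slot(rest, r_mat, m, t)
        if (d < best_d) { best_d <- d; best <- c(2L, p, t) }
      }
    }
    if (is.null(best)) return(ord)
    if (best[1] == 1L) {
      ord[best[2]:best[3]] <- rev(ord[best[2]:best[3]])
    } else {
      m <- ord[best[2]]
      rest <- ord[-best[2]]
      ord <- append(rest, m, after = best[3] - 1L)
    }
  }
}

#' Order the markers of a linkage group by simulated annealing on SARF
#'
#' The ordering pipeline: (1) a greedy nearest-neighbour seriation gives an
#' initial order; (2) spatial sampling selects a core subset -- the most
#' informative marker (highest summed LOD, or lowest summed r when no LOD
#' matrix is given) in each window of `window` consecutive markers of the
#' initial order; (3) simulated annealing over core permutations minimises
#' the sum of adjacent recombination fractions (moves: segment reversal and
#' single-marker insertion; geometric cooling; the chain stops after
#' `patience` consecutive rejections); (4) the remaining markers are
#' inserted one at a time at their SARF-minimising interval; (5) a
#' deterministic best-improvement local search over reversals and
#' reinsertions runs until no move improves.  With a fixed seed the result
#' is reproducible bit for bit.
#'
#' @param r_mat complete symmetric recombination-fraction matrix of the
#'   group.
#' @param lod_mat optional LOD matrix (informativeness for core selection;
#'   also used to verify connectivity when supplied with `min_lod`).
#' @param seed integer seed for the annealing chain.
#' @param window spatial-sampling window size (markers); default 5.
#' @param cooling geometric cooling factor per step; default 0.995.
#' @param patience stop a chain after this many steps without improvement.
#' @param max_steps hard cap on annealing steps per chain.
#' @param restarts independent annealing chains; the best final order
#'   (after insertion and local search) is kept.
#' @param min_lod if `lod_mat` is given, error when the group is not
#'   connected at this LOD (default 3).
#' @return a list of class `"order_state"`: `order` (integer permutation),
#'   `sarf`, `seed`.
#' @export
order_sa <- function(r_mat, lod_mat = NULL, seed = NULL, window = 5L,
                     cooling = 0.995, patience = 2000L, max_steps = 200000L,
                     restarts = 2L, min_lod = 3) {
  n <- nrow(r_mat)
  stopifnot(n >= 1L, ncol(r_mat) == n)
  if (any(is.na(r_mat[upper.tri(r_mat)])))
    stop("pairwise r matrix is incomplete within the group")
  if (!is.null(lod_mat)) {
    comp <- group_markers(lod_mat, mlod_threshold = min_lod)
    nc <- length(comp$groups) + length(comp$unlinked)
    if (nc > 1L)
      stop(sprintf("group is disconnected at LOD %.1f: %d components",
                   min_lod, nc))
  }
  if (n <= 2L)
    return(structure(list(order = seq_len(n),
                          sarf = sarf(seq_len(n), r_mat), seed = seed),
                     class = "order_state"))
  with_seed(seed, {
    init <- greedy_order(r_mat)
    info <- if (!is.null(lod_mat)) rowSums(lod_mat) else -rowSums(r_mat)
    if (n > 2L * window) {
      wins <- split(init, ceiling(seq_along(init) / window))
      core <- vapply(wins, function(w) w[which.max(info[w])], integer(1))
    } else core <- init
    best_final <- NULL; best_final_s <- Inf
    for (restart in seq_len(restarts)) {
    ord <- core
    s <- sarf(ord, r_mat)
    if (length(ord) >= 3L) {
      rnd <- replicate(100, sarf(sample(ord), r_mat))
      temp <- stats::sd(rnd)
      if (is.finite(temp) && temp > 0) {
        stale <- 0L                      # steps since the last improvement
        nc <- length(ord)
        for (step in seq_len(max_steps)) {
          if (stats::runif(1) < 0.5) {
            ij <- sample.int(nc, 2L)
            i <- min(ij); j <- max(ij)
            d <- delta_reverse(ord, r_mat, i, j)
            if (d <= 0 || stats::runif(1) < exp(-d / temp))
              ord[i:j] <- rev(ord[i:j])
            else d <- NA
          } else {
            p <- sample.int(nc, 1L)
            t <- sample.int(nc - 1L, 1L)
            if (t >= p) t <- t + 1L
            m <- ord[p]
            rest <- ord[-p]
            d <- -delta_insert_slot(rest, r_mat, m, p) +
              delta_insert_slot(rest, r_mat, m, t)
            if (d <= 0 || stats::runif(1) < exp(-d / temp))
              ord <- append(rest, m, after = t - 1L)
            else d <- NA
          }
          stale <- if (!is.na(d) && d < -1e-12) 0L else stale + 1L
          temp <- temp * cooling
          if (stale >= patience) break
        }
      }
    }
    # insert non-core markers, most informative first
    rest <- setdiff(init, ord)
    for (m in rest[order(-info[rest])]) {
      deltas <- vapply(seq_len(length(ord) + 1L), function(t)
        delta_insert_slot(ord, r_mat, m, t), numeric(1))
      ord <- append(ord, m, after = which.min(deltas) - 1L)
    }
    ord <- polish_order(ord, r_mat)
    s_fin <- sarf(ord, r_mat)
    if (s_fin < best_final_s) { best_final_s <- s_fin; best_final <- ord }
    }
    structure(list(order = best_final, sarf = best_final_s, seed = seed),
              class = "order_state")
  })
}

# F2 genotype transition probabilities along a chromosome at recombination
# fraction r (states 0 = aa, 1 = ab, 2 = bb); the genotype process is the
# sum of two independent binary gamete chains.
f2_transition <- function(r) {
  p <- 1 - r
  matrix(c(p^2,     2 * r * p, r^2,
           r * p,   p^2 + r^2, r * p,
           r^2,     2 * r * p, p^2),
         nrow = 3, byrow = TRUE)
}

# Vectorised transition probability P(to | from) for vectors r/from/to.
f2_trans_vec <- function(r, from, to) {
  p <- 1 - r
  c00 <- p^2; c01 <- 2 * r * p; c02 <- r^2
  c10 <- r * p; c11 <- p^2 + r^2
  key <- from * 3L + to
  out <- numeric(length(key))
  out[key == 0L] <- c00[key == 0L]; out[key == 1L] <- c01[key == 1L]
  out[key == 2L] <- c02[key == 2L]; out[key == 3L] <- c10[key == 3L]
  out[key == 4L] <- c11[key == 4L]; out[key == 5L] <- c10[key == 5L]
  out[key == 6L] <- c02[key == 6L]; out[key == 7L] <- c01[key == 7L]
  out[key == 8L] <- c00[key == 8L]
  out
}

# Emission matrices (individuals x 3, one per marker): one-hot for observed
# hard calls / flat for missing, or the supplied likelihood array.
make_emissions <- function(g, emission = NULL) {
  m <- nrow(g); n <- ncol(g)
  if (!is.null(emission)) {
    stopifnot(identical(dim(emission)[1:2], dim(g)))
    return(lapply(seq_len(m), function(k) {
      e <- matrix(emission[k, , ], n, 3)
      e / pmax(rowSums(e), 1e-300)
    }))
  }
  lapply(seq_len(m), function(k) {
    e <- matrix(1, n, 3)
    obs <- !is.na(g[k, ])
    e[obs, ] <- 0
    e[cbind(which(obs), g[k, obs] + 1L)] <- 1
    e
  })
}

# Scaled forward-backward over the three-state genotype chain with adjacent
# recombination fractions r (length = #markers - 1).
fb_pass <- function(emis, r, prior = c(0.25, 0.5, 0.25)) {
  m <- length(emis)
  Tm <- lapply(r, f2_transition)
  alpha <- vector("list", m); beta <- vector("list", m)
  a <- sweep(emis[[1]], 2, prior, `*`)
  alpha[[1]] <- a / pmax(rowSums(a), 1e-300)
  for (k in seq_len(m - 1L) + 1L) {
    a <- (alpha[[k - 1L]] %*% Tm[[k - 1L]]) * emis[[k]]
    alpha[[k]] <- a / pmax(rowSums(a), 1e-300)
  }
  beta[[m]] <- matrix(1, nrow(emis[[1]]), 3)
  if (m > 1L) for (k in (m - 1L):1L) {
    b <- (beta[[k + 1L]] * emis[[k + 1L]]) %*% t(Tm[[k]])
    beta[[k]] <- b / pmax(rowSums(b), 1e-300)
  }
  list(alpha = alpha, beta = beta, Tm = Tm)
}

#' Posterior genotype re-calling along the map
#'
#' Runs the forward-backward algorithm over the three-state genotype chain
#' with the given adjacent recombination fractions and per-marker data
#' likelihoods, and returns the maximum-a-posteriori genotype of every
#' marker x individual cell.  At low read depth this recovers
#' heterozygotes undercalled from 1--3 reads, because the flanking markers
#' contribute exactly the information a single cell lacks; missing cells
#' (flat likelihood) are imputed by the same rule.
#'
#' @param genotypes_ordered markers x individuals hard-call matrix (rows in
#'   map order); used for emissions when `emission` is `NULL`.
#' @param r_adj adjacent recombination fractions (length `nrow - 1`).
#' @param emission optional markers x individuals x 3 likelihood array (see
#'   [multipoint_adjacent_r()]).
#' @param min_posterior only adopt the MAP re-call where its posterior
#'   reaches this value; elsewhere fall back per `fallback`.  The default 0
#'   adopts every MAP call.  A conservative setting (e.g. 0.9) stops the
#'   re-caller from imprinting an assumed marker order onto ambiguous
#'   cells, which would bias later re-ordering toward that assumption.
#' @param fallback what to keep where the posterior is below
#'   `min_posterior`: the original call (`"original"`) or missing
#'   (`"missing"`).
#' @return list with `genotypes` (re-calls, same shape) and `posterior`
#'   (markers x individuals matrix of the MAP posterior).
#' @export
hmm_recall_genotypes <- function(genotypes_ordered, r_adj, emission = NULL,
                                 min_posterior = 0,
                                 fallback = c("original", "missing")) {
  g <- genotypes_ordered
  fallback <- match.arg(fallback)
  m <- nrow(g)
  stopifnot(length(r_adj) == m - 1L)
  emis <- make_emissions(g, emission)
  fb <- fb_pass(emis, pmin(pmax(r_adj, 1e-7), 0.4999))
  out <- g
  pp <- matrix(NA_real_, m, ncol(g), dimnames = dimnames(g))
  for (k in seq_len(m)) {
    post <- fb$alpha[[k]] * fb$beta[[k]]
    post <- post / pmax(rowSums(post), 1e-300)
    map_call <- max.col(post, ties.method = "first")
    pk <- post[cbind(seq_len(nrow(post)), map_call)]
    keep <- pk >= min_posterior
    out[k, keep] <- map_call[keep] - 1L
    if (fallback == "missing") out[k, !keep] <- NA_integer_
    pp[k, ] <- pk
  }
  list(genotypes = out, posterior = pp)
}

# Total log-likelihood of the genotype chain (forward algorithm with
# scaling), summed over individuals.
chain_loglik <- function(emis, r, prior = c(0.25, 0.5, 0.25)) {
  m <- length(emis)
  a <- sweep(emis[[1]], 2, prior, `*`)
  s <- pmax(rowSums(a), 1e-300)
  ll <- log(s)
  a <- a / s
  if (m > 1L) for (k in 2:m) {
    a <- (a %*% f2_transition(r[k - 1L])) * emis[[k]]
    s <- pmax(rowSums(a), 1e-300)
    ll <- ll + log(s)
    a <- a / s
  }
  sum(ll)
}

# EM for adjacent r on a list of emission matrices (internal core of
# multipoint_adjacent_r, reused by the order refinement).
mp_fit_r <- function(emis, r, max_iter = 20L, tol = 1e-6) {
  m <- length(emis)
  r <- pmin(pmax(r, 1e-7), 0.4999)
  for (iter in seq_len(max_iter)) {
    fb <- fb_pass(emis, r)
    r_new <- r
    for (k in seq_len(m - 1L)) {
      left <- fb$alpha[[k]]
      right <- emis[[k + 1L]] * fb$beta[[k + 1L]]
      z <- pmax(rowSums(left * (right %*% t(fb$Tm[[k]]))), 1e-300)
      tab <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3)
        tab[i, j] <- sum(left[, i] * fb$Tm[[k]][i, j] * right[, j] / z)
      fit <- estimate_r_em(tab)
      if (fit$defined) r_new[k] <- fit$r_hat
    }
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  r
}

# Refine a marker order by maximum likelihood of the genotype chain under
# the ORIGINAL per-call emissions: first-improvement sweeps over adjacent
# swaps and short-range relocations, each candidate scored by the chain
# log-likelihood with adjacent r refitted (warm-started EM).  Because the
# score uses raw read likelihoods, an order imprinted on re-called
# genotypes earns no spurious support here.
refine_order_ml <- function(ord, emis_all, r_adj = NULL, max_sweeps = 4L,
                            reloc_range = 2L) {
  m <- length(ord)
  if (m < 3L) return(list(order = ord, r = r_adj))
  cur_emis <- emis_all[ord]
  r <- mp_fit_r(cur_emis, if (is.null(r_adj)) rep(0.1, m - 1L) else r_adj,
                max_iter = 8L)
  cur_ll <- chain_loglik(cur_emis, r)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(m - 1L)) {
      cand_sets <- list(replace(seq_len(m), c(i, i + 1L), c(i + 1L, i)))
      for (L in 3:6) {                   # short segment reversals
        if (i + L - 1L <= m) {
          perm <- seq_len(m)
          perm[i:(i + L - 1L)] <- rev(perm[i:(i + L - 1L)])
          cand_sets <- c(cand_sets, list(perm))
        }
      }
      if (reloc_range >= 2L) {
        if (i + 2L <= m)
          cand_sets <- c(cand_sets, list(append(seq_len(m)[-i], i,
                                                after = i + 1L)))
        if (i >= 2L)
          cand_sets <- c(cand_sets, list(append(seq_len(m)[-(i + 1L)], i + 1L,
                                                after = i - 2L + 1L)))
      }
      for (perm in cand_sets) {
        new_ord <- ord[perm]
        new_emis <- emis_all[new_ord]
        new_r <- mp_fit_r(new_emis, r, max_iter = 3L)
        new_ll <- chain_loglik(new_emis, new_r)
        if (new_ll > cur_ll + 1e-6) {
          ord <- new_ord
          r <- mp_fit_r(new_emis, new_r, max_iter = 5L)
          cur_ll <- chain_loglik(emis_all[ord], r)
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(order = ord, r = r)
}

#' Multipoint re-estimation of adjacent recombination fractions
#'
#' EM over a hidden Markov model along the ordered group: genotypes form a
#' three-state Markov chain with transition matrices determined by the
#' adjacent recombination fractions; missing genotypes are marginalised by
#' the forward--backward algorithm; each adjacent pair's expected joint
#' genotype table is then refit by the two-point EM ([estimate_r_em()]).
#' With complete data this reduces exactly to complete-case two-point
#' estimates.  This deterministic scheme stands in for a sampling-based
#' multipoint estimator; the interface (ordered genotypes in, updated
#' adjacent r out) is the same.
#'
#' @param genotypes_ordered markers x individuals genotype matrix with rows
#'   in map order.
#' @param r_init optional initial adjacent r vector (length `nrow - 1`);
#'   defaults to complete-case two-point estimates.
#' @param max_iter,tol EM sweeps over the chain and convergence tolerance
#'   on max |delta r|.
#' @param emission optional markers x individuals x 3 array of per-genotype
#'   data likelihoods (e.g. the `likelihood` component of
#'   [call_genotypes()]).  When given, it replaces the one-hot emissions of
#'   the hard calls, so genotype uncertainty at low read depth is
#'   marginalised instead of trusted; the estimates then approximate the
#'   read-level maximum likelihood.
#' @return numeric vector of adjacent recombination fractions.
#' @export
multipoint_adjacent_r <- function(genotypes_ordered, r_init = NULL,
                                  max_iter = 20L, tol = 1e-6,
                                  emission = NULL) {
  g <- genotypes_ordered
  m <- nrow(g); n <- ncol(g)
  if (m < 2L) return(numeric(0))
  if (is.null(r_init)) {
    r_init <- vapply(seq_len(m - 1L), function(k)
      estimate_r_em(pair_table(g[k, ], g[k + 1L, ]))$r_hat, numeric(1))
    r_init[is.na(r_init)] <- 0.25
  }
  emis <- make_emissions(g, emission)
  mp_fit_r(emis, r_init, max_iter = max_iter, tol = tol)
}

#' SMOOTH-style removal of singleton genotyping errors
#'
#' For every observed genotype the conditional probability given the
#' nearest non-missing flanking genotypes of the same individual is
#' computed from the three-state genotype Markov chain, with recombination
#' fractions derived from the map distances through the inverse Kosambi
#' function (so flanks are weighted by distance).  Observations whose
#' probability falls below `threshold` -- in practice singletons whose two
#' flanks agree against them, implying a double recombinant in a short
#' interval -- are set to missing, never rewritten.  Passes repeat until a
#' pass makes no change.
#'
#' @param genotypes_ordered markers x individuals matrix, rows in map order.
#' @param positions_cM map positions of the rows (non-decreasing).
#' @param threshold probability below which an observation is removed;
#'   default 0.001.
#' @param max_passes cap on correction passes.
#' @param rise multiplier applied to the threshold after each pass that
#'   makes no change (rising stringency); default 1 keeps the threshold
#'   fixed.
#' @param threshold_max ceiling of the rising threshold.
#' @return list with the corrected `genotypes` and a `changes` data.frame
#'   (`marker`, `individual`, `old_genotype`, `prob`, `pass`).
#' @export
smooth_correct <- function(genotypes_ordered, positions_cM,
                           threshold = 0.001, max_passes = 10L,
                           rise = 1, threshold_max = threshold) {
  g <- genotypes_ordered
  m <- nrow(g); n <- ncol(g)
  if (is.unsorted(positions_cM)) stop("positions must be in map order")
  stopifnot(length(positions_cM) == m)
  changes <- list()
  thr <- threshold
  for (pass in seq_len(max_passes)) {
    n_changed <- 0L
    for (ind in seq_len(n)) {
      obs <- which(!is.na(g[, ind]))
      if (length(obs) < 2L) next
      gi <- g[obs, ind]
      no <- length(obs)
      lft <- c(NA, obs[-no]); rgt <- c(obs[-1L], NA)
      gl <- c(NA_integer_, gi[-no]); gr <- c(gi[-1L], NA_integer_)
      dl <- positions_cM[obs] - positions_cM[lft]
      dr <- positions_cM[rgt] - positions_cM[obs]
      rl <- pmin(kosambi_inverse(ifelse(is.na(dl), 0, dl)), 0.4999)
      rr <- pmin(kosambi_inverse(ifelse(is.na(dr), 0, dr)), 0.4999)
      # unnormalised P(g | flanks) for each candidate genotype 0/1/2
      lik <- sapply(0:2, function(cand) {
        cv <- rep.int(cand, no)
        l <- f2_trans_vec(rl, ifelse(is.na(gl), 0L, gl), cv)
        l[is.na(gl)] <- stats::dbinom(cand, 2, 0.5)
        rgtp <- f2_trans_vec(rr, cv, ifelse(is.na(gr), 0L, gr))
        rgtp[is.na(gr)] <- 1
        l * rgtp
      })
      if (no == 1L) lik <- matrix(lik, nrow = 1L)
      p_obs <- lik[cbind(seq_len(no), gi + 1L)] / rowSums(lik)
      bad <- which(p_obs < thr)
      if (length(bad)) {
        for (t in bad) {
          changes[[length(changes) + 1L]] <- data.frame(
            marker = rownames(g)[obs[t]] %||% as.character(obs[t]),
            individual = colnames(g)[ind] %||% as.character(ind),
            old_genotype = gi[t], prob = p_obs[t], pass = pass)
        }
        g[obs[bad], ind] <- NA_integer_
        n_changed <- n_changed + length(bad)
      }
    }
    if (n_changed == 0L) {
      if (thr >= threshold_max || rise <= 1) break
      thr <- min(thr * rise, threshold_max)
    }
  }
  list(genotypes = g,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(marker = character(0),
                                 individual = character(0),
                                 old_genotype = integer(0),
                                 prob = numeric(0), pass = integer(0)))
}

#' Impute missing genotypes by k nearest markers on the map
#'
#' Each missing genotype takes the majority genotype among the `k` nearest
#' non-missing markers (by map distance) of the same individual; ties go to
#' the single nearest marker.  Individuals with no observed genotypes stay
#' missing.
#'
#' @param genotypes_ordered markers x individuals matrix, rows in map
#'   order.
#' @param positions_cM map positions of the rows.
#' @param k number of neighbours (>= 1).
#' @return the completed genotype matrix.
#' @export
knn_impute <- function(genotypes_ordered, positions_cM, k = 5L) {
  if (k < 1L) stop("'k' must be at least 1")
  g <- genotypes_ordered
  stopifnot(length(positions_cM) == nrow(g))
  for (ind in seq_len(ncol(g))) {
    obs <- which(!is.na(g[, ind]))
    if (length(obs) == 0L) next
    for (j in which(is.na(g[, ind]))) {
      d <- abs(positions_cM[obs] - positions_cM[j])
      nb <- obs[order(d, obs)][seq_len(min(k, length(obs)))]
      cnt <- tabulate(g[nb, ind] + 1L, nbins = 3L)
      top <- which(cnt == max(cnt))
      g[j, ind] <- if (length(top) == 1L) top - 1L
                   else g[obs[which.min(d)], ind]
    }
  }
  g
}

# Best position of one marker relative to a reference map: scans every
# interval (and both ends) over a position grid, scoring the conditional
# likelihood of the marker's genotypes given the nearest non-missing
# reference flanks (up to two per side, weighted by map distance through
# the inverse Kosambi function).  Returns list(pos, loglik, max_lod).
place_one_marker <- function(ga, ref_pos, ref_geno, grid_points,
                             end_extension_cM) {
  nf <- length(ref_pos)
  n_ind <- length(ga)
  lods <- vapply(seq_len(nf), function(k) {
    f <- estimate_r_em(pair_table(ref_geno[k, ], ga))
    if (f$defined) f$lod else 0
  }, numeric(1))
  best_ll <- -Inf; best_pos <- NA_real_
  obs <- which(!is.na(ga))
  for (t in 0:nf) {                       # interval between t and t+1
    lo <- if (t == 0L) ref_pos[1] - end_extension_cM else ref_pos[t]
    hi <- if (t == nf) ref_pos[nf] + end_extension_cM else ref_pos[t + 1L]
    if (hi - lo < 1e-9) next
    flank_l <- if (t >= 1L) max(1L, t - 1L):t else integer(0)
    flank_r <- if (t < nf) (t + 1L):min(nf, t + 2L) else integer(0)
    # nearest non-missing flank genotype/position per individual
    pick <- function(idx, nearest_first) {
      gsel <- rep(NA_integer_, n_ind); psel <- rep(NA_real_, n_ind)
      for (f in if (nearest_first) rev(idx) else idx) {
        fill <- is.na(gsel) & !is.na(ref_geno[f, ])
        gsel[fill] <- ref_geno[f, fill]; psel[fill] <- ref_pos[f]
      }
      list(g = gsel, p = psel)
    }
    L <- pick(flank_l, nearest_first = TRUE)
    R <- pick(flank_r, nearest_first = FALSE)
    gl0 <- ifelse(is.na(L$g), 0L, L$g)
    gr0 <- ifelse(is.na(R$g), 0L, R$g)
    grid <- seq(lo, hi, length.out = grid_points + 2L)
    grid <- grid[-c(1L, length(grid))]
    # framework positions themselves are candidates (exact co-location)
    if (t >= 1L) grid <- c(ref_pos[t], grid)
    if (t < nf) grid <- c(grid, ref_pos[t + 1L])
    for (x in grid) {
      dl <- pmax(x - L$p, 0); dl[is.na(dl)] <- 0
      dr <- pmax(R$p - x, 0); dr[is.na(dr)] <- 0
      rl <- pmin(kosambi_inverse(dl), 0.4999)
      rr <- pmin(kosambi_inverse(dr), 0.4999)
      lik <- sapply(0:2, function(cand) {
        cv <- rep.int(cand, n_ind)
        lv <- f2_trans_vec(rl, gl0, cv)
        lv[is.na(L$g)] <- stats::dbinom(cand, 2, 0.5)
        rv <- f2_trans_vec(rr, cv, gr0)
        rv[is.na(R$g)] <- 1
        lv * rv
      })
      p <- lik[cbind(obs, ga[obs] + 1L)] / rowSums(lik[obs, , drop = FALSE])
      ll <- sum(log(pmax(p, 1e-300)))
      if (ll > best_ll) { best_ll <- ll; best_pos <- x }
    }
  }
  list(pos = best_pos, loglik = best_ll, max_lod = max(lods))
}

#' Insert distorted accessory markers into a finished framework map
#'
#' Each accessory marker is placed, without reordering or moving the
#' framework markers, at the position maximising its multipoint likelihood
#' given up to two flanking reference genotypes on each side: every
#' reference interval (and the two chromosome ends) is scanned over a
#' position grid; the likelihood of the accessory genotypes given the
#' nearest non-missing flanks (recombination fractions from inverse
#' Kosambi of the map distances) is summed over individuals.  Markers whose
#' maximum two-point LOD against the reference falls below `lod_threshold`
#' are left unplaced.  With `chain = TRUE` (the default) insertion proceeds
#' in rounds, each placed marker joining the reference set, so a cluster of
#' distorted markers beyond the framework's edge -- the typical geometry of
#' a segregation distortion region under strong gamete selection -- is
#' reached stepwise; framework positions never move.  If an end placement
#' implies a negative coordinate, all positions are shifted so the minimum
#' is zero (framework spacing unchanged).
#'
#' @param framework_positions named numeric vector: map positions (cM) of
#'   the framework markers, in order.
#' @param framework_geno framework genotype matrix (rows in map order).
#' @param accessory_geno genotype matrix of the accessory markers (same
#'   individuals).
#' @param lod_threshold minimum linkage to the reference (default 5).
#' @param grid_points positions tested per interval.
#' @param end_extension_cM how far beyond each map end to scan.
#' @param chain allow placed accessory markers to serve as reference for
#'   the still-unplaced ones?
#' @return a data.frame `marker_id`, `position_cM`, `accessory`, `placed`
#'   covering framework and accessory markers, sorted by position (ties:
#'   framework first).
#' @export
insert_skewed <- function(framework_positions, framework_geno,
                          accessory_geno, lod_threshold = 5,
                          grid_points = 9L, end_extension_cM = 30,
                          chain = TRUE) {
  nf <- length(framework_positions)
  stopifnot(nrow(framework_geno) == nf)
  fpos <- as.numeric(framework_positions)
  fids <- names(framework_positions) %||% rownames(framework_geno)
  out <- data.frame(marker_id = fids, position_cM = fpos,
                    accessory = FALSE, placed = TRUE,
                    stringsAsFactors = FALSE)
  if (is.null(accessory_geno) || nrow(accessory_geno) == 0L) return(out)
  na <- nrow(accessory_geno)
  aids <- rownames(accessory_geno) %||% sprintf("acc%03d", seq_len(na))
  acc_pos <- rep(NA_real_, na)
  remaining <- seq_len(na)
  ref_pos <- fpos; ref_geno <- framework_geno
  repeat {
    # cheap pre-pass: best two-point LOD of each remaining marker against
    # the current reference, to fix the placement order (strongest first)
    pre_lod <- vapply(remaining, function(a) {
      max(vapply(seq_along(ref_pos), function(k) {
        f <- estimate_r_em(pair_table(ref_geno[k, ], accessory_geno[a, ]))
        if (f$defined) f$lod else 0
      }, numeric(1)))
    }, numeric(1))
    eligible <- remaining[pre_lod >= lod_threshold]
    eligible <- eligible[order(-pre_lod[pre_lod >= lod_threshold])]
    placed_now <- integer(0)
    for (a in eligible) {
      pl <- place_one_marker(accessory_geno[a, ], ref_pos, ref_geno,
                             grid_points, end_extension_cM)
      if (pl$max_lod >= lod_threshold && !is.na(pl$pos)) {
        acc_pos[a] <- pl$pos
        placed_now <- c(placed_now, a)
        if (chain) {
          at <- findInterval(pl$pos, ref_pos)
          ref_pos <- append(ref_pos, pl$pos, after = at)
          ref_geno <- rbind(ref_geno[seq_len(at), , drop = FALSE],
                            accessory_geno[a, , drop = FALSE],
                            if (at < nrow(ref_geno))
                              ref_geno[(at + 1L):nrow(ref_geno), ,
                                       drop = FALSE])
        }
      }
    }
    remaining <- setdiff(remaining, placed_now)
    if (!chain || length(placed_now) == 0L || length(remaining) == 0L) break
  }
  out <- rbind(out, data.frame(marker_id = aids, position_cM = acc_pos,
                               accessory = TRUE, placed = !is.na(acc_pos),
                               stringsAsFactors = FALSE))
  placed <- out[out$placed, , drop = FALSE]
  shift <- min(placed$position_cM)
  out$position_cM <- out$position_cM - shift
  out[order(out$position_cM, out$accessory, method = "radix",
            na.last = TRUE), , drop = FALSE]
}
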