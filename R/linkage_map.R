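# The central fitting function: from a called F2 genotype matrix to a
# finished linkage map, and the S3 methods of the resulting object.

# One complete mapping round: QC split, grouping, per-group ordering with
# multipoint cycles, posterior re-calling (when read likelihoods are
# available), SMOOTH correction and kNN imputation, accessory insertion.
map_round <- function(genotypes, lik, progeny_depth, parent_depth, qc, alpha,
                      mlod_threshold, group_threshold, cycles,
                      smooth_threshold, smooth_rise, smooth_threshold_max,
                      knn_k, insert_accessory, max_adjacent_r, grid_points,
                      refine_ml, seed) {
  qc_use <- qc_config(parent_depth_min = qc$parent_depth_min,
                      progeny_depth_min = qc$progeny_depth_min,
                      missing_max = qc$missing_max, alpha = alpha)
  qc_res <- apply_filters(genotypes, progeny_depth, parent_depth, qc_use)
  fw <- genotypes[qc_res$framework, , drop = FALSE]
  acc <- genotypes[qc_res$accessory, , drop = FALSE]
  if (nrow(fw) < 2L) stop("fewer than two framework markers survive QC")
  # linkage groups are formed over every marker that passed QC -- framework
  # and accessory alike -- so that a stretch of distorted markers keeps its
  # chromosome in one piece; only framework members are ordered and mapped
  allg <- rbind(fw, acc)
  is_fw <- c(rep(TRUE, nrow(fw)), rep(FALSE, nrow(acc)))
  pl_all <- pairwise_linkage(allg)
  grp_all <- group_markers(pl_all$mlod, group_threshold)
  comp_fw <- lapply(grp_all$groups, function(ix) ix[is_fw[ix]])
  keep_comp <- vapply(comp_fw, length, integer(1)) >= 2L
  if (!any(keep_comp))
    stop("no linkage groups form at the MLOD threshold")
  groups_fw <- lapply(comp_fw[keep_comp], function(ix) ix)  # indices in allg
  acc_comp <- lapply(grp_all$groups[keep_comp],
                     function(ix) ix[!is_fw[ix]] - nrow(fw))
  unlinked_fw <- sort(c(grp_all$unlinked[grp_all$unlinked <= nrow(fw)],
                        unlist(comp_fw[!keep_comp], use.names = FALSE)))
  pl <- list(r = pl_all$r[seq_len(nrow(fw)), seq_len(nrow(fw)), drop = FALSE],
             lod = pl_all$lod[seq_len(nrow(fw)), seq_len(nrow(fw)),
                              drop = FALSE])
  grp <- list(groups = groups_fw, unlinked = unlinked_fw)

  # fragment healing: single-linkage at a hard per-pair threshold breaks a
  # chromosome whenever one junction pair dips below it by sampling noise.
  # Two fragments of one chromosome share many moderately-linked terminal
  # pairs, so aggregate evidence over the 3x3 terminal windows (sum of
  # MLOD, plus one pair at >= 3) separates a weak true junction from a
  # pair of distinct chromosomes by an order of magnitude.
  if (length(grp$groups) > 1L) {
    mlod_fw <- pl_all$mlod[seq_len(nrow(fw)), seq_len(nrow(fw)),
                           drop = FALSE]
    tentative_order <- function(idx) {
      if (length(idx) <= 2L) return(idx)
      st <- order_sa(pl$r[idx, idx, drop = FALSE],
                     pl$lod[idx, idx, drop = FALSE],
                     seed = if (is.null(seed)) NULL else seed + 977L,
                     patience = 500L, max_steps = 20000L, restarts = 1L,
                     min_lod = 0)
      idx[st$order]
    }
    ords <- lapply(grp$groups, tentative_order)
    ends_of <- function(o) {
      k <- min(3L, length(o))
      list(s = o[seq_len(k)], e = o[length(o) - seq_len(k) + 1L])
    }
    repeat {
      n_grp <- length(grp$groups)
      if (n_grp < 2L) break
      best <- NULL; best_sum <- -Inf
      for (a in seq_len(n_grp - 1L)) for (b in (a + 1L):n_grp) {
        ea <- ends_of(ords[[a]]); eb <- ends_of(ords[[b]])
        for (wa in ea) for (wb in eb) {
          sub <- mlod_fw[wa, wb, drop = FALSE]
          if (sum(sub) > best_sum) { best_sum <- sum(sub)
            best <- list(a = a, b = b, single = max(sub)) }
        }
      }
      if (is.null(best) || best_sum < 3 * group_threshold ||
          best$single < 3) break
      merged <- c(grp$groups[[best$a]], grp$groups[[best$b]])
      grp$groups[[best$a]] <- merged
      acc_comp[[best$a]] <- c(acc_comp[[best$a]], acc_comp[[best$b]])
      grp$groups[[best$b]] <- NULL
      acc_comp[[best$b]] <- NULL
      ords[[best$a]] <- tentative_order(merged)
      ords[[best$b]] <- NULL
    }
  }
  sub_lik <- function(ids) {
    if (is.null(lik)) NULL else lik[ids, , , drop = FALSE]
  }

  group_fits <- lapply(seq_along(grp$groups), function(g) {
    idx <- grp$groups[[g]]
    r_sub <- pl$r[idx, idx, drop = FALSE]
    lod_sub <- pl$lod[idx, idx, drop = FALSE]
    gseed <- if (is.null(seed)) NULL else seed + 7919L * g
    # framework members of a component may be bridged only through
    # accessory markers, so no connectivity requirement is imposed here
    st <- order_sa(r_sub, lod_sub, seed = gseed, min_lod = 0)
    ord <- st$order
    geno_ord <- fw[idx[ord], , drop = FALSE]
    ems <- sub_lik(rownames(geno_ord))
    r_adj <- NULL
    if (cycles > 0L) {
      for (cyc in seq_len(cycles)) {
        r_adj <- multipoint_adjacent_r(geno_ord, r_init = r_adj,
                                       emission = ems)
        for (k in seq_along(r_adj)) {
          a <- ord[k]; b <- ord[k + 1L]
          r_sub[a, b] <- r_sub[b, a] <- r_adj[k]
        }
        new_ord <- polish_order(ord, r_sub)
        if (identical(new_ord, ord)) break
        ord <- new_ord
        geno_ord <- fw[idx[ord], , drop = FALSE]
        ems <- sub_lik(rownames(geno_ord))
        r_adj <- NULL
      }
    }
    # maximum-likelihood refinement of the order under the original
    # read-level emissions (final round): local swaps/relocations scored
    # by the chain likelihood, immune to any imprint of earlier re-calls
    if (refine_ml && !is.null(ems) && length(ord) >= 3L) {
      r_adj <- multipoint_adjacent_r(geno_ord, r_init = r_adj,
                                     emission = ems)
      rf <- refine_order_ml(seq_along(ord), make_emissions(geno_ord, ems),
                            r_adj)
      if (!identical(rf$order, seq_along(ord))) {
        ord <- ord[rf$order]
        geno_ord <- fw[idx[ord], , drop = FALSE]
        ems <- sub_lik(rownames(geno_ord))
      }
      r_adj <- rf$r
    }
    # canonical orientation: lexicographically smaller terminal id first
    ids <- rownames(fw)[idx[ord]]
    if (ids[length(ids)] < ids[1]) {
      ord <- rev(ord)
      geno_ord <- fw[idx[ord], , drop = FALSE]
      ems <- sub_lik(rownames(geno_ord))
      r_adj <- if (is.null(r_adj)) NULL else rev(r_adj)
    }
    r_adj <- multipoint_adjacent_r(geno_ord, r_init = r_adj, emission = ems)
    if (!is.null(ems) && length(r_adj))
      geno_ord <- hmm_recall_genotypes(geno_ord, r_adj,
                                       emission = ems)$genotypes
    pos0 <- c(0, cumsum(kosambi(pmin(r_adj, max_adjacent_r))))
    sm <- smooth_correct(geno_ord, pos0, threshold = smooth_threshold,
                         rise = smooth_rise,
                         threshold_max = smooth_threshold_max,
                         max_passes = 25L)
    geno_corr <- sm$genotypes
    pos1 <- pos0
    geno_full <- knn_impute(geno_corr, pos1, k = knn_k)
    r_fin <- multipoint_adjacent_r(geno_full, r_init = r_adj, emission = ems)
    pos <- c(0, cumsum(kosambi(pmin(r_fin, max_adjacent_r))))
    list(marker_idx = idx[ord], positions = pos, genotypes = geno_full,
         changes = sm$changes, sarf = sarf(ord, r_sub))
  })

  # accessory markers belong to the component they grouped with;
  # insert_skewed() decides (with chaining) whether each is linked enough
  acc_assign <- rep(NA_integer_, nrow(acc))
  if (insert_accessory && nrow(acc) > 0L)
    for (g in seq_along(acc_comp)) acc_assign[acc_comp[[g]]] <- g

  # provisional rounds place component accessory markers unconditionally
  # (their linkage to the group was already established at the grouping
  # threshold), so the distorted tail gets positions and hence posterior
  # cleaning; the final round re-places everything from cleaned genotypes
  # at the full threshold
  prov_thr <- if (refine_ml) mlod_threshold else 0
  ext_maps <- lapply(seq_along(group_fits), function(g) {
    gf <- group_fits[[g]]
    fpos <- stats::setNames(gf$positions, rownames(fw)[gf$marker_idx])
    acc_here <- which(!is.na(acc_assign) & acc_assign == g)
    ext <- insert_skewed(fpos, gf$genotypes,
                         acc[acc_here, , drop = FALSE],
                         lod_threshold = prov_thr,
                         grid_points = grid_points)
    ext$lg <- g
    ext
  })

  # second pass: markers that fell out of grouping (unlinked framework
  # markers, accessory markers without a component) are offered to the
  # finished maps by the same multipoint placement -- the "unmapped
  # markers" are added back and the build iterates round over round.
  # Provisional rounds accept weaker linkage so the marker gets cleaned
  # and can re-enter QC properly next round; the final round applies the
  # full threshold.
  rescue_thr <- if (refine_ml) mlod_threshold else 3
  rescue_ids <- c(rownames(fw)[grp$unlinked],
                  if (insert_accessory) rownames(acc)[is.na(acc_assign)])
  rescue_is_acc <- c(rep(FALSE, length(grp$unlinked)),
                     if (insert_accessory) rep(TRUE, sum(is.na(acc_assign))))
  still_unlinked <- character(0); unplaced <- character(0)
  if (!insert_accessory) unplaced <- rownames(acc) %||% character(0)
  if (length(rescue_ids) && length(ext_maps)) {
    refs <- lapply(seq_along(ext_maps), function(g) {
      ext <- ext_maps[[g]][ext_maps[[g]]$placed, , drop = FALSE]
      gf <- group_fits[[g]]
      rows <- rbind(gf$genotypes,
                    allg[setdiff(ext$marker_id, rownames(gf$genotypes)), ,
                         drop = FALSE])[ext$marker_id, , drop = FALSE]
      list(pos = ext$position_cM, geno = rows)
    })
    for (k in seq_along(rescue_ids)) {
      rid <- rescue_ids[k]
      gr <- allg[rid, ]
      best_lod <- -Inf; best_g <- NA_integer_
      for (g in seq_along(refs)) {
        probe <- unique(round(seq(1, nrow(refs[[g]]$geno),
                                  length.out = min(12L,
                                                   nrow(refs[[g]]$geno)))))
        lods <- vapply(probe, function(j) {
          tab <- pair_table(refs[[g]]$geno[j, ], gr)
          f <- estimate_r_em(tab)
          if (f$defined) min(f$lod, independence_lod(tab)) else 0
        }, numeric(1))
        if (max(lods) > best_lod) { best_lod <- max(lods); best_g <- g }
      }
      placed <- FALSE
      if (is.finite(best_lod) && best_lod >= rescue_thr) {
        pl <- place_one_marker(gr, refs[[best_g]]$pos, refs[[best_g]]$geno,
                               grid_points, end_extension_cM = 30)
        if (pl$max_lod >= rescue_thr && !is.na(pl$pos)) {
          ext_maps[[best_g]] <- rbind(
            ext_maps[[best_g]],
            data.frame(marker_id = rid, position_cM = pl$pos,
                       accessory = rescue_is_acc[k], placed = TRUE,
                       lg = ext_maps[[best_g]]$lg[1],
                       stringsAsFactors = FALSE))
          at <- findInterval(pl$pos, refs[[best_g]]$pos)
          refs[[best_g]]$pos <- append(refs[[best_g]]$pos, pl$pos,
                                       after = at)
          rg <- refs[[best_g]]$geno
          refs[[best_g]]$geno <- rbind(
            rg[seq_len(at), , drop = FALSE],
            allg[rid, , drop = FALSE],
            if (at < nrow(rg)) rg[(at + 1L):nrow(rg), , drop = FALSE])
          placed <- TRUE
        }
      }
      if (!placed) {
        if (rescue_is_acc[k]) unplaced <- c(unplaced, rid)
        else still_unlinked <- c(still_unlinked, rid)
      }
    }
    ext_maps <- lapply(ext_maps, function(ext) {
      ext <- ext[order(ext$position_cM, ext$accessory, method = "radix",
                       na.last = TRUE), , drop = FALSE]
      shift <- min(ext$position_cM[ext$placed])
      ext$position_cM <- ext$position_cM - shift
      ext
    })
  } else still_unlinked <- rownames(fw)[grp$unlinked]
  list(qc_res = qc_res, group_fits = group_fits, ext_maps = ext_maps,
       fw = fw, acc = acc, allg = allg, unplaced = unplaced,
       unlinked = still_unlinked)
}

# Cleaned genotypes for every placed marker of a finished round, used as the
# input of the next round: posterior re-call along the extended map when
# likelihoods are available, SMOOTH + kNN otherwise.
corrected_matrix <- function(round, lik, knn_k, smooth_threshold,
                             smooth_rise, smooth_threshold_max) {
  blocks <- lapply(seq_along(round$ext_maps), function(g) {
    ext <- round$ext_maps[[g]]
    ext <- ext[ext$placed, , drop = FALSE]
    gf <- round$group_fits[[g]]
    rows <- rbind(gf$genotypes,
                  round$allg[setdiff(ext$marker_id,
                                     rownames(gf$genotypes)), ,
                             drop = FALSE])
    rows <- rows[ext$marker_id, , drop = FALSE]
    r_adj <- pmin(kosambi_inverse(pmax(diff(ext$position_cM), 0)), 0.4999)
    if (!is.null(lik) && nrow(rows) > 1L) {
      hmm_recall_genotypes(rows, r_adj,
                           emission = lik[ext$marker_id, , ,
                                          drop = FALSE])$genotypes
    } else {
      sm <- smooth_correct(rows, ext$position_cM,
                           threshold = smooth_threshold, rise = smooth_rise,
                           threshold_max = smooth_threshold_max,
                           max_passes = 25L)
      knn_impute(sm$genotypes, ext$position_cM, k = knn_k)
    }
  })
  do.call(rbind, blocks)
}

#' Fit a genetic linkage map to an F2 genotype matrix
#'
#' Runs the full map-construction pipeline: marker QC (depth and
#' missingness filters plus the 1:2:1 chi-square segregation test, which
#' splits framework from distorted accessory markers), two-point EM
#' recombination fractions and LOD scores over all framework pairs,
#' single-linkage grouping at the MLOD threshold, within-group
#' simulated-annealing ordering on the sum of adjacent recombination
#' fractions alternated with multipoint (HMM) re-estimation of adjacent r,
#' SMOOTH-style singleton error removal with rising stringency,
#' k-nearest-neighbour imputation, Kosambi map distances, and multipoint
#' maximum-likelihood insertion of the accessory markers.
#'
#' When `x` is a [call_genotypes()] object its per-call genotype
#' likelihoods feed the multipoint steps: adjacent recombination fractions
#' are estimated with read-level emissions, and genotypes are re-called
#' from the posterior given reads plus flanking markers.  At the ~3x
#' offspring coverage typical of reduced-representation F2 designs this is
#' essential -- a quarter of heterozygotes are undercalled from 1--3 reads,
#' which would otherwise inflate every recombination fraction and flood the
#' segregation test with spurious distortion.
#'
#' With `rounds > 1` (default 3) the whole map building is repeated: each round's
#' cleaned genotype matrix seeds the next, in which the segregation test,
#' grouping and ordering are redone from scratch.  Early rounds use a
#' stricter distortion alpha (`alpha / 50`, at most 1e-3) so that markers
#' whose apparent distortion stems from genotyping noise stay in the
#' framework until the noise has been corrected; the final round applies
#' the configured alpha.
#'
#' @param x markers x individuals integer matrix (0 = aa, 1 = ab, 2 = bb,
#'   NA = missing) of aa x bb markers, or a `"genotype_matrix"` from
#'   [call_genotypes()] (recommended: enables likelihood-aware multipoint).
#' @param progeny_depth,parent_depth optional depth metadata passed to
#'   [apply_filters()] in the first round (depth filters are skipped when
#'   `NULL`).
#' @param qc a [qc_config()].
#' @param mlod_threshold grouping LOD threshold (default 5).
#' @param rounds map-building rounds (default 3).
#' @param cycles ordering/multipoint alternation cycles per round
#'   (default 4; 0 keeps the pure two-point order and distances).
#' @param smooth_threshold starting probability threshold of
#'   [smooth_correct()].
#' @param smooth_rise,smooth_threshold_max rising-stringency schedule of
#'   the correction (threshold multiplied by `smooth_rise` after each
#'   clean pass, up to the ceiling).
#' @param knn_k neighbours for [knn_impute()].
#' @param insert_accessory place distorted markers after framework mapping?
#' @param min_run minimum run length of [detect_sdr()].
#' @param max_adjacent_r cap on adjacent recombination fractions when
#'   converting to Kosambi distances (default 0.49).
#' @param seed integer seed controlling the annealing chains (per-group
#'   and per-round seeds are derived from it); fixed seed gives a
#'   reproducible map.
#' @return an object of class `"linkage_map"`: list with `map` (data.frame
#'   `marker_id`, `lg`, `position_cM`, `accessory`, `distorted`), `stats`
#'   (a [map_stats()] summary), `sdr`, `qc`, `groups` (framework marker ids
#'   per group), `genotypes` (final cleaned framework matrix in map order),
#'   `unlinked`, `unplaced`, `changes` (SMOOTH log of the final round),
#'   `mlod_threshold`, `seed`, `call`.
#' @seealso [simulate_slaf_population()], [call_genotypes()]
#' @examples
#' \donttest{
#' cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = c(80, 100),
#'                   markers_per_chrom = 12, offspring_depth_mean = 6,
#'                   polymorphic_fraction = 1, distortion_loci = list(),
#'                   seed = 7)
#' sim <- simulate_slaf_population(cfg)
#' gm <- call_genotypes(sim$counts_a, sim$counts_b)
#' fit <- fit_linkage_map(gm, seed = 7)
#' summary(fit)
#' }
#' @export
fit_linkage_map <- function(x, progeny_depth = NULL,
                            parent_depth = NULL, qc = qc_config(),
                            mlod_threshold = 5, rounds = 3L, cycles = 4L,
                            smooth_threshold = 0.001,
                            smooth_rise = sqrt(10),
                            smooth_threshold_max = 0.05, knn_k = 5L,
                            insert_accessory = TRUE, min_run = 3L,
                            max_adjacent_r = 0.49, seed = NULL) {
  cl <- match.call()
  lik <- NULL
  if (inherits(x, "genotype_matrix")) {
    genotypes <- x$genotypes
    lik <- x$likelihood
  } else genotypes <- x
  stopifnot(is.matrix(genotypes), rounds >= 1L)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("m%04d", seq_len(nrow(genotypes)))
    if (!is.null(lik)) dimnames(lik)[[1]] <- rownames(genotypes)
  }
  geno_work <- genotypes
  pdep <- progeny_depth; padep <- parent_depth
  rd <- NULL
  for (round_i in seq_len(rounds)) {
    final <- round_i == rounds
    rseed <- if (is.null(seed)) NULL else seed + 31L * (round_i - 1L)
    rd <- map_round(
      geno_work, lik, pdep, padep, qc,
      alpha = if (final) qc$alpha else min(qc$alpha / 50, 1e-3),
      mlod_threshold = mlod_threshold,
      group_threshold = mlod_threshold, cycles = cycles,
      smooth_threshold = smooth_threshold, smooth_rise = smooth_rise,
      smooth_threshold_max = smooth_threshold_max, knn_k = knn_k,
      insert_accessory = insert_accessory,
      max_adjacent_r = max_adjacent_r,
      grid_points = if (final) 9L else 5L,
      refine_ml = final, seed = rseed)
    if (!final) {
      cleaned <- corrected_matrix(rd, lik, knn_k, smooth_threshold,
                                  smooth_rise, smooth_threshold_max)
      # dropped markers (unlinked/unplaced) get another chance next round
      left_out <- setdiff(rownames(geno_work), rownames(cleaned))
      geno_work <- rbind(cleaned, geno_work[left_out, , drop = FALSE])
      pdep <- NULL; padep <- NULL    # depth filters apply to raw data only
    }
  }

  map <- do.call(rbind, rd$ext_maps)
  unplaced <- c(rd$unplaced, map$marker_id[!map$placed])
  map <- map[map$placed, c("marker_id", "lg", "position_cM", "accessory")]
  map$distorted <- map$accessory
  rownames(map) <- NULL
  stats_ <- map_stats(map)
  sdr <- detect_sdr(map, min_run = min_run)
  structure(list(
    map = map, stats = stats_, sdr = sdr, qc = rd$qc_res,
    groups = lapply(rd$group_fits,
                    function(gf) rownames(rd$fw)[gf$marker_idx]),
    group_sarf = vapply(rd$group_fits, `[[`, numeric(1), "sarf"),
    genotypes = do.call(rbind, lapply(rd$group_fits, `[[`, "genotypes")),
    unlinked = rd$unlinked,
    unplaced = unplaced,
    changes = do.call(rbind, lapply(rd$group_fits, `[[`, "changes")),
    mlod_threshold = mlod_threshold, seed = seed, call = cl),
    class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  ov <- x$stats$overall
  cat("F2 linkage map\n")
  cat(sprintf("  %d markers in %d linkage groups, %.1f cM total\n",
              ov$n_markers, ov$n_lg, ov$total_cM))
  cat(sprintf("  %d accessory (distorted) markers, %d SDRs\n",
              sum(x$map$accessory), nrow(x$sdr)))
  if (length(x$unlinked) || length(x$unplaced))
    cat(sprintf("  %d unlinked, %d unplaced markers\n",
                length(x$unlinked), length(x$unplaced)))
  invisible(x)
}

#' @export
summary.linkage_map <- function(object, ...) {
  structure(list(per_lg = object$stats$per_lg,
                 overall = object$stats$overall,
                 sdr = object$sdr,
                 qc_verdicts = table(object$qc$table$verdict)),
            class = "summary.linkage_map")
}

#' @export
print.summary.linkage_map <- function(x, ...) {
  cat("Per-group map statistics:\n")
  print(x$per_lg, row.names = FALSE)
  cat("\nOverall:\n")
  print(x$overall, row.names = FALSE)
  cat("\nQC verdicts:\n")
  print(x$qc_verdicts)
  cat(sprintf("\n%d segregation distortion regions\n", nrow(x$sdr)))
  invisible(x)
}

#' Plot a linkage map
#'
#' Draws each linkage group as a vertical bar with one tick per marker;
#' distorted (accessory) markers are highlighted.
#'
#' @param x a `"linkage_map"`.
#' @param accessory_col tick colour for accessory markers.
#' @param ... passed to [graphics::plot()].
#' @export
plot.linkage_map <- function(x, accessory_col = "forestgreen", ...) {
  map <- x$map
  lgs <- sort(unique(map$lg))
  ymax <- max(map$position_cM)
  graphics::plot(NA, xlim = c(0.5, length(lgs) + 0.5), ylim = c(ymax, 0),
                 xlab = "Linkage group", ylab = "Position (cM)",
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_along(lgs), labels = lgs)
  for (i in seq_along(lgs)) {
    d <- map[map$lg == lgs[i], ]
    graphics::segments(i - 0.18, min(d$position_cM),
                       i - 0.18, max(d$position_cM), lwd = 3,
                       col = "grey60")
    graphics::segments(i - 0.28, d$position_cM, i - 0.08, d$position_cM,
                       col = ifelse(d$accessory, accessory_col, "black"))
  }
  invisible(x)
}
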