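# Synthetic SLAF-seq F2 data: meiosis simulation with optional gamete-viability
# segregation distortion, then a read-count layer with Poisson depth and
# per-read sequencing error.  Ground truth is retained for recovery testing.

#' Configuration for a synthetic SLAF-seq F2 experiment
#'
#' Defaults emulate the design of a high-density sorghum F2 study: two fully
#' homozygous parents, 130 selfed-F1 offspring, 10 chromosomes with map
#' lengths between 132.8 and 300.4 cM, parent sequencing depths of 12.9x and
#' 16.8x, offspring depth 2.8x, a 12% polymorphism rate among loci, and
#' segregation distortion produced by gamete-viability selection at a small
#' number of chromosomal loci.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_lengths_cM map length of each chromosome in centimorgans.
#' @param markers_per_chrom number of simulated loci per chromosome
#'   (recycled to `n_chromosomes`).
#' @param n_individuals number of F2 offspring.
#' @param parent_depth_mean mean fold-coverage of the two parents
#'   (length 1 or 2; maternal, paternal).
#' @param offspring_depth_mean mean fold-coverage per offspring.
#' @param depth_dispersion if non-`NULL`, read depths are negative binomial
#'   with this `size` parameter instead of Poisson.
#' @param seq_error_rate probability that a read reports the wrong allele.
#' @param missing_extra_rate probability that a sequenced genotype is masked
#'   (counts zeroed) on top of depth-0 missingness.
#' @param distortion_loci list of distortion loci, each a list with elements
#'   `chrom` (index), `pos_cM`, `s` (selection coefficient in \[0,1\]) and
#'   `allele` (`"a"` or `"b"`, the favoured allele).  Defaults place the
#'   loci near chromosome ends, where segregation distortion regions
#'   cluster in real biparental maps.
#' @param distortion_mechanism `"gametic"` (gametes carrying the disfavoured
#'   allele are rejected with probability `s` and redrawn) or `"zygotic"`
#'   (zygote viability `(1-s)^k` with `k` disfavoured alleles carried).
#' @param polymorphic_fraction probability that a locus differs between the
#'   parents.
#' @param marker_placement `"uniform"` (sorted uniform positions) or
#'   `"even"` (equally spaced).
#' @param tag_length length in bp of the simulated SLAF tag sequences.
#' @param transition_fraction probability that a simulated SNP is a
#'   transition (R or Y type) rather than a transversion.
#' @param class_probs probabilities that a polymorphic locus carries SNPs
#'   only, an InDel only, or both (named or in that order).
#' @param seed integer seed; fixed seed reproduces the dataset exactly.
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [simulate_meioses()], [simulate_reads()],
#'   [simulate_slaf_population()]
#' @export
sim_config <- function(n_chromosomes = 10,
                       chrom_lengths_cM = c(238.7, 287.9, 286.7, 300.4, 183.7,
                                            175.0, 266.3, 134.6, 152.2, 132.8),
                       markers_per_chrom = c(200, 292, 250, 315, 218,
                                             216, 217, 189, 123, 226),
                       n_individuals = 130,
                       parent_depth_mean = c(12.9, 16.8),
                       offspring_depth_mean = 2.8,
                       depth_dispersion = NULL,
                       seq_error_rate = 0.01,
                       missing_extra_rate = 0.05,
                       distortion_loci = list(
                         list(chrom = 2, pos_cM = 5, s = 0.8, allele = "a"),
                         list(chrom = 7, pos_cM = 260, s = 0.8, allele = "b")),
                       distortion_mechanism = c("gametic", "zygotic"),
                       polymorphic_fraction = 0.12,
                       marker_placement = c("uniform", "even"),
                       tag_length = 100,
                       transition_fraction = 0.655,
                       class_probs = c(SNP_only = 2237, InDel_only = 3,
                                       SNP_InDel = 6) / 2246,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_cM = rep_len(as.numeric(chrom_lengths_cM), n_chromosomes),
    markers_per_chrom = rep_len(as.integer(markers_per_chrom), n_chromosomes),
    n_individuals = as.integer(n_individuals),
    parent_depth_mean = rep_len(as.numeric(parent_depth_mean), 2L),
    offspring_depth_mean = as.numeric(offspring_depth_mean),
    depth_dispersion = depth_dispersion,
    seq_error_rate = as.numeric(seq_error_rate),
    missing_extra_rate = as.numeric(missing_extra_rate),
    distortion_loci = distortion_loci,
    distortion_mechanism = match.arg(distortion_mechanism),
    polymorphic_fraction = as.numeric(polymorphic_fraction),
    marker_placement = match.arg(marker_placement),
    tag_length = as.integer(tag_length),
    transition_fraction = as.numeric(transition_fraction),
    class_probs = as.numeric(class_probs) / sum(class_probs),
    seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  if (any(!is.finite(cfg$chrom_lengths_cM)) || any(cfg$chrom_lengths_cM < 0))
    stop("chromosome lengths must be finite and non-negative")
  if (any(cfg$markers_per_chrom < 1L)) stop("need >= 1 marker per chromosome")
  if (cfg$n_individuals < 1L) stop("need >= 1 individual")
  if (any(cfg$parent_depth_mean < 0) || cfg$offspring_depth_mean < 0)
    stop("depths must be non-negative")
  stop_if_not_prob(cfg$seq_error_rate, "seq_error_rate")
  stop_if_not_prob(cfg$missing_extra_rate, "missing_extra_rate")
  stop_if_not_prob(cfg$polymorphic_fraction, "polymorphic_fraction")
  stop_if_not_prob(cfg$transition_fraction, "transition_fraction")
  for (d in cfg$distortion_loci) {
    if (!is.finite(d$s) || d$s < 0 || d$s > 1)
      stop("distortion selection coefficient s must be in [0, 1]")
    if (!d$allele %in% c("a", "b")) stop("distortion allele must be 'a' or 'b'")
    if (d$chrom < 1 || d$chrom > cfg$n_chromosomes)
      stop("distortion locus on nonexistent chromosome")
  }
  invisible(cfg)
}

# One gamete from an F1 meiosis on a single chromosome: allele (0 = a, 1 = b)
# at each requested cM position.  Crossovers are Poisson(length in Morgans)
# with uniform positions, i.e. no interference.
draw_gamete <- function(pos_cM, length_cM) {
  n_co <- stats::rpois(1L, length_cM / 100)
  phase <- stats::rbinom(1L, 1L, 0.5)
  if (n_co == 0L) return(rep.int(phase, length(pos_cM)))
  co <- sort(stats::runif(n_co, 0, length_cM))
  (phase + findInterval(pos_cM, co)) %% 2L
}

#' Simulate F2 meioses and true genotypes
#'
#' Each F2 individual is formed from two independent F1 gametes per
#' chromosome.  Crossover counts are Poisson in the map length (Morgans)
#' with uniform positions (Haldane model, no interference).  Under gametic
#' distortion, a gamete carrying the disfavoured allele at a distortion
#' locus is rejected with probability `s` and redrawn; under zygotic
#' distortion whole zygotes are rejected with viability `(1-s)^k`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `"truth_set"`: a list with `positions`
#'   (data.frame `marker_id`, `chrom`, `cM`, `polymorphic`), `genotypes`
#'   (polymorphism-agnostic markers x individuals integer matrix, 0/1/2
#'   counting `b` alleles), `distortion_loci` and `config`.
#' @export
simulate_meioses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_ind <- config$n_individuals
    pos_list <- vector("list", config$n_chromosomes)
    geno_list <- vector("list", config$n_chromosomes)
    for (ch in seq_len(config$n_chromosomes)) {
      L <- config$chrom_lengths_cM[ch]
      m <- config$markers_per_chrom[ch]
      pos <- if (config$marker_placement == "even") {
        if (m == 1L) L / 2 else seq(0, L, length.out = m)
      } else sort(stats::runif(m, 0, L))
      d_here <- Filter(function(d) d$chrom == ch, config$distortion_loci)
      d_pos <- vapply(d_here, `[[`, numeric(1), "pos_cM")
      d_s <- vapply(d_here, `[[`, numeric(1), "s")
      d_fav <- as.integer(vapply(d_here, `[[`, character(1), "allele") == "b")
      all_pos <- c(pos, d_pos)
      g <- matrix(0L, m, n_ind)
      zygotic_sel <- config$distortion_mechanism == "zygotic" &&
        length(d_here) > 0L
      for (i in seq_len(n_ind)) {
        repeat {
          gam <- make_selected_gametes(all_pos, L, d_pos, d_s, d_fav,
                                       config$distortion_mechanism)
          if (!zygotic_sel) break
          zg <- gam[[1]][m + seq_along(d_pos)] + gam[[2]][m + seq_along(d_pos)]
          k <- ifelse(d_fav == 1L, 2L - zg, zg)  # disfavoured alleles carried
          if (stats::runif(1) <= prod((1 - d_s)^k)) break
        }
        g[, i] <- gam[[1]][seq_len(m)] + gam[[2]][seq_len(m)]
      }
      pos_list[[ch]] <- data.frame(
        marker_id = sprintf("c%02d_m%03d", ch, seq_len(m)),
        chrom = ch, cM = pos, stringsAsFactors = FALSE)
      geno_list[[ch]] <- g
    }
    positions <- do.call(rbind, pos_list)
    positions$polymorphic <-
      stats::runif(nrow(positions)) < config$polymorphic_fraction
    genotypes <- do.call(rbind, geno_list)
    dimnames(genotypes) <- list(positions$marker_id,
                                sprintf("ind%03d", seq_len(n_ind)))
    structure(list(positions = positions, genotypes = genotypes,
                   distortion_loci = config$distortion_loci, config = config),
              class = "truth_set")
  })
}

# Draw the two gametes of one individual on one chromosome, applying gametic
# viability selection (rejection sampling) when requested.
make_selected_gametes <- function(all_pos, L, d_pos, d_s, d_fav, mechanism) {
  nd <- length(d_pos)
  m <- length(all_pos) - nd
  draw_one <- function() {
    if (mechanism != "gametic" || nd == 0L) return(draw_gamete(all_pos, L))
    for (it in seq_len(100000L)) {
      gam <- draw_gamete(all_pos, L)
      carried <- gam[m + seq_len(nd)]
      keep_p <- prod(ifelse(carried == d_fav, 1, 1 - d_s))
      if (keep_p == 1 || stats::runif(1) <= keep_p) return(gam)
    }
    stop("gamete rejection sampling failed to accept (s too close to 1?)")
  }
  list(draw_one(), draw_one())
}

DNA <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

random_tag <- function(len) paste(sample(DNA, len, replace = TRUE),
                                  collapse = "")

# Mutate a tag into the second allele: n_snp substitutions with the given
# transition probability, plus optionally a short deletion (InDel classes).
mutate_tag <- function(tag, n_snp, ts_frac, with_indel) {
  s <- strsplit(tag, "")[[1]]
  if (n_snp > 0L) {
    at <- sample(length(s), n_snp)
    for (i in at) {
      s[i] <- if (stats::runif(1) < ts_frac) TRANSITION[[s[i]]]
              else sample(setdiff(DNA, c(s[i], TRANSITION[[s[i]]])), 1L)
    }
  }
  if (with_indel) {
    del_len <- sample(1:2, 1L)
    # keep the deletion away from the ends so prefix/suffix anchoring works
    start <- sample(seq(5L, length(s) - 5L - del_len), 1L)
    s <- s[-(start:(start + del_len - 1L))]
  }
  paste(s, collapse = "")
}

#' Simulate SLAF read counts from a set of true genotypes
#'
#' Lays a sequencing layer over a [simulate_meioses()] truth set.  Read depth
#' per marker and sample is Poisson (or negative binomial) around the
#' configured means; each read reports the true allele with probability
#' `1 - seq_error_rate`, otherwise the other allele; heterozygotes draw each
#' read from either allele with probability 1/2.  Depth 0 means missing, and
#' an additional masking rate zeroes further entries.  Tag sequences for the
#' two alleles of each polymorphic locus are generated with configurable
#' transition fraction and rare InDel classes.
#'
#' @param truth a `"truth_set"` from [simulate_meioses()].
#' @param config the same [sim_config()]; reads are drawn from a stream
#'   seeded at `config$seed + 1`.
#' @return an object of class `"slaf_sim"`: list with `loci` (data.frame of
#'   `locus_id`, `chrom`, `cM`, `polymorphic`, `allele_a`, `allele_b`),
#'   `counts_a`, `counts_b` (markers x individuals integer matrices),
#'   `parent_counts_a`, `parent_counts_b` (markers x 2), plus the `truth`
#'   and `config`.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  seed2 <- if (is.null(config$seed)) NULL else config$seed + 1L
  with_seed(seed2, {
    pos <- truth$positions
    m <- nrow(pos)
    n <- ncol(truth$genotypes)
    rdepth <- function(k, mu) {
      if (is.null(config$depth_dispersion)) stats::rpois(k, mu)
      else stats::rnbinom(k, size = config$depth_dispersion, mu = mu)
    }
    eps <- config$seq_error_rate
    g <- truth$genotypes
    depth <- matrix(rdepth(m * n, config$offspring_depth_mean), m, n)
    masked <- matrix(stats::runif(m * n) < config$missing_extra_rate, m, n)
    depth[masked] <- 0L
    # P(read reports allele b | genotype)
    pb <- matrix(c(eps, 0.5, 1 - eps)[g + 1L], m, n)
    counts_b <- matrix(stats::rbinom(m * n, depth, pb), m, n)
    counts_a <- depth - counts_b
    counts_b[!pos$polymorphic, ] <- 0L              # monomorphic: single tag
    counts_a[!pos$polymorphic, ] <- depth[!pos$polymorphic, ]
    dimnames(counts_a) <- dimnames(counts_b) <- dimnames(g)

    pdep <- cbind(rdepth(m, config$parent_depth_mean[1]),
                  rdepth(m, config$parent_depth_mean[2]))
    # parent 1 is aa everywhere, parent 2 bb at polymorphic loci
    p1_b <- stats::rbinom(m, pdep[, 1], eps)
    p2_b <- stats::rbinom(m, pdep[, 2], ifelse(pos$polymorphic, 1 - eps, eps))
    parent_counts_b <- cbind(P1 = p1_b, P2 = p2_b)
    parent_counts_a <- pdep - parent_counts_b
    rownames(parent_counts_a) <- rownames(parent_counts_b) <- pos$marker_id

    allele_a <- vapply(seq_len(m), function(i) random_tag(config$tag_length),
                       character(1))
    cls <- sample(c("SNP_only", "InDel_only", "SNP_InDel"), m, replace = TRUE,
                  prob = config$class_probs)
    n_snp <- ifelse(cls == "InDel_only", 0L,
                    sample(1:3, m, replace = TRUE, prob = c(0.80, 0.15, 0.05)))
    allele_b <- allele_a
    for (i in which(pos$polymorphic)) {
      allele_b[i] <- mutate_tag(allele_a[i], n_snp[i],
                                config$transition_fraction,
                                cls[i] != "SNP_only")
    }
    loci <- data.frame(locus_id = pos$marker_id, chrom = pos$chrom,
                       cM = pos$cM, polymorphic = pos$polymorphic,
                       allele_a = allele_a,
                       allele_b = ifelse(pos$polymorphic, allele_b, NA),
                       stringsAsFactors = FALSE)
    structure(list(loci = loci, counts_a = counts_a, counts_b = counts_b,
                   parent_counts_a = parent_counts_a,
                   parent_counts_b = parent_counts_b,
                   truth = truth, config = config),
              class = "slaf_sim")
  })
}

#' Simulate a complete synthetic SLAF-seq F2 dataset
#'
#' Convenience wrapper: [simulate_meioses()] followed by [simulate_reads()].
#'
#' @inheritParams simulate_reads
#' @param config a [sim_config()].
#' @return a `"slaf_sim"` object (see [simulate_reads()]).
#' @export
simulate_slaf_population <- function(config = sim_config()) {
  simulate_reads(simulate_meioses(config), config)
}

#' Write simulator outputs as tab-delimited text
#'
#' Emits the allele-count table (long format: marker, individual, countA,
#' countB), the true map, the true genotype matrix and a config echo.
#'
#' @param sim a `"slaf_sim"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_files <- function(sim, dir) {
  stopifnot(inherits(sim, "slaf_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("allele_counts.tsv", "true_map.tsv",
                            "true_genotypes.tsv", "config_echo.tsv"))
  long <- data.frame(
    marker_id = rep(rownames(sim$counts_a), ncol(sim$counts_a)),
    individual_id = rep(colnames(sim$counts_a), each = nrow(sim$counts_a)),
    countA = as.vector(sim$counts_a), countB = as.vector(sim$counts_b))
  utils::write.table(long, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$positions, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geno_to_char(sim$truth$genotypes), paths[3], sep = "\t",
                     quote = FALSE, col.names = NA)
  cfg <- sim$config
  simple <- vapply(cfg, function(x) is.atomic(x) || is.null(x), logical(1))
  echo <- data.frame(
    key = names(cfg)[simple],
    value = vapply(cfg[simple], function(x)
      paste(format(x, trim = TRUE), collapse = ","), character(1)))
  utils::write.table(echo, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
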