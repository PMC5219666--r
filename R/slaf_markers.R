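# SLAF locus identification and marker classification: identity clustering of
# tags, minor-allele-frequency allele definition, locus status filters,
# segregation patterns and SNP/InDel typing.

#' Cluster equal-length tag sequences into SLAF loci
#'
#' Single-linkage grouping: two tags link when their fraction of matching
#' positions exceeds `identity_threshold`; loci are the transitive closures.
#' This is a deliberate simplification of similarity-search clustering
#' (tags from one reduced-representation locus are fixed-length fragments),
#' and it requires all tags to have equal length.
#'
#' @param tag_sequences character vector of equal-length A/C/G/T sequences.
#' @param identity_threshold minimum (exclusive) fraction of identical
#'   positions for two tags to share a locus; default 0.95.
#' @return integer vector of locus ids (1-based, in order of first
#'   appearance), one per input tag.
#' @examples
#' cluster_tags(c("AAAA", "AAAA", "TTTT"))  # 1 1 2
#' @export
cluster_tags <- function(tag_sequences, identity_threshold = 0.95) {
  n <- length(tag_sequences)
  if (n == 0L) return(integer(0))
  lens <- nchar(tag_sequences)
  if (length(unique(lens)) != 1L)
    stop("all tag sequences must have equal length for identity clustering")
  if (any(grepl("[^ACGT]", tag_sequences)))
    stop("tag sequences must be over the A/C/G/T alphabet")
  L <- lens[1]
  chars <- matrix(unlist(strsplit(tag_sequences, "")), nrow = L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ident <- sum(chars[, i] == chars[, j]) / L
      if (ident > identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Define the two alleles of a SLAF locus by minor-allele frequency
#'
#' The two tags with the highest aggregate read counts become alleles A and
#' B (A = the more frequent); the minor allele frequency is the minor count
#' over the total across all tags at the locus.  Ties are broken
#' lexicographically by tag sequence for determinism.
#'
#' @param counts named numeric vector of aggregate read counts per tag
#'   (names are tag sequences).
#' @return a list with `alleles` (character length 2, or `NULL` if
#'   monomorphic), `maf` (minor allele frequency, `NA` if monomorphic) and
#'   `monomorphic` (logical).
#' @examples
#' define_alleles(c(T1 = 90, T2 = 60))  # alleles T1,T2; MAF 0.4
#' @export
define_alleles <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be named by tag sequence")
  if (length(counts) < 2L)
    return(list(alleles = NULL, maf = NA_real_, monomorphic = TRUE))
  ord <- order(-counts, names(counts))
  top2 <- names(counts)[ord[1:2]]
  maf <- counts[[ord[2]]] / sum(counts)
  list(alleles = top2, maf = maf, monomorphic = FALSE)
}

#' Classify a SLAF locus status
#'
#' Applies the locus-level filters in order: more than 4 distinct tags is
#' repetitive; more than 3 SNPs between the parental alleles is filtered;
#' mean sequence depth below `low_depth_threshold` (default 2.20, taken as
#' the mean across sequenced samples) is low-depth; 2--4 tags with
#' differing parents is polymorphic; otherwise non-polymorphic.
#'
#' @param n_distinct_tags number of distinct tags in the cluster.
#' @param n_snps_between_parents SNP count between the parental alleles.
#' @param mean_depth mean read depth across sequenced samples.
#' @param parents_differ do the two parents carry different alleles?
#' @param low_depth_threshold depth cutoff (default 2.20).
#' @param max_tags repetitive-locus tag cutoff (default 4).
#' @param max_snps SNP-excess cutoff (default 3).
#' @return one of `"repetitive"`, `"filtered_snp_excess"`, `"low_depth"`,
#'   `"polymorphic"`, `"non_polymorphic"`.
#' @export
classify_locus <- function(n_distinct_tags, n_snps_between_parents,
                           mean_depth, parents_differ,
                           low_depth_threshold = 2.20,
                           max_tags = 4L, max_snps = 3L) {
  stopifnot(n_distinct_tags >= 1L)
  if (n_distinct_tags > max_tags) return("repetitive")
  if (!is.na(n_snps_between_parents) && n_snps_between_parents > max_snps)
    return("filtered_snp_excess")
  if (is.finite(mean_depth) && mean_depth < low_depth_threshold)
    return("low_depth")
  if (n_distinct_tags >= 2L && isTRUE(parents_differ)) return("polymorphic")
  "non_polymorphic"
}

SEG_PATTERNS <- c("ab x cd", "ef x eg", "hk x hk", "lm x ll",
                  "nn x np", "aa x bb", "ab x cc", "cc x ab")

# Needleman-Wunsch global alignment of two character vectors; returns the
# aligned sequences with NA at gap positions.
nw_align <- function(a, b, mismatch = 1, gap = 1.2) {
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1L, m + 1L)
  sc[, 1] <- (0:n) * gap
  sc[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    sub <- sc[i, 1:m] + ifelse(a[i] == b, 0, mismatch)
    row <- numeric(m)
    up <- sc[i, 2:(m + 1L)] + gap
    prev <- sc[i + 1L, 1L]
    for (j in seq_len(m)) {
      prev <- min(sub[j], up[j], prev + gap)
      row[j] <- prev
    }
    sc[i + 1L, 2:(m + 1L)] <- row
  }
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        sc[i + 1L, j + 1L] ==
          sc[i, j] + (if (a[i] == b[j]) 0 else mismatch)) {
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && sc[i + 1L, j + 1L] == sc[i, j + 1L] + gap) {
      out_a <- c(a[i], out_a); out_b <- c(NA, out_b)
      i <- i - 1L
    } else {
      out_a <- c(NA, out_a); out_b <- c(b[j], out_b)
      j <- j - 1L
    }
  }
  list(a = out_a, b = out_b)
}

#' Classify the segregation pattern of a marker from the parental genotypes
#'
#' Parental genotypes are given as length-2 character vectors of allele
#' labels (e.g. `c("A","A")` for a homozygote).  The eight possible
#' patterns of a cross between (possibly heterozygous) parents are
#' `ab x cd`, `ef x eg`, `hk x hk`, `lm x ll`, `nn x np`, `aa x bb`,
#' `ab x cc` and `cc x ab`.  Only `aa x bb` (both parents homozygous for
#' different alleles) is fully informative in an F2 from homozygous
#' parents and used for map construction.
#'
#' @param maternal,paternal character vectors of length 2 (the two allele
#'   labels carried by each parent), or `NA` if the parent is uncallable.
#' @return the pattern string, or `"undetermined"` if a parent is
#'   uncallable.
#' @examples
#' classify_segregation_pattern(c("A", "A"), c("B", "B"))  # "aa x bb"
#' @export
classify_segregation_pattern <- function(maternal, paternal) {
  if (anyNA(maternal) || anyNA(paternal)) return("undetermined")
  m <- sort(as.character(maternal)); p <- sort(as.character(paternal))
  m_het <- m[1] != m[2]; p_het <- p[1] != p[2]
  shared <- intersect(m, p)
  if (m_het && p_het) {
    if (identical(m, p)) return("hk x hk")              # ab x ab
    if (length(shared) == 1L) return("ef x eg")          # one shared allele
    return("ab x cd")                                    # four alleles
  }
  if (m_het && !p_het) {
    if (p[1] %in% m) return("lm x ll")                   # het x hom, shared
    return("ab x cc")                                    # het x hom, distinct
  }
  if (!m_het && p_het) {
    if (m[1] %in% p) return("nn x np")
    return("cc x ab")
  }
  if (m[1] == p[1]) return("undetermined")               # identical homozygotes
  "aa x bb"
}

IUPAC_SNP <- c("AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
               "GT" = "K", "AC" = "M")

#' Classify the variant carried by a pair of parental alleles
#'
#' Substitutions are typed by the IUPAC ambiguity code of the unordered
#' base pair (R = G/A, Y = T/C, S = G/C, W = A/T, K = G/T, M = A/C);
#' length-changing differences are InDels.  Alleles of unequal length are
#' anchored by their longest common prefix and suffix, so a single
#' contiguous InDel is recognised alongside flanking substitutions.
#'
#' @param allele_a,allele_b allele sequences (A/C/G/T).
#' @return a list with `variant_class` (`"SNP_only"`, `"InDel_only"`,
#'   `"SNP_InDel"` or `"identical"`), `snp_types` (character vector, one
#'   IUPAC code per substitution) and `n_snps`.
#' @examples
#' classify_variant("ACGT", "ACAT")  # SNP_only, type R (G/A)
#' @export
classify_variant <- function(allele_a, allele_b) {
  if (grepl("[^ACGT]", allele_a) || grepl("[^ACGT]", allele_b))
    stop("alleles must be over the A/C/G/T alphabet")
  a <- strsplit(allele_a, "")[[1]]
  b <- strsplit(allele_b, "")[[1]]
  has_indel <- length(a) != length(b)
  if (has_indel) {
    # global alignment (match 0, mismatch 1, gap 1.2) so substitutions
    # flanking the InDel are still recognised; gapped columns are removed
    # and the remaining aligned columns compared as usual
    al <- nw_align(a, b)
    keep <- !is.na(al$a) & !is.na(al$b)
    a <- al$a[keep]; b <- al$b[keep]
  }
  mism <- which(a != b)
  snp_types <- vapply(mism, function(i) {
    key <- paste(sort(c(a[i], b[i])), collapse = "")
    IUPAC_SNP[[key]]
  }, character(1))
  n_snps <- length(snp_types)
  cls <- if (has_indel && n_snps > 0L) "SNP_InDel"
         else if (has_indel) "InDel_only"
         else if (n_snps > 0L) "SNP_only"
         else "identical"
  list(variant_class = cls, snp_types = snp_types, n_snps = n_snps)
}

#' Build a marker table from simulated loci
#'
#' Applies [classify_locus()], [classify_segregation_pattern()] and
#' [classify_variant()] across a simulated dataset, producing the marker
#' table consumed by genotype calling (only `aa x bb` markers of status
#' `polymorphic` are map-eligible in an F2 from homozygous parents).
#'
#' @param sim a `"slaf_sim"` object from [simulate_slaf_population()].
#' @param low_depth_threshold see [classify_locus()].
#' @return data.frame with one row per locus: `marker_id`, `status`,
#'   `pattern`, `variant_class`, `snp_types` (comma-collapsed), `n_snps`,
#'   `map_eligible`.
#' @export
identify_markers <- function(sim, low_depth_threshold = 2.20) {
  stopifnot(inherits(sim, "slaf_sim"))
  loci <- sim$loci
  depth <- sim$counts_a + sim$counts_b
  pdepth <- sim$parent_counts_a + sim$parent_counts_b
  mean_depth <- rowMeans(cbind(depth, pdepth))
  out <- lapply(seq_len(nrow(loci)), function(i) {
    poly <- loci$polymorphic[i]
    if (poly) {
      v <- classify_variant(loci$allele_a[i], loci$allele_b[i])
      pattern <- classify_segregation_pattern(c("a", "a"), c("b", "b"))
    } else {
      v <- list(variant_class = "identical", snp_types = character(0),
                n_snps = 0L)
      pattern <- "undetermined"
    }
    status <- classify_locus(
      n_distinct_tags = if (poly) 2L else 1L,
      n_snps_between_parents = v$n_snps,
      mean_depth = mean_depth[i], parents_differ = poly,
      low_depth_threshold = low_depth_threshold)
    data.frame(marker_id = loci$locus_id[i], status = status,
               pattern = pattern, variant_class = v$variant_class,
               snp_types = paste(v$snp_types, collapse = ","),
               n_snps = v$n_snps,
               map_eligible = status == "polymorphic" && pattern == "aa x bb",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
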