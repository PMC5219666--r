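# Marker-level QC: depth and missingness filters and the 1:2:1 chi-square
# segregation test splitting framework from accessory (distorted) markers.

#' Chi-square test of the F2 Mendelian 1:2:1 segregation ratio
#'
#' Expected counts are (n/4, n/2, n/4); the statistic is the usual
#' Pearson sum over the three genotype classes without continuity
#' correction, referred to a chi-square distribution with 2 degrees of
#' freedom.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts (vectorised).
#' @return data.frame with `chi2`, `df` (2) and `p_value`; `NA` where the
#'   total count is zero.
#' @examples
#' chi_square_121(25, 50, 25)  # chi2 = 0, p = 1
#' @export
chi_square_121 <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  e_aa <- n / 4; e_ab <- n / 2
  chi2 <- (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
    (n_bb - e_aa)^2 / e_aa
  chi2[n == 0] <- NA_real_
  data.frame(chi2 = chi2, df = 2L,
             p_value = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Marker QC configuration
#'
#' @param parent_depth_min minimum mean parental fold-coverage (exclusive);
#'   default 29.
#' @param progeny_depth_min minimum mean progeny fold-coverage (exclusive);
#'   default 3.
#' @param missing_max maximum tolerated missing fraction; default 0.30.
#' @param alpha significance level of the segregation chi-square test;
#'   default 0.05 (no multiple-testing correction, by design).
#' @return a list of class `"qc_config"`.
#' @export
qc_config <- function(parent_depth_min = 29, progeny_depth_min = 3,
                      missing_max = 0.30, alpha = 0.05) {
  stop_if_not_prob(missing_max, "missing_max")
  stop_if_not_prob(alpha, "alpha")
  structure(list(parent_depth_min = parent_depth_min,
                 progeny_depth_min = progeny_depth_min,
                 missing_max = missing_max, alpha = alpha),
            class = "qc_config")
}

#' Apply marker-level filters and the segregation test
#'
#' Filters are applied in order depth, then missingness, then the 1:2:1
#' chi-square test: markers failing depth thresholds (mean parental depth
#' must exceed `parent_depth_min`, mean progeny depth `progeny_depth_min`)
#' are `filtered_depth`; markers with more than `missing_max` missing calls
#' are `filtered_missing`; markers rejecting the 1:2:1 test at `alpha`
#' become `accessory_distorted` (set aside and re-inserted after framework
#' mapping); the remainder are `framework`.
#'
#' @param genotypes markers x individuals matrix (0/1/2/NA).
#' @param progeny_depth markers x individuals depth matrix, or a
#'   per-marker vector of mean progeny depth (optional; depth filter
#'   skipped if `NULL`).
#' @param parent_depth per-marker vector (or markers x 2 matrix) of
#'   parental depth (optional).
#' @param config a [qc_config()].
#' @return a list of class `"qc_result"`: `table` (per-marker data.frame
#'   with depths, `missing_fraction`, `chi2`, `p_value`, `verdict`) and
#'   index vectors `framework`, `accessory`.
#' @export
apply_filters <- function(genotypes, progeny_depth = NULL,
                          parent_depth = NULL, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  m <- nrow(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("m%04d", seq_len(m))
  mean_prog <- if (is.null(progeny_depth)) rep(NA_real_, m)
               else if (is.matrix(progeny_depth)) rowMeans(progeny_depth)
               else as.numeric(progeny_depth)
  mean_par <- if (is.null(parent_depth)) rep(NA_real_, m)
              else if (is.matrix(parent_depth)) rowMeans(parent_depth)
              else as.numeric(parent_depth)
  missing_fraction <- rowMeans(is.na(genotypes))
  n_aa <- rowSums(genotypes == 0L, na.rm = TRUE)
  n_ab <- rowSums(genotypes == 1L, na.rm = TRUE)
  n_bb <- rowSums(genotypes == 2L, na.rm = TRUE)
  chi <- chi_square_121(n_aa, n_ab, n_bb)

  verdict <- rep("framework", m)
  fail_depth <- (!is.na(mean_par) & mean_par <= config$parent_depth_min) |
    (!is.na(mean_prog) & mean_prog <= config$progeny_depth_min)
  verdict[fail_depth] <- "filtered_depth"
  fail_missing <- verdict == "framework" &
    missing_fraction > config$missing_max
  verdict[fail_missing] <- "filtered_missing"
  distorted <- verdict == "framework" & !is.na(chi$p_value) &
    chi$p_value < config$alpha
  verdict[distorted] <- "accessory_distorted"
  verdict[verdict == "framework" & is.na(chi$p_value)] <- "filtered_missing"

  tab <- data.frame(marker_id = ids, mean_parent_depth = mean_par,
                    mean_progeny_depth = mean_prog,
                    missing_fraction = missing_fraction,
                    n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
                    chi2 = chi$chi2, p_value = chi$p_value,
                    verdict = verdict, stringsAsFactors = FALSE)
  if (!any(verdict %in% c("framework", "accessory_distorted")))
    stop("no markers survive QC: check depth/missingness thresholds")
  structure(list(table = tab,
                 framework = which(verdict == "framework"),
                 accessory = which(verdict == "accessory_distorted"),
                 config = config),
            class = "qc_result")
}
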