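# Map summary statistics, printed-table percentage arithmetic, segregation
# distortion region detection and file output.

#' Per-linkage-group and overall map statistics
#'
#' For each linkage group: marker count, total distance (last position),
#' average adjacent distance (total / (n - 1)), largest gap, and the
#' percentage of gaps at most 5 cM.  The overall row reports total markers,
#' summed distance, and unweighted means over the per-group values of the
#' remaining columns.  Rounding for reporting is half-up at 1 decimal
#' (distances, percents) and 2 decimals (average distances); the `raw`
#' component keeps full precision.
#'
#' @param map data.frame with columns `marker_id`, `lg`, `position_cM`
#'   (positions non-decreasing within each group).
#' @param gap_cutoff_cM gap-size cutoff for the percentage column
#'   (default 5).
#' @return list of class `"map_summary"` with `per_lg`, `overall` (rounded
#'   report tables) and `raw` (unrounded per-LG values).
#' @export
map_stats <- function(map, gap_cutoff_cM = 5) {
  stopifnot(all(c("marker_id", "lg", "position_cM") %in% names(map)))
  lgs <- split(map, map$lg)
  raw <- do.call(rbind, lapply(lgs, function(d) {
    pos <- sort(d$position_cM)
    n <- length(pos)
    if (n < 2L)
      return(data.frame(lg = d$lg[1], n_markers = n, total_cM = 0,
                        avg_cM = NA_real_, largest_gap_cM = NA_real_,
                        pct_gap_le = NA_real_))
    gaps <- diff(pos)
    data.frame(lg = d$lg[1], n_markers = n, total_cM = pos[n] - pos[1],
               avg_cM = (pos[n] - pos[1]) / (n - 1),
               largest_gap_cM = max(gaps),
               pct_gap_le = 100 * mean(gaps <= gap_cutoff_cM))
  }))
  rownames(raw) <- NULL
  overall <- data.frame(
    n_lg = nrow(raw),
    n_markers = sum(raw$n_markers),
    total_cM = sum(raw$total_cM),
    mean_markers = mean(raw$n_markers),
    mean_avg_cM = mean(raw$avg_cM, na.rm = TRUE),
    mean_largest_gap_cM = mean(raw$largest_gap_cM, na.rm = TRUE),
    mean_pct_gap_le = mean(raw$pct_gap_le, na.rm = TRUE))
  per_lg <- transform(raw,
                      total_cM = round_half_up(total_cM, 1),
                      avg_cM = round_half_up(avg_cM, 2),
                      largest_gap_cM = round_half_up(largest_gap_cM, 1),
                      pct_gap_le = round_half_up(pct_gap_le, 1))
  overall_r <- transform(overall,
                         total_cM = round_half_up(total_cM, 1),
                         mean_markers = round_half_up(mean_markers, 1),
                         mean_avg_cM = round_half_up(mean_avg_cM, 2),
                         mean_largest_gap_cM =
                           round_half_up(mean_largest_gap_cM, 1),
                         mean_pct_gap_le = round_half_up(mean_pct_gap_le, 1))
  structure(list(per_lg = per_lg, overall = overall_r, raw = raw),
            class = "map_summary")
}

#' Aggregate printed per-group map statistics
#'
#' Overall summary from an already-tabulated per-group table (as printed in
#' a map report): unweighted means of per-group average distance, largest
#' gap and gap percentage, mean marker count, and sums.  Used to reproduce
#' report-level arithmetic when only the per-group table is available.
#'
#' @param per_lg data.frame with columns `n_markers`, `total_cM`,
#'   `avg_cM`, `largest_gap_cM`, `pct_gap_le` (one row per group).
#' @return one-row data.frame of rounded overall statistics (half-up; 1
#'   decimal, 2 for `mean_avg_cM`).
#' @export
overall_map_summary <- function(per_lg) {
  data.frame(
    n_markers = sum(per_lg$n_markers),
    total_cM = round_half_up(sum(per_lg$total_cM), 1),
    mean_markers = round_half_up(mean(per_lg$n_markers), 1),
    mean_avg_cM = round_half_up(mean(per_lg$avg_cM), 2),
    mean_largest_gap_cM = round_half_up(mean(per_lg$largest_gap_cM), 1),
    mean_pct_gap_le = round_half_up(mean(per_lg$pct_gap_le), 1))
}

#' Percentages of counts over a whole, rounded half-up to one decimal
#'
#' `100 * part / whole`, the arithmetic behind marker-identification,
#' SNP-type and distortion report tables.
#'
#' @param part numeric vector of counts.
#' @param whole the denominator (scalar or vector).
#' @return percentages rounded half-up to 1 decimal; `NA` with a warning
#'   where the denominator is zero.
#' @examples
#' summary_ratios(6353, 52928)  # 12.0
#' @export
summary_ratios <- function(part, whole) {
  out <- 100 * part / whole
  if (any(whole == 0)) {
    warning("zero denominator in summary_ratios(); returning NA")
    out[whole == 0] <- NA_real_
  }
  round_half_up(out, 1)
}

#' Detect segregation distortion regions along a map
#'
#' An SDR is a maximal run of at least `min_run` consecutive
#' distortion-flagged markers along a linkage group.  The result is
#' invariant to reversing the orientation of a group.
#'
#' @param map data.frame with `marker_id`, `lg`, `position_cM` and a
#'   logical `distorted` column, ordered by position within group.
#' @param min_run minimum run length (default 3).
#' @return data.frame of class `"sdr_set"`: `lg`, `start_marker`,
#'   `end_marker`, `start_cM`, `end_cM`, `n_markers` (zero rows when there
#'   is no SDR).
#' @export
detect_sdr <- function(map, min_run = 3L) {
  stopifnot(all(c("lg", "marker_id", "position_cM", "distorted") %in%
                  names(map)), min_run >= 1L)
  res <- list()
  for (d in split(map, map$lg)) {
    d <- d[order(d$position_cM), , drop = FALSE]
    rl <- rle(as.logical(d$distorted))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- which(rl$values & rl$lengths >= min_run)
    for (k in keep) {
      res[[length(res) + 1L]] <- data.frame(
        lg = d$lg[1],
        start_marker = d$marker_id[starts[k]],
        end_marker = d$marker_id[ends[k]],
        start_cM = d$position_cM[starts[k]],
        end_cM = d$position_cM[ends[k]],
        n_markers = rl$lengths[k], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(lg = character(0), start_marker = character(0),
                         end_marker = character(0), start_cM = numeric(0),
                         end_cM = numeric(0), n_markers = integer(0),
                         stringsAsFactors = FALSE)
  class(out) <- c("sdr_set", "data.frame")
  out
}

#' Write the map and its summary tables as tab-delimited text
#'
#' Emits, deterministically for fixed input: the map file (`marker_id`,
#' `lg`, `position_cM`, `accessory`, `distorted`), the per-group summary
#' table, the SNP-type table, the distortion table and a run manifest
#' (key--value text).
#'
#' @param fit a `"linkage_map"` object from [fit_linkage_map()].
#' @param dir output directory.
#' @param snp_type_counts optional named counts over the six SNP types.
#' @return invisibly, the paths written.
#' @export
write_map_outputs <- function(fit, dir, snp_type_counts = NULL) {
  stopifnot(inherits(fit, "linkage_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  paths <- c(
    wt(fit$map, "map.tsv"),
    wt(fit$stats$per_lg, "map_summary.tsv"),
    wt(fit$sdr, "sdr.tsv"))
  if (!is.null(snp_type_counts)) {
    snp_tab <- data.frame(snp_type = names(snp_type_counts),
                          n = as.integer(snp_type_counts),
                          pct = summary_ratios(as.numeric(snp_type_counts),
                                               sum(snp_type_counts)))
    paths <- c(paths, wt(snp_tab, "snp_types.tsv"))
  }
  dist_by_lg <- stats::aggregate(distorted ~ lg, data = fit$map, FUN = sum)
  tot_by_lg <- stats::aggregate(marker_id ~ lg, data = fit$map, FUN = length)
  dt <- merge(tot_by_lg, dist_by_lg, by = "lg")
  names(dt) <- c("lg", "n_markers", "n_distorted")
  dt$pct_distorted_on_lg <- summary_ratios(dt$n_distorted, dt$n_markers)
  paths <- c(paths, wt(dt, "distortion_summary.tsv"))
  manifest <- c(
    package = "slafmap",
    version = as.character(utils::packageVersion("slafmap")),
    seed = as.character(fit$seed %||% NA),
    n_markers = nrow(fit$map),
    n_groups = length(unique(fit$map$lg)),
    mlod_threshold = fit$mlod_threshold)
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(c(paths, file.path(dir, "manifest.tsv")))
}
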