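#' Single-copy-gene quality estimate of a partition
#'
#' For each bin, completeness is estimated as the percentage of the marker
#' universe present at least once, and contamination as the percentage of
#' duplicated marker hits:
#' `completeness = 100 * distinct_markers / G`,
#' `contamination = 100 * (total_hits - distinct_markers) / G`.
#' The partition score is the sum of six counts: bins with contamination
#' strictly below 5% or 10%, crossed with completeness strictly above 50%,
#' 70% or 90%. This score drives automatic parameter selection.
#'
#' @param assignment A `bin_assignment`.
#' @param scg An `scg_table` (with nonempty marker universe for meaningful
#'   estimates).
#' @return A `quality_estimate`: list with `per_bin` (data frame `bin_id`,
#'   `completeness`, `contamination`), `six_metrics` (named counts) and
#'   `score`.
#' @export
estimate_quality <- function(assignment, scg) {
  stopifnot(inherits(assignment, "bin_assignment"), inherits(scg, "scg_table"))
  G <- scg$G
  bins <- names(assignment$bin_sizes)
  if (G == 0 || length(bins) == 0) {
    if (G == 0) warning("empty marker universe; quality estimates are all zero")
    per_bin <- data.frame(bin_id = bins, completeness = numeric(length(bins)),
                          contamination = numeric(length(bins)))
    six <- stats::setNames(integer(6), six_metric_names())
    return(structure(list(per_bin = per_bin, six_metrics = six, score = 0L),
                     class = "quality_estimate"))
  }
  hit_bin <- assignment$labels[scg$hits$contig_id]
  per_bin <- data.frame(bin_id = bins,
                        completeness = 0, contamination = 0,
                        stringsAsFactors = FALSE)
  keep <- !is.na(hit_bin)
  if (any(keep)) {
    hb <- hit_bin[keep]
    hm <- scg$hits$marker_id[keep]
    total <- tapply(hm, hb, length)
    distinct <- tapply(hm, hb, function(x) length(unique(x)))
    idx <- match(names(total), per_bin$bin_id)
    per_bin$completeness[idx] <- 100 * distinct / G
    per_bin$contamination[idx] <- 100 * (total - distinct) / G
  }
  six <- six_metric_counts(per_bin)
  structure(list(per_bin = per_bin, six_metrics = six,
                 score = sum(six)),
            class = "quality_estimate")
}

six_metric_names <- function() {
  as.vector(outer(c("cont_lt5", "cont_lt10"), c("comp_gt50", "comp_gt70", "comp_gt90"),
                  paste, sep = "_"))
}

six_metric_counts <- function(per_bin) {
  counts <- integer(0)
  for (comp in c(50, 70, 90)) {
    for (cont in c(5, 10)) {
      counts <- c(counts, sum(per_bin$contamination < cont &
                              per_bin$completeness > comp))
    }
  }
  names(counts) <- as.vector(outer(c("cont_lt5", "cont_lt10"),
                                   c("comp_gt50", "comp_gt70", "comp_gt90"),
                                   paste, sep = "_"))
  counts
}

#' @export
print.quality_estimate <- function(x, ...) {
  cat(sprintf("quality_estimate: score %d over %d bins\n",
              x$score, nrow(x$per_bin)))
  invisible(x)
}

#' Remove bins below the minimum size
#'
#' Drops bins whose total length is strictly smaller than `min_bin_bp`
#' (default 200 kbp, too small to be a credible draft genome); their contigs
#' become unbinned. A bin of exactly `min_bin_bp` is retained.
#'
#' @param assignment A `bin_assignment`.
#' @param contig_lengths Named contig lengths.
#' @param min_bin_bp Minimum bin size in bp (default 200000).
#' @return The filtered `bin_assignment`.
#' @export
filter_small_bins <- function(assignment, contig_lengths, min_bin_bp = 200000) {
  stopifnot(inherits(assignment, "bin_assignment"))
  keep_bins <- names(assignment$bin_sizes)[assignment$bin_sizes >= min_bin_bp]
  labels <- assignment$labels[assignment$labels %in% keep_bins]
  bin_assignment(labels, contig_lengths, params = assignment$params)
}
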