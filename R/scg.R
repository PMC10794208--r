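#' Single-copy marker-gene hit table
#'
#' Marker hits are a multiset of `(contig_id, marker_id)` pairs: a contig can
#' legitimately carry the same marker twice (an assembly artefact or a true
#' duplication), and duplicate hits are what the contamination estimate
#' counts, so multiplicity is preserved. The marker universe (with size `G`)
#' defaults to the distinct markers observed unless supplied explicitly.
#'
#' @param hits Data frame with columns `contig_id`, `marker_id`.
#' @param marker_universe Character vector of all marker ids considered.
#' @return An `scg_table`: list with `hits`, `marker_universe`, `G`.
#' @export
scg_table <- function(hits, marker_universe = NULL) {
  stopifnot(all(c("contig_id", "marker_id") %in% names(hits)))
  hits <- data.frame(contig_id = as.character(hits$contig_id),
                     marker_id = as.character(hits$marker_id),
                     stringsAsFactors = FALSE)
  if (is.null(marker_universe)) marker_universe <- sort(unique(hits$marker_id))
  structure(list(hits = hits,
                 marker_universe = as.character(marker_universe),
                 G = length(marker_universe)),
            class = "scg_table")
}

#' @export
print.scg_table <- function(x, ...) {
  cat(sprintf("scg_table: %d hits, %d markers (G = %d)\n",
              nrow(x$hits), length(unique(x$hits$marker_id)), x$G))
  invisible(x)
}

#' Read a single-copy marker-gene hit table
#'
#' Expects a TSV with header columns `contig_id` and `marker_id` (produced
#' upstream by gene calling + HMM search, or by the synthetic community
#' generator). Rows naming contigs absent from the assembly are dropped with
#' a warning. An empty table is valid: clustering then runs unconstrained.
#'
#' @param path Path to the TSV.
#' @param contigs The `contig_set` the hits refer to.
#' @param universe_path Optional one-column file (`marker_id`) defining the
#'   full marker universe; defaults to the distinct markers in `path`.
#' @return An `scg_table`.
#' @export
read_scg_table <- function(path, contigs, universe_path = NULL) {
  stopifnot(inherits(contigs, "contig_set"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("contig_id", "marker_id") %in% names(df))) {
    stop("SCG table ", path, " must have columns contig_id, marker_id")
  }
  known <- df$contig_id %in% contigs$ids
  if (any(!known)) {
    warning(sprintf("SCG table %s: dropping %d rows for unknown contigs",
                    path, sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  universe <- NULL
  if (!is.null(universe_path)) {
    universe <- utils::read.table(universe_path, header = TRUE,
                                  colClasses = "character")[[1]]
  }
  scg_table(df, universe)
}

#' Write an SCG hit table (TSV)
#'
#' @param scg An `scg_table`.
#' @param path Output path.
#' @export
write_scg_table <- function(scg, path) {
  utils::write.table(scg$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
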