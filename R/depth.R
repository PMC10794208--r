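#' Per-base read depth for one sequencing sample
#'
#' A `depth_track` stores, for every contig, a run-length encoding of the
#' per-base read depth: a data frame of half-open 0-based intervals
#' `(start, end, depth)` that tile `[0, contig_length)` without gaps or
#' overlaps. All coverage statistics are computed directly on this encoding;
#' per-base vectors are never materialized.
#'
#' @param sample_id Sample label.
#' @param intervals Named list (by contig id) of data frames with columns
#'   `start`, `end`, `depth`.
#' @param contig_lengths Named contig lengths used to validate tiling.
#' @return A `depth_track` object.
#' @export
depth_track <- function(sample_id, intervals, contig_lengths) {
  for (cid in names(intervals)) {
    iv <- intervals[[cid]]
    len <- contig_lengths[[cid]]
    if (is.null(len)) stop("depth for unknown contig: ", cid)
    if (nrow(iv) == 0) stop("empty interval set for contig ", cid)
    iv <- iv[order(iv$start), , drop = FALSE]
    if (any(iv$depth < 0)) stop("negative depth on contig ", cid)
    if (iv$start[1] != 0 || iv$end[nrow(iv)] != len ||
        (nrow(iv) > 1 && any(iv$end[-nrow(iv)] != iv$start[-1]))) {
      stop("depth intervals do not tile [0, ", len, ") for contig ", cid)
    }
    intervals[[cid]] <- iv
  }
  structure(list(sample_id = sample_id, intervals = intervals),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track '%s': %d contigs, %d intervals\n", x$sample_id,
              length(x$intervals), sum(vapply(x$intervals, nrow, 1L))))
  invisible(x)
}

#' Read per-base depth for one sample
#'
#' Accepts either a BED-style 4-column per-base depth file
#' (`contig  start  end  depth`, 0-based half-open, the `genomecov -bga`
#' dialect) or a coordinate-sorted indexed BAM (pileup computed with
#' Rsamtools). Contigs of the assembly absent from the input get a single
#' zero-depth interval; rows for unknown contigs are skipped with a warning.
#'
#' @param path Path to a `.bed`/`.tsv` depth file or a `.bam` file.
#' @param contigs The `contig_set` the depths refer to.
#' @param sample_id Sample label (defaults to the file name).
#' @return A `depth_track`.
#' @export
read_depth <- function(path, contigs, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bed|tsv|txt|bam)$", "", basename(path), ignore.case = TRUE)
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    read_depth_bam(path, contigs, sample_id)
  } else {
    read_depth_bed(path, contigs, sample_id)
  }
}

#' @rdname read_depth
#' @export
read_depth_bed <- function(path, contigs, sample_id = basename(path)) {
  stopifnot(inherits(contigs, "contig_set"))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "start", "end", "depth"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  known <- df$contig %in% contigs$ids
  if (any(!known)) {
    warning(sprintf("depth file %s: skipping %d rows for unknown contigs",
                    path, sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  intervals <- vector("list", length(contigs$ids))
  names(intervals) <- contigs$ids
  by_contig <- split(df[c("start", "end", "depth")], df$contig)
  for (cid in names(by_contig)) {
    iv <- by_contig[[cid]]
    len <- contigs$lengths[[cid]]
    if (any(iv$end > len) || any(iv$start < 0)) {
      stop("depth interval beyond contig bounds for ", cid,
           " (length ", len, ") in ", path)
    }
    intervals[[cid]] <- iv[order(iv$start), , drop = FALSE]
  }
  for (cid in contigs$ids) {
    if (is.null(intervals[[cid]])) {
      intervals[[cid]] <- data.frame(start = 0, end = contigs$lengths[[cid]],
                                     depth = 0)
    }
  }
  depth_track(sample_id, intervals, contigs$lengths)
}

#' @rdname read_depth
#' @export
read_depth_bam <- function(path, contigs, sample_id = basename(path)) {
  stopifnot(inherits(contigs, "contig_set"))
  bf <- Rsamtools::BamFile(path)
  p <- Rsamtools::pileup(
    bf,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1e6L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = FALSE))
  p$seqnames <- as.character(p$seqnames)
  known <- p$seqnames %in% contigs$ids
  if (any(!known)) {
    warning(sprintf("BAM %s: skipping pileup on %d unknown reference(s)",
                    path, length(unique(p$seqnames[!known]))))
    p <- p[known, , drop = FALSE]
  }
  intervals <- vector("list", length(contigs$ids))
  names(intervals) <- contigs$ids
  by_contig <- split(p[c("pos", "count")], p$seqnames)
  for (cid in names(by_contig)) {
    pc <- by_contig[[cid]]
    len <- contigs$lengths[[cid]]
    if (any(pc$pos > len)) stop("pileup beyond contig bounds for ", cid)
    d <- numeric(len)
    d[pc$pos] <- pc$count          # pileup pos is 1-based
    r <- rle(d)
    e <- cumsum(r$lengths)
    intervals[[cid]] <- data.frame(start = c(0, e[-length(e)]), end = e,
                                   depth = r$values)
  }
  for (cid in contigs$ids) {
    if (is.null(intervals[[cid]])) {
      intervals[[cid]] <- data.frame(start = 0, end = contigs$lengths[[cid]],
                                     depth = 0)
    }
  }
  depth_track(sample_id, intervals, contigs$lengths)
}

#' Mean and standard deviation of depth over an interval
#'
#' Computes the per-base mean and the population standard deviation of the
#' read depth over `[start, end)` of a contig, directly from the run-length
#' encoding.
#'
#' @param track A `depth_track`.
#' @param contig_id Contig identifier.
#' @param start,end Half-open 0-based interval; defaults to the full contig.
#' @return Numeric `c(mean, sd)`.
#' @export
coverage_stats <- function(track, contig_id, start = NULL, end = NULL) {
  iv <- track$intervals[[contig_id]]
  if (is.null(iv)) stop("no depth track for contig ", contig_id)
  clen <- iv$end[nrow(iv)]
  if (is.null(start)) start <- 0
  if (is.null(end)) end <- clen
  if (start < 0 || end > clen || end <= start) {
    stop(sprintf("invalid interval [%s, %s) on contig %s (length %s)",
                 start, end, contig_id, clen))
  }
  w <- pmin(iv$end, end) - pmax(iv$start, start)
  keep <- w > 0
  w <- w[keep]; d <- iv$depth[keep]
  L <- end - start
  m <- sum(w * d) / L
  v <- sum(w * d * d) / L - m * m
  c(mean = m, sd = sqrt(max(v, 0)))
}
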