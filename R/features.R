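#' Canonical k-mer index
#'
#' Maps every k-mer to a canonical class shared with its reverse complement
#' (a sequence and its reverse complement have identical composition
#' features, as either strand may have been assembled). Classes are numbered
#' 0..T-1 in lexicographic order of the canonical k-mer. The class count is
#' obtained by enumeration: (4^k - p)/2 + p classes, where p is the number
#' of reverse-complement palindromes. For the default k = 4 this gives
#' T = 136 classes, 16 of which are palindromic singletons.
#'
#' @param k Word size (default 4).
#' @return A `kmer_index`: list with `k`, `T`, `class_of` (named integer
#'   vector, k-mer -> 0-based class id) and `kmers` (all 4^k words in
#'   lexicographic A<C<G<T order).
#' @export
build_canonical_index <- function(k = 4L) {
  stopifnot(k >= 1)
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  rc <- vapply(kmers, function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  canon <- ifelse(kmers <= rc, kmers, rc)
  classes <- sort(unique(canon))
  class_of <- stats::setNames(match(canon, classes) - 1L, kmers)
  structure(list(k = as.integer(k), T = length(classes),
                 class_of = class_of, kmers = kmers),
            class = "kmer_index")
}

#' Composition feature: canonical tetranucleotide frequencies
#'
#' Slides a window of length `k` with stride 1 over each sequence, counting
#' canonical k-mer classes; windows containing non-ACGT characters are
#' skipped. A pseudocount of 1 is added to every class (so no entry is
#' zero) and the vector is normalized to sum to one, removing the effect of
#' contig length.
#'
#' @param seqs Character vector of DNA sequences (each of length >= `k` with
#'   at least one all-ACGT window).
#' @param index A `kmer_index` from [build_canonical_index()].
#' @return Numeric matrix, one row per sequence, `index$T` columns (named by
#'   canonical k-mer); rows sum to 1 and are strictly positive.
#' @export
compute_tnf <- function(seqs, index) {
  stopifnot(inherits(index, "kmer_index"))
  dna <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(dna, width = index$k)
  if (any(rowSums(counts) < 1)) {
    bad <- which(rowSums(counts) < 1)
    stop("no valid ", index$k, "-mer window in sequence(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  # collapse the 4^k columns onto canonical classes
  cls <- index$class_of[colnames(counts)] + 1L
  coll <- t(rowsum(t(counts), group = cls))
  f <- coll + 1
  q <- f / rowSums(f)
  cn <- character(index$T)
  keep <- !duplicated(index$class_of)
  cn[index$class_of[keep] + 1L] <- names(index$class_of)[keep]
  colnames(q) <- cn
  q
}

#' Coverage feature: per-view depth mean and standard deviation
#'
#' For each view (a contig or a fragment of one) and each sample, computes
#' the per-base depth mean and population standard deviation over the view's
#' parent-contig interval, producing a `2M`-column matrix (all M means, then
#' all M standard deviations). A small offset (default `1e-5`) is added to
#' every entry so that no coverage vector is identically zero.
#'
#' @param views A `view_set`.
#' @param depth_tracks List of `depth_track`, one per sample.
#' @param offset Additive offset (default `1e-5`).
#' @return Numeric matrix `nrow(views) x 2M` with columns
#'   `mean.<sample>`..., `sd.<sample>`....
#' @export
assemble_coverage <- function(views, depth_tracks, offset = 1e-5) {
  stopifnot(inherits(views, "view_set"), length(depth_tracks) >= 1)
  M <- length(depth_tracks)
  nv <- nrow(views)
  means <- matrix(0, nv, M)
  sds <- matrix(0, nv, M)
  for (m in seq_len(M)) {
    tr <- depth_tracks[[m]]
    missing <- setdiff(unique(views$parent_id), names(tr$intervals))
    if (length(missing)) {
      stop("sample '", tr$sample_id, "' has no depth track for contig(s) ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    for (i in seq_len(nv)) {
      st <- coverage_stats(tr, views$parent_id[i], views$start[i], views$end[i])
      means[i, m] <- st[1]
      sds[i, m] <- st[2]
    }
  }
  C <- cbind(means, sds) + offset
  ids <- vapply(depth_tracks, function(t) t$sample_id, character(1))
  colnames(C) <- c(paste0("mean.", ids), paste0("sd.", ids))
  C
}

#' Normalize coverage across contigs
#'
#' Divides every column of the raw coverage matrix by that column's maximum
#' taken over the original-contig views only (view 0). This removes
#' between-sample differences in sequencing effort, and reusing the
#' original-contig divisors for the augmented fragments keeps the original
#' contigs' features invariant to which fragments were drawn. Mean and
#' standard-deviation columns are normalized independently, each by its own
#' maximum.
#'
#' @param C Raw coverage matrix from [assemble_coverage()] (strictly
#'   positive).
#' @param view_index Integer vector aligned with the rows of `C`; rows with
#'   `view_index == 0` are the original contigs.
#' @param divisors Optional precomputed column divisors (reuse at inference).
#' @return List with `x_cov` (normalized matrix; original-view rows have
#'   column maximum exactly 1) and `divisors`.
#' @export
normalize_coverage <- function(C, view_index, divisors = NULL) {
  stopifnot(all(C > 0))
  if (is.null(divisors)) {
    orig <- view_index == 0L
    if (!any(orig)) stop("no original-contig views (view_index == 0) found")
    divisors <- apply(C[orig, , drop = FALSE], 2, max)
  }
  list(x_cov = sweep(C, 2, divisors, "/"), divisors = divisors)
}

#' Build the full feature block for a view set
#'
#' Convenience wrapper combining [compute_tnf()], [assemble_coverage()] and
#' [normalize_coverage()] into the per-view feature matrices consumed by the
#' encoders.
#'
#' @param views A `view_set`.
#' @param depth_tracks List of `depth_track`, one per sample.
#' @param index A `kmer_index` (default: canonical tetramers).
#' @param offset Coverage offset (default `1e-5`).
#' @return A `feature_block`: list with `x_com` (n x T), `x_cov` (n x 2M),
#'   `views` (coordinates), `divisors`, `M`.
#' @export
build_features <- function(views, depth_tracks,
                           index = build_canonical_index(4L), offset = 1e-5) {
  x_com <- compute_tnf(views$seq, index)
  C <- assemble_coverage(views, depth_tracks, offset = offset)
  nc <- normalize_coverage(C, views$view_index)
  structure(list(x_com = x_com, x_cov = nc$x_cov,
                 views = views[c("parent_id", "view_index", "start", "end")],
                 divisors = nc$divisors, M = length(depth_tracks)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block: %d views, composition %d-dim, coverage %d-dim (M = %d)\n",
              nrow(x$x_com), ncol(x$x_com), ncol(x$x_cov), x$M))
  invisible(x)
}
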