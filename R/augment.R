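#' Multi-view augmentation of contigs
#'
#' Builds the view set used for contrastive learning: for every contig, view
#' 0 is the original sequence and views 1..`n_aug` are randomly extracted
#' contiguous fragments. Fragments sampled from the same contig are treated
#' as positive pairs downstream, on the assumption that sub-sequences of one
#' contig belong to the same genome. With the defaults this yields six views
#' per contig.
#'
#' Fragment law: length drawn uniformly on `[min_frag_len, contig_length]`,
#' then start uniformly on `[0, contig_length - length]`. Fragments may
#' overlap or repeat; no deduplication is applied. Each contig gets its own
#' RNG stream derived from `(seed, contig_id)`, so the result is independent
#' of contig order and safe to parallelize.
#'
#' @param contigs A `contig_set`; all contigs must be >= `min_frag_len`.
#' @param n_aug Number of augmented fragment views per contig (default 5).
#' @param min_frag_len Minimum fragment length in bp (default 1000).
#' @param seed Integer seed; fully determines the views.
#' @return A `view_set`: data frame with columns `parent_id`, `view_index`
#'   (0..`n_aug`), `start`, `end` (half-open, 0-based), `seq`, plus
#'   attributes `n_views` and `contig_ids`.
#' @export
augment_contigs <- function(contigs, n_aug = 5L, min_frag_len = 1000L, seed = 1L) {
  stopifnot(inherits(contigs, "contig_set"), n_aug >= 0)
  short <- contigs$lengths < min_frag_len
  if (any(short)) {
    stop("contigs shorter than min_frag_len (", min_frag_len, " bp): ",
         paste(utils::head(contigs$ids[short], 5), collapse = ", "))
  }
  per_contig <- lapply(contigs$ids, function(cid) {
    L <- contigs$lengths[[cid]]
    if (n_aug > 0) {
      draws <- with_seed(derive_seed(seed, cid), {
        # sample integer length uniformly on [min_frag_len, L], then start
        flen <- min_frag_len + floor(stats::runif(n_aug) * (L - min_frag_len + 1))
        flen <- pmin(flen, L)
        fstart <- floor(stats::runif(n_aug) * (L - flen + 1))
        list(start = as.integer(fstart), len = as.integer(flen))
      })
      starts <- c(0L, draws$start)
      ends <- c(L, draws$start + draws$len)
    } else {
      starts <- 0L
      ends <- L
    }
    data.frame(parent_id = cid, view_index = 0:n_aug,
               start = starts, end = ends, stringsAsFactors = FALSE)
  })
  vs <- do.call(rbind, per_contig)
  vs$seq <- substr(contigs$seqs[vs$parent_id], vs$start + 1L, vs$end)
  rownames(vs) <- NULL
  structure(vs, n_views = n_aug + 1L, contig_ids = contigs$ids,
            class = c("view_set", "data.frame"))
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("view_set: %d contigs x %d views\n",
              length(attr(x, "contig_ids")), attr(x, "n_views")))
  invisible(x)
}

#' Dump view coordinates for audit
#'
#' @param views A `view_set`.
#' @param path Output TSV path.
#' @export
write_view_table <- function(views, path) {
  utils::write.table(views[c("parent_id", "view_index", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
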