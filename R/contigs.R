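#' Read assembled contigs from FASTA
#'
#' Loads contigs, uppercases the sequences and drops contigs shorter than
#' `min_contig_len` (binning operates on contigs of at least 1 kbp by
#' default; shorter sequences carry too little composition and coverage
#' signal). The assembly N50 is recomputed over the retained contigs and
#' later drives the default contrastive temperature (see [tau_from_n50()]).
#'
#' @param path Path to a FASTA file.
#' @param min_contig_len Minimum contig length in bp to retain (default 1000).
#' @return A `contig_set`: list with `ids`, `seqs` (named uppercase character
#'   vector over A/C/G/T/N), `lengths` (named integer) and `n50`.
#' @export
read_fasta <- function(path, min_contig_len = 1000L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dna <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(dna) == 0) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(dna))
  names(seqs) <- ids
  keep <- nchar(seqs) >= min_contig_len
  if (any(!keep)) {
    cb_log("io", "dropped %d/%d contigs shorter than %d bp",
           sum(!keep), length(keep), min_contig_len)
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0) {
    stop("no contigs of length >= ", min_contig_len, " bp in ", path)
  }
  contig_set(ids = names(seqs), seqs = unname(seqs))
}

#' Construct a contig set
#'
#' @param ids Unique contig identifiers.
#' @param seqs DNA sequences (same order as `ids`).
#' @return A `contig_set` object.
#' @export
contig_set <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  seqs <- toupper(seqs)
  lengths <- nchar(seqs)
  names(seqs) <- ids
  names(lengths) <- ids
  structure(
    list(ids = as.character(ids), seqs = seqs,
         lengths = stats::setNames(as.integer(lengths), ids),
         n50 = n50(lengths)),
    class = "contig_set"
  )
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %.2f Mbp total, N50 = %d bp\n",
              length(x$ids), sum(as.numeric(x$lengths)) / 1e6, x$n50))
  invisible(x)
}

#' @export
length.contig_set <- function(x) length(x$ids)

#' Write bins to disk
#'
#' Writes a `contig_bins.tsv` table (`contig_id` TAB `bin_id`), one FASTA per
#' bin under `outdir`, and an `unbinned.tsv` listing contigs without a bin.
#' Bins are renamed deterministically `bin_000`, `bin_001`, ... in order of
#' decreasing total bp (ties broken by smallest member contig id).
#'
#' @param assignment A `bin_assignment` (see [bin_assignment()]).
#' @param contigs The `contig_set` the assignment refers to.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the renamed `bin_assignment`.
#' @export
write_bins <- function(assignment, contigs, outdir) {
  stopifnot(inherits(assignment, "bin_assignment"), inherits(contigs, "contig_set"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)

  labels <- assignment$labels
  binned <- names(labels)
  sizes <- tapply(as.numeric(contigs$lengths[binned]), labels, sum)
  firsts <- tapply(binned, labels, function(m) min(sort(m)))
  ord <- order(-sizes, firsts)
  new_names <- sprintf("bin_%03d", seq_along(ord) - 1L)
  names(new_names) <- names(sizes)[ord]
  labels_out <- unname(new_names[as.character(labels)])

  tsv <- file.path(outdir, "contig_bins.tsv")
  utils::write.table(
    data.frame(contig_id = binned, bin_id = labels_out, stringsAsFactors = FALSE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  for (b in new_names) {
    members <- binned[labels_out == b]
    dna <- Biostrings::DNAStringSet(contigs$seqs[members])
    Biostrings::writeXStringSet(dna, file.path(outdir, paste0(b, ".fa")))
  }

  unb <- setdiff(contigs$ids, binned)
  utils::write.table(
    data.frame(contig_id = unb, stringsAsFactors = FALSE),
    file.path(outdir, "unbinned.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  out <- bin_assignment(stats::setNames(labels_out, binned),
                        contig_lengths = contigs$lengths,
                        params = assignment$params)
  invisible(out)
}

#' Read a bin assignment table written by [write_bins()]
#'
#' @param path Path to a `contig_bins.tsv` file.
#' @param contig_lengths Named vector of contig lengths (for bin sizes).
#' @return A `bin_assignment`.
#' @export
read_bins_tsv <- function(path, contig_lengths) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  bin_assignment(stats::setNames(df$bin_id, df$contig_id), contig_lengths)
}

#' Construct a bin assignment
#'
#' @param labels Named character vector: `contig_id -> bin_id` (binned
#'   contigs only; each contig appears at most once).
#' @param contig_lengths Named lengths covering at least the binned contigs.
#' @param params Optional list of the clustering parameters that produced it
#'   (`sigma`, `resolution`, `edge_ratio`).
#' @return A `bin_assignment`: list with `labels`, `bin_sizes` (total bp per
#'   bin) and `params`.
#' @export
bin_assignment <- function(labels, contig_lengths, params = NULL) {
  stopifnot(!is.null(names(labels)) || length(labels) == 0)
  if (anyDuplicated(names(labels))) stop("a contig appears in more than one bin")
  if (length(labels)) {
    missing <- setdiff(names(labels), names(contig_lengths))
    if (length(missing)) stop("binned contigs without lengths: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    bin_sizes <- tapply(as.numeric(contig_lengths[names(labels)]), labels, sum)
    bin_sizes <- stats::setNames(as.numeric(bin_sizes), names(bin_sizes))
  } else {
    bin_sizes <- stats::setNames(numeric(0), character(0))
  }
  structure(list(labels = labels, bin_sizes = bin_sizes, params = params),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("bin_assignment: %d contigs in %d bins\n",
              length(x$labels), length(x$bin_sizes)))
  invisible(x)
}
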