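# Interface to the Leiden backend (python-igraph + leidenalg), which
# supports the two departures from stock Leiden this method needs: frozen
# (fixed-membership) nodes and contig lengths as node sizes.

find_python <- function() {
  py <- Sys.getenv("CONTRABIN_PYTHON", "python")
  if (Sys.which(py) == "") {
    stop("python interpreter '", py, "' not found on PATH; the Leiden ",
         "backend needs python with igraph and leidenalg installed ",
         "(override with the CONTRABIN_PYTHON environment variable)")
  }
  py
}

backend_script <- function() {
  p <- system.file("python", "leiden_backend.py", package = "contrabin")
  if (p == "") stop("leiden_backend.py not found; is contrabin installed?")
  p
}

# Run the backend on a set of (sigma, resolution) combos sharing one edge
# set. Returns an integer membership matrix (n_nodes x n_combos).
run_leiden_batch <- function(edges, n_nodes, node_sizes, fixed_nodes,
                             combos, seed, n_iterations = -1L) {
  stopifnot(nrow(edges) >= 1)
  tmp <- tempfile("leiden_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  edge_file <- file.path(tmp, "edges.tsv")
  out_file <- file.path(tmp, "membership.tsv")
  utils::write.table(
    data.frame(i = edges$i - 1L, j = edges$j - 1L, d2 = edges$d2),
    edge_file, sep = "\t", quote = FALSE, row.names = FALSE)
  job <- list(n_nodes = n_nodes, edge_file = edge_file,
              node_sizes = I(as.integer(node_sizes)),
              fixed_nodes = I(as.integer(fixed_nodes - 1L)),
              combos = combos, seed = as.integer(seed),
              n_iterations = as.integer(n_iterations), out_file = out_file)
  job_file <- file.path(tmp, "job.json")
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA)
  res <- system2(find_python(), c(backend_script(), job_file),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("Leiden backend failed:\n", paste(res, collapse = "\n"))
  }
  mem <- utils::read.table(out_file, header = TRUE, sep = "\t")
  as.matrix(mem)
}

#' Pick the seed marker for the clustering constraint
#'
#' Selects the single-copy marker gene hitting the largest number of
#' distinct contigs; those contigs are frozen in distinct communities
#' during Leiden, since contigs carrying the same single-copy marker must
#' come from different genomes. Ties go to the lexicographically smallest
#' marker id; an empty table yields `NULL` (unconstrained clustering).
#'
#' @param scg An `scg_table`.
#' @return Marker id, or `NULL`.
#' @export
pick_seed_marker <- function(scg) {
  stopifnot(inherits(scg, "scg_table"))
  if (nrow(scg$hits) == 0) return(NULL)
  counts <- tapply(scg$hits$contig_id, scg$hits$marker_id,
                   function(x) length(unique(x)))
  cand <- names(counts)[counts == max(counts)]
  sort(cand)[1]
}

#' Constrained Leiden clustering of a similarity graph
#'
#' Runs Leiden community detection on the similarity-weighted graph with
#' singleton initial membership, contig lengths as node sizes (each node is
#' treated as an aggregation of its base pairs) and the given contigs frozen
#' in their distinct initial communities, so no two of them can merge.
#' Unconstrained nodes may join any community, including a frozen one.
#'
#' @param simgraph A `similarity_graph` (see [to_similarity()]).
#' @param resolution Leiden resolution parameter.
#' @param contig_lengths Named lengths for all graph nodes.
#' @param fixed_contigs Character vector of contig ids to freeze (e.g. the
#'   contigs carrying the marker from [pick_seed_marker()]).
#' @param seed RNG seed for the Leiden optimiser.
#' @param n_iterations Leiden iterations; `-1` (default) runs to
#'   convergence.
#' @return A `bin_assignment` covering every node.
#' @export
leiden_cluster <- function(simgraph, resolution, contig_lengths,
                           fixed_contigs = character(0), seed = 1L,
                           n_iterations = -1L) {
  stopifnot(inherits(simgraph, "similarity_graph"))
  ids <- simgraph$ids
  fixed_idx <- match(fixed_contigs, ids)
  if (anyNA(fixed_idx)) stop("fixed contigs not in graph: ",
                             paste(fixed_contigs[is.na(fixed_idx)], collapse = ", "))
  mem <- run_leiden_batch(simgraph$edges, simgraph$n,
                          node_sizes = contig_lengths[ids],
                          fixed_nodes = fixed_idx,
                          combos = list(list(sigma = simgraph$sigma,
                                             resolution = resolution)),
                          seed = seed, n_iterations = n_iterations)
  labels <- stats::setNames(paste0("c", mem[, 1]), ids)
  bin_assignment(labels, contig_lengths,
                 params = list(sigma = simgraph$sigma, resolution = resolution,
                               edge_ratio = NA_real_))
}
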