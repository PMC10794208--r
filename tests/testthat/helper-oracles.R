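# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Dictionary-count TNF oracle: slide a window, skip non-ACGT windows, count
# per canonical k-mer (min of word and reverse complement), add 1, normalize.
oracle_tnf <- function(seq, k = 4) {
  counts <- list()
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    canon <- min(w, revcomp_chr(w))
    counts[[canon]] <- (counts[[canon]] %||% 0) + 1
  }
  # canonical k-mers in class-id order, derived independently by enumeration
  bases <- c("A", "C", "G", "T")
  all_kmers <- apply(do.call(expand.grid, rep(list(bases), k)), 1, paste,
                     collapse = "")
  canon_kmers <- sort(unique(vapply(all_kmers,
                                    function(w) min(w, revcomp_chr(w)),
                                    character(1))))
  f <- vapply(canon_kmers, function(cw) (counts[[cw]] %||% 0) + 1, numeric(1))
  unname(f / sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-base expansion oracle for depth statistics.
oracle_cov_stats <- function(intervals, start, end) {
  per_base <- rep(intervals$depth, intervals$end - intervals$start)
  x <- per_base[(start + 1):end]
  c(mean(x), sqrt(mean((x - mean(x))^2)))
}

# Triple-loop multi-view NT-Xent oracle, straight from the printed formula.
oracle_multiview <- function(Z, tau, V) {
  N <- nrow(Z) / V
  total <- 0
  z <- function(i, v) Z[(i - 1) * V + v, ]
  for (i in seq_len(N)) {
    for (v in seq_len(V)) {
      for (v1 in seq_len(V)) {
        if (v1 == v) next
        num <- exp(cosine(z(i, v), z(i, v1)) / tau)
        den <- num
        for (j in seq_len(N)) {
          if (j == i) next
          for (v2 in seq_len(V)) {
            den <- den + exp(cosine(z(i, v), z(j, v2)) / tau)
          }
        }
        total <- total - log(num / den)
      }
    }
  }
  total / (N * V * (V - 1))
}

# Random run-length depth intervals tiling [0, len).
random_intervals <- function(len, max_depth = 20) {
  cuts <- sort(unique(c(0, sample(len - 1, sample(1:8, 1)), len)))
  data.frame(start = cuts[-length(cuts)], end = cuts[-1],
             depth = sample(0:max_depth, length(cuts) - 1, replace = TRUE))
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A small, quick community for unit tests (not the acceptance fixture).
tiny_community <- function(seed = 7, n_genomes = 4, genome_length = 60000,
                           n_samples = 3) {
  simulate_community(community_spec(
    n_genomes = n_genomes, genome_length = genome_length,
    n_samples = n_samples, composition_divergence = 1.5,
    contig_len_range = c(1000L, 4000L), n_markers = 5L, seed = seed))
}

small_encoder <- function(latent = 16) {
  encoder_config(cov_hidden = c(32, 32), cov_out_dim = 32,
                 combine_hidden = c(64, 64), latent_dim = latent,
                 dropout = 0.1)
}

# Adjusted Rand index (chance-corrected clustering agreement); independent
# cross-check lives in mclust, used directly where available.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
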