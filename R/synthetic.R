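#' Specification of a synthetic metagenomic community
#'
#' The generator emulates the inputs a binner consumes after assembly and
#' read alignment: genomes with genome-distinct k-mer composition (each
#' genome is drawn from its own order-1 base-transition law whose departure
#' from uniform is controlled by `composition_divergence`), fragmented into
#' contigs of at least 1 kbp, with per-sample per-base depth tracks driven
#' by genome-specific abundances plus multiplicative lognormal noise and a
#' smooth within-contig modulation, and single-copy marker genes planted
#' exactly once per genome per marker.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Genome length in bp (each genome).
#' @param n_samples Number of sequencing samples (M).
#' @param abundance Optional `n_genomes x n_samples` relative-abundance
#'   matrix; default: independent lognormal(0, 1) entries (distinct
#'   profiles).
#' @param composition_divergence Strength of per-genome base-transition
#'   bias; 0 means all genomes share the uniform law.
#' @param contig_len_range Contig length law: uniform over this range (bp).
#' @param depth_scale Mean per-base depth multiplier per abundance unit.
#' @param noise_sd Standard deviation of the per-contig lognormal depth
#'   factor.
#' @param mod_amp Amplitude of the smooth within-contig depth modulation
#'   (keeps the per-base depth standard deviation nonzero).
#' @param n_markers Number of single-copy markers (G).
#' @param min_contig_len Minimum contig length retained (default 1000).
#' @param seed Integer seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 10L, genome_length = 300000L,
                           n_samples = 5L, abundance = NULL,
                           composition_divergence = 1.5,
                           contig_len_range = c(1000L, 5000L),
                           depth_scale = 30, noise_sd = 0.3, mod_amp = 0.3,
                           n_markers = 10L, min_contig_len = 1000L,
                           seed = 1L) {
  stopifnot(n_genomes >= 1, n_samples >= 1, n_markers >= 1,
            contig_len_range[1] >= min_contig_len,
            composition_divergence >= 0)
  if (!is.null(abundance)) {
    stopifnot(nrow(abundance) == n_genomes, ncol(abundance) == n_samples,
              all(abundance >= 0))
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length),
                 n_samples = as.integer(n_samples), abundance = abundance,
                 composition_divergence = composition_divergence,
                 contig_len_range = as.integer(contig_len_range),
                 depth_scale = depth_scale, noise_sd = noise_sd,
                 mod_amp = mod_amp, n_markers = as.integer(n_markers),
                 min_contig_len = as.integer(min_contig_len),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Canonical test-community presets
#'
#' `"easy"`: 10 genomes, 5 samples, strong composition divergence and
#' distinct abundance profiles, roughly 100 contigs per genome — the
#' canonical end-to-end fixture. `"hard-strain"`: two genomes sharing one
#' base-composition law and differing only in abundance, so only coverage
#' features can separate them.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [community_spec()].
#' @return A `community_spec`.
#' @export
community_preset <- function(name = c("easy", "hard-strain"), seed = 1L, ...) {
  name <- match.arg(name)
  if (name == "easy") {
    # distinct abundance profiles by construction: genome peaks evenly
    # spaced around the sample axis (circular), so no two profiles coincide
    n_g <- 10L; n_s <- 5L
    ab <- 3 * exp(1.5 * cos(2 * pi * outer(seq_len(n_g) - 1, seq_len(n_s) - 1,
                                           function(g, m) m / n_s - g / n_g)))
    community_spec(n_genomes = n_g, genome_length = 300000L, n_samples = n_s,
                   abundance = ab, composition_divergence = 1.5,
                   n_markers = 10L, seed = seed, ...)
  } else {
    ab <- matrix(c(40, 25, 10, 4, 1,
                   1, 4, 10, 25, 40), nrow = 2, byrow = TRUE)
    community_spec(n_genomes = 2L, genome_length = 400000L, n_samples = 5L,
                   composition_divergence = 0, abundance = ab,
                   n_markers = 10L, seed = seed, ...)
  }
}

# Order-1 Markov base sampler with per-genome transition matrix.
sim_markov_seq <- function(len, trans, seed) {
  bases <- c("A", "C", "G", "T")
  cp <- t(apply(trans, 1, cumsum))
  with_seed(seed, {
    u <- stats::runif(len)
    s <- integer(len)
    s[1] <- 1L + (u[1] > 0.25) + (u[1] > 0.5) + (u[1] > 0.75)
    for (i in seq_len(len - 1L)) {
      r <- cp[s[i], ]
      s[i + 1L] <- 1L + (u[i + 1L] > r[1]) + (u[i + 1L] > r[2]) + (u[i + 1L] > r[3])
    }
    paste(bases[s], collapse = "")
  })
}

#' Simulate genome sequences
#'
#' Each genome is drawn from its own order-1 base-transition law
#' `P_g(b -> b') proportional to exp(divergence * B_g[b, b'])` with `B_g`
#' standard-normal per genome, giving genome-distinct tetranucleotide
#' signatures when divergence is large and a single shared uniform law when
#' it is zero.
#'
#' @param spec A `community_spec`.
#' @return Named character vector of genome sequences (`g01`, `g02`, ...).
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  genomes <- character(spec$n_genomes)
  names(genomes) <- sprintf("g%02d", seq_len(spec$n_genomes))
  for (g in seq_len(spec$n_genomes)) {
    B <- with_seed(derive_seed(spec$seed, paste0("bias", g)),
                   matrix(stats::rnorm(16), 4, 4))
    W <- exp(spec$composition_divergence * B)
    trans <- W / rowSums(W)
    genomes[g] <- sim_markov_seq(spec$genome_length, trans,
                                 derive_seed(spec$seed, paste0("genome", g)))
  }
  genomes
}

#' Fragment genomes into contigs and generate depth tracks
#'
#' Cuts each genome into consecutive contigs with lengths drawn uniformly
#' from `contig_len_range` (a trailing piece shorter than `min_contig_len`
#' is absorbed into the last contig). Per sample and contig, the depth is
#' `abundance[g, m] * depth_scale * lognormal_factor`, modulated smoothly
#' along the contig by a sinusoid and rounded to integers in steps of
#' ~150 bp, stored run-length encoded.
#'
#' @param genomes Output of [simulate_genomes()].
#' @param spec The `community_spec`.
#' @return List with `contigs` (a `contig_set`), `depth_tracks` (list of
#'   `depth_track`, one per sample), `truth` (named vector contig ->
#'   genome), `abundance` (the matrix used).
#' @export
fragment_and_cover <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  ab <- spec$abundance
  if (is.null(ab)) {
    ab <- with_seed(derive_seed(spec$seed, "abundance"),
                    matrix(stats::rlnorm(spec$n_genomes * spec$n_samples, 0, 1),
                           spec$n_genomes, spec$n_samples))
  }
  ids <- character(0); seqs <- character(0); truth <- character(0)
  cuts <- list()
  for (g in seq_along(genomes)) {
    gid <- names(genomes)[g]
    L <- nchar(genomes[[g]])
    lens <- with_seed(derive_seed(spec$seed, paste0("cuts", g)), {
      out <- integer(0); pos <- 0L
      while (pos < L) {
        l <- sample(spec$contig_len_range[1]:spec$contig_len_range[2], 1L)
        if (L - pos - l < spec$min_contig_len) l <- L - pos  # absorb remainder
        out <- c(out, min(l, L - pos)); pos <- pos + out[length(out)]
      }
      out
    })
    starts <- cumsum(c(0L, lens[-length(lens)]))
    cid <- sprintf("%s_c%04d", gid, seq_along(lens))
    ids <- c(ids, cid)
    seqs <- c(seqs, substring(genomes[[g]], starts + 1L, starts + lens))
    truth <- c(truth, stats::setNames(rep(gid, length(cid)), cid))
    cuts[[gid]] <- data.frame(contig_id = cid, length = lens, genome = g)
  }
  contigs <- contig_set(ids, seqs)
  cutdf <- do.call(rbind, cuts)

  step <- 150L
  tracks <- vector("list", spec$n_samples)
  for (m in seq_len(spec$n_samples)) {
    intervals <- vector("list", nrow(cutdf))
    names(intervals) <- cutdf$contig_id
    for (r in seq_len(nrow(cutdf))) {
      len <- cutdf$length[r]
      g <- cutdf$genome[r]
      prm <- with_seed(derive_seed(spec$seed,
                                   paste0("depth", m, "_", cutdf$contig_id[r])), {
        list(fac = stats::rlnorm(1, 0, spec$noise_sd),
             phase = stats::runif(1, 0, 2 * pi),
             period = stats::runif(1, 2000, 8000))
      })
      base <- ab[g, m] * spec$depth_scale * prm$fac
      st <- seq(0L, len - 1L, by = step)
      en <- pmin(st + step, len)
      mid <- (st + en) / 2
      d <- round(pmax(0, base * (1 + spec$mod_amp * sin(2 * pi * mid / prm$period + prm$phase))))
      rr <- rle(d)
      ee <- en[cumsum(rr$lengths)]
      intervals[[r]] <- data.frame(start = c(0, ee[-length(ee)]), end = ee,
                                   depth = rr$values)
    }
    tracks[[m]] <- depth_track(sprintf("s%02d", m), intervals, contigs$lengths)
  }
  list(contigs = contigs, depth_tracks = tracks, truth = truth, abundance = ab)
}

#' Plant single-copy marker genes
#'
#' Places each of `G` markers exactly once per genome on a uniformly chosen
#' contig of that genome: every marker is single-copy within a genome and
#' present once in each genome, mirroring universal single-copy gene sets.
#'
#' @param contigs A `contig_set`.
#' @param truth Named vector contig -> genome.
#' @param G Number of markers.
#' @param seed Integer seed.
#' @return An `scg_table` with `n_genomes * G` hits.
#' @export
plant_scgs <- function(contigs, truth, G, seed = 1L) {
  genomes <- unique(truth)
  rows <- list()
  for (g in genomes) {
    members <- names(truth)[truth == g]
    picks <- with_seed(derive_seed(seed, paste0("scg", g)),
                       sample(members, G, replace = TRUE))
    rows[[g]] <- data.frame(contig_id = picks,
                            marker_id = sprintf("m%03d", seq_len(G)))
  }
  scg_table(do.call(rbind, rows),
            marker_universe = sprintf("m%03d", seq_len(G)))
}

#' Simulate a complete community
#'
#' One-call wrapper: genomes, contigs, depth tracks, marker table and truth
#' labels.
#'
#' @param spec A `community_spec` (or preset, see [community_preset()]).
#' @return List with `contigs`, `depth_tracks`, `scg`, `truth`,
#'   `abundance`, `spec`.
#' @export
simulate_community <- function(spec = community_preset("easy")) {
  genomes <- simulate_genomes(spec)
  fc <- fragment_and_cover(genomes, spec)
  scg <- plant_scgs(fc$contigs, fc$truth, spec$n_markers,
                    seed = derive_seed(spec$seed, "scg"))
  list(contigs = fc$contigs, depth_tracks = fc$depth_tracks, scg = scg,
       truth = fc$truth, abundance = fc$abundance, spec = spec)
}

#' Write a simulated community in the package's input formats
#'
#' Emits `contigs.fa`, one `depth_<sample>.bed` per sample (0-based
#' half-open 4-column), `scg.tsv` and `truth.tsv` under `dir`.
#'
#' @param community Output of [simulate_community()].
#' @param dir Output directory.
#' @return Invisibly, the list of written paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(contigs = file.path(dir, "contigs.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(community$contigs$seqs), paths$contigs)
  paths$depth <- character(0)
  for (tr in community$depth_tracks) {
    p <- file.path(dir, sprintf("depth_%s.bed", tr$sample_id))
    rows <- do.call(rbind, lapply(names(tr$intervals), function(cid) {
      iv <- tr$intervals[[cid]]
      data.frame(contig = cid, start = iv$start, end = iv$end, depth = iv$depth)
    }))
    utils::write.table(rows, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$depth <- c(paths$depth, p)
  }
  paths$scg <- file.path(dir, "scg.tsv")
  write_scg_table(community$scg, paths$scg)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(contig_id = names(community$truth),
               genome_id = unname(community$truth)),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
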