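test_that("genome simulation is seeded and composition divergence controls TNF separation", {
  spec <- community_spec(n_genomes = 3, genome_length = 20000, n_samples = 2,
                         composition_divergence = 1.5, seed = 23)
  g1 <- simulate_genomes(spec)
  g2 <- simulate_genomes(spec)
  expect_identical(g1, g2)
  expect_equal(unname(nchar(g1)), rep(20000L, 3))

  idx <- build_canonical_index(4)
  # high divergence: genome TNF centroids far apart relative to
  # within-genome contig scatter
  comm <- simulate_community(community_spec(
    n_genomes = 3, genome_length = 40000, n_samples = 2,
    composition_divergence = 1.5, n_markers = 3, seed = 24))
  tnf <- compute_tnf(comm$contigs$seqs, idx)
  lab <- comm$truth[comm$contigs$ids]
  cent <- apply(tnf, 2, tapply, lab, mean)
  inter <- mean(dist(cent))
  intra <- mean(sapply(unique(lab), function(g) {
    rows <- tnf[lab == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, colMeans(rows))^2)))
  }))
  expect_gt(inter, intra)

  # zero divergence: centroids statistically indistinguishable (distance of
  # the same order as the within-genome scatter)
  comm0 <- simulate_community(community_spec(
    n_genomes = 3, genome_length = 40000, n_samples = 2,
    composition_divergence = 0, n_markers = 3, seed = 24))
  tnf0 <- compute_tnf(comm0$contigs$seqs, idx)
  lab0 <- comm0$truth[comm0$contigs$ids]
  cent0 <- apply(tnf0, 2, tapply, lab0, mean)
  intra0 <- mean(sapply(unique(lab0), function(g) {
    rows <- tnf0[lab0 == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, colMeans(rows))^2)))
  }))
  expect_lt(mean(dist(cent0)), intra0)
})

test_that("contigs respect the length floor and depth tracks follow abundance", {
  ab <- matrix(c(1, 0, 0,
                 2, 1, 1), nrow = 2, byrow = TRUE)
  spec <- community_spec(n_genomes = 2, genome_length = 50000, n_samples = 3,
                         abundance = ab, noise_sd = 0.1, depth_scale = 20,
                         seed = 25)
  comm <- simulate_community(spec)
  expect_true(all(comm$contigs$lengths >= 1000))
  expect_equal(sum(comm$contigs$lengths[names(comm$truth)[comm$truth == "g01"]]),
               50000)

  mean_depth <- function(genome, sample) {
    ids <- names(comm$truth)[comm$truth == genome]
    mean(sapply(ids, function(cid)
      coverage_stats(comm$depth_tracks[[sample]], cid)[["mean"]]))
  }
  # abundance 0 -> (near) zero depth in that sample
  expect_lt(mean_depth("g01", 2), 0.5)
  expect_lt(mean_depth("g01", 3), 0.5)
  # doubling abundance roughly doubles depth (sample 1: g02 at 2x g01)
  r <- mean_depth("g02", 1) / mean_depth("g01", 1)
  expect_gt(r, 1.5); expect_lt(r, 2.7)
})

test_that("planted SCGs are one-per-genome-per-marker and score perfectly under truth", {
  comm <- simulate_community(community_spec(
    n_genomes = 10, genome_length = 30000, n_samples = 2,
    n_markers = 10, seed = 26))
  expect_equal(nrow(comm$scg$hits), 100L)    # n_genomes * G
  expect_equal(comm$scg$G, 10L)
  per <- table(comm$truth[comm$scg$hits$contig_id], comm$scg$hits$marker_id)
  expect_true(all(per == 1))                 # single copy per genome per marker

  # binning by the true genome labels is perfect under the estimator
  asg <- bin_assignment(comm$truth, comm$contigs$lengths)
  q <- estimate_quality(asg, comm$scg)
  expect_true(all(q$per_bin$completeness == 100))
  expect_true(all(q$per_bin$contamination == 0))
  expect_equal(q$score, 6L * 10L)
})

test_that("the hard-strain preset separates by coverage but not composition", {
  comm <- simulate_community(community_preset("hard-strain", seed = 27))
  lab <- comm$truth[comm$contigs$ids]
  idx <- build_canonical_index(4)
  tnf <- compute_tnf(comm$contigs$seqs, idx)
  views0 <- augment_contigs(comm$contigs, n_aug = 0, seed = 1)
  C <- assemble_coverage(views0, comm$depth_tracks)
  cov <- normalize_coverage(C, views0$view_index)$x_cov

  split_score <- function(X) {
    km <- stats::kmeans(X, centers = 2, nstart = 10)
    ari(km$cluster, lab)
  }
  set.seed(28)
  expect_gt(split_score(cov), 0.8)    # abundance profiles separate the pair
  expect_lt(split_score(tnf), 0.2)    # shared composition law does not
})
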