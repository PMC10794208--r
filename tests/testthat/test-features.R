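idx4 <- build_canonical_index(4)

test_that("canonical index collapses reverse complements into 136 classes", {
  expect_equal(idx4$T, 136L)
  expect_equal(idx4$class_of[["AAAA"]], idx4$class_of[["TTTT"]])
  expect_equal(idx4$class_of[["ACGT"]], idx4$class_of[["ACGT"]])  # palindrome
  # every k-mer shares its class with exactly its reverse complement
  pal <- 0L
  for (w in idx4$kmers) {
    rc <- revcomp_chr(w)
    expect_equal(idx4$class_of[[w]], idx4$class_of[[rc]])
    if (w == rc) pal <- pal + 1L
  }
  expect_equal(pal, 16L)
  # palindromes are singleton classes
  sizes <- table(idx4$class_of)
  expect_equal(sum(sizes == 1), 16L)
  expect_equal(sum(sizes == 2), 120L)
  expect_equal(range(idx4$class_of), c(0L, 135L))
  # class count formula for other k, by enumeration
  idx3 <- build_canonical_index(3)
  expect_equal(idx3$T, 32L)   # odd k: no palindromes, 64/2
})

test_that("compute_tnf matches the worked homopolymer example and handles N", {
  q <- compute_tnf("AAAAAAAAAA", idx4)
  expect_equal(unname(q[1, "AAAA"]), 8 / 143)
  expect_equal(sum(q[1, -which(colnames(q) == "AAAA")]), 135 / 143)
  expect_equal(sum(q), 1)
  # N windows skipped: AAANAAAA has exactly one valid window
  qn <- compute_tnf("AAANAAAA", idx4)
  expect_equal(unname(qn[1, "AAAA"]), 2 / 137)
  expect_error(compute_tnf("ANNNA", idx4), "no valid")
})

test_that("compute_tnf agrees with the dictionary-count oracle and is strand-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    s <- random_dna(sample(50:400, 1),
                    alphabet = c("A", "C", "G", "T", if (rep %% 4 == 0) "N"))
    if (grepl("^[N]*$", s)) next
    q <- compute_tnf(s, idx4)
    expect_equal(unname(q[1, ]), oracle_tnf(s), tolerance = 1e-14)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q > 0))
    expect_equal(compute_tnf(revcomp_chr(s), idx4), q, ignore_attr = TRUE)
  }
})

test_that("coverage_stats matches per-base expansion on random run-length tracks", {
  set.seed(31)
  for (rep in 1:30) {
    len <- sample(50:500, 1)
    iv <- random_intervals(len)
    cs <- contig_set("c", random_dna(len))
    tr <- depth_track("s", list(c = iv), cs$lengths)
    st <- sample(0:(len - 2), 1)
    en <- sample((st + 1):len, 1)
    expect_equal(unname(coverage_stats(tr, "c", st, en)),
                 oracle_cov_stats(iv, st, en), tolerance = 1e-12)
  }
  tr <- depth_track("s", list(c = data.frame(start = c(0, 1), end = c(1, 2),
                                             depth = c(1, 3))),
                    c(c = 2L))
  expect_equal(unname(coverage_stats(tr, "c")), c(2, 1))  # population sd
  expect_error(coverage_stats(tr, "c", 1, 1), "invalid interval")
})

test_that("coverage assembly gives 2M offset columns and slices fragment intervals", {
  cs <- contig_set(c("a", "b"), c(random_dna(2000), random_dna(1500)))
  mk_track <- function(sid, d_a, d_b) depth_track(sid, list(
    a = data.frame(start = c(0, 1000), end = c(1000, 2000), depth = c(d_a, 3 * d_a)),
    b = data.frame(start = 0, end = 1500, depth = d_b)), cs$lengths)
  tracks <- list(mk_track("s1", 2, 4), mk_track("s2", 5, 1), mk_track("s3", 1, 1))
  views <- augment_contigs(cs, n_aug = 2, seed = 5)
  C <- assemble_coverage(views, tracks)
  expect_equal(dim(C), c(6L, 6L))          # M = 3 -> 2M columns
  # original contig b in sample 1: uniform 4 -> mean 4, sd 0, plus offset
  rb <- which(views$parent_id == "b" & views$view_index == 0)
  expect_equal(unname(C[rb, "mean.s1"]), 4 + 1e-5)
  expect_equal(unname(C[rb, "sd.s1"]), 0 + 1e-5)
  # fragments use the parent's [start, end) slice
  for (r in which(views$view_index > 0)) {
    tr <- tracks[[2]]
    expect_equal(unname(C[r, "mean.s2"]),
                 coverage_stats(tr, views$parent_id[r], views$start[r],
                                views$end[r])[["mean"]] + 1e-5)
  }
  # a fragment's mean depth is bracketed by the parent's depth range
  fr <- which(views$parent_id == "a" & views$view_index > 0)
  expect_true(all(C[fr, "mean.s1"] >= 2 & C[fr, "mean.s1"] <= 6 + 1e-5))
  expect_error(assemble_coverage(views, list()), "length")
})

test_that("coverage normalization divides by the original-contig column maxima", {
  cs <- contig_set(c("a", "b"), c(random_dna(1000), random_dna(1000)))
  tracks <- list(depth_track("s1", list(
    a = data.frame(start = 0, end = 1000, depth = 2),
    b = data.frame(start = 0, end = 1000, depth = 4)), cs$lengths))
  views <- augment_contigs(cs, n_aug = 0, seed = 1)
  C <- assemble_coverage(views, tracks)
  nc <- normalize_coverage(C, views$view_index)
  expect_equal(nc$x_cov[, 1], (c(2, 4) + 1e-5) / (4 + 1e-5))
  # per column, max over original views is exactly 1
  expect_equal(unname(apply(nc$x_cov, 2, max)), c(1, 1))
  # supplied divisors are honored (inference path)
  nc2 <- normalize_coverage(C, views$view_index, divisors = nc$divisors)
  expect_identical(nc2$x_cov, nc$x_cov)
  # single contig: self-maximum -> all ones
  one <- normalize_coverage(C[1, , drop = FALSE], 0L)
  expect_equal(unname(one$x_cov[1, ]), c(1, 1))
})

test_that("multi-sample coverage uses identical machinery for M tracks", {
  comm <- tiny_community(seed = 13, n_genomes = 2, genome_length = 15000,
                         n_samples = 4)
  views <- augment_contigs(comm$contigs, n_aug = 2, seed = 3)
  fb <- build_features(views, comm$depth_tracks)
  expect_equal(ncol(fb$x_cov), 8L)   # 2M with M = 4
  expect_equal(ncol(fb$x_com), 136L)
  expect_equal(fb$M, 4L)
  orig <- fb$views$view_index == 0
  expect_equal(unname(apply(fb$x_cov[orig, ], 2, max)), rep(1, 8))
  expect_true(all(abs(rowSums(fb$x_com) - 1) < 1e-12))
})
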