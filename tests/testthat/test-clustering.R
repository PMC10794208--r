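test_that("knn graph recovers hand-computed neighbours and brute-force exact sets", {
  # 3 points on a line at 0, 1, 3 with k = 1: edges {0-1, 1-3's nearest}
  X <- matrix(c(0, 1, 3), ncol = 1)
  rownames(X) <- c("p0", "p1", "p3")
  g <- knn_graph(X, k = 1)
  expect_equal(g$edges[c("i", "j")], data.frame(i = c(1L, 2L), j = c(2L, 3L)),
               ignore_attr = TRUE)
  expect_equal(g$edges$d2, c(1, 4))
  expect_true(all(g$edges$i != g$edges$j))   # no self loops
  expect_error(knn_graph(X, k = 3), "must be smaller")

  # exact recall against a brute-force oracle on random points
  set.seed(41)
  N <- 300; d <- 8; k <- 10
  Y <- matrix(rnorm(N * d), N, d)
  rownames(Y) <- paste0("n", 1:N)
  g2 <- knn_graph(Y, k = k, block = 64)
  D <- as.matrix(dist(Y))^2
  hits <- 0
  for (i in 1:N) {
    nn <- order(D[i, setdiff(1:N, i)])
    nn_ids <- setdiff(1:N, i)[nn[1:k]]
    have <- union(g2$edges$j[g2$edges$i == i], g2$edges$i[g2$edges$j == i])
    hits <- hits + length(intersect(nn_ids, have))
  }
  expect_gte(hits / (N * k), 0.99)
  # distances are squared L2
  e1 <- g2$edges[1, ]
  expect_equal(e1$d2, sum((Y[e1$i, ] - Y[e1$j, ])^2), tolerance = 1e-12)
})

test_that("edge filtering keeps the smallest-distance fraction", {
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  rownames(X) <- paste0("n", 1:20)
  g <- knn_graph(X, k = 3)
  expect_identical(filter_edges(g, 1.0), g)
  gf <- filter_edges(g, 0.5)
  expect_equal(nrow(gf$edges), floor(0.5 * nrow(g$edges)))
  dropped <- setdiff(seq_len(nrow(g$edges)),
                     match(paste(gf$edges$i, gf$edges$j),
                           paste(g$edges$i, g$edges$j)))
  expect_lte(max(gf$edges$d2), min(g$edges$d2[dropped]))
})

test_that("similarity kernel follows exp(-d2/sigma)", {
  g <- list(edges = data.frame(i = 1:3, j = c(2L, 3L, 4L), d2 = c(0, 0.2, 1)),
            ids = paste0("n", 1:4), n = 4L, k = 1L)
  class(g) <- "knn_graph"
  sg <- to_similarity(g, sigma = 0.2)
  expect_equal(sg$edges$s, c(1, exp(-1), exp(-5)))
  expect_true(all(sg$edges$s > 0 & sg$edges$s <= 1))
  expect_true(all(diff(sg$edges$s[order(sg$edges$d2)]) <= 0))
})

test_that("seed marker maximizes distinct contigs with lexical tie-break", {
  scg <- scg_table(data.frame(
    contig_id = c("c1", "c2", "c3", "c4", "c5", "c1", "c2", "c3"),
    marker_id = c(rep("m2", 5), rep("m1", 3))))
  expect_equal(pick_seed_marker(scg), "m2")
  tie <- scg_table(data.frame(contig_id = c("c1", "c2", "c1", "c2"),
                              marker_id = c("mB", "mB", "mA", "mA")))
  expect_equal(pick_seed_marker(tie), "mA")
  # duplicates on one contig do not inflate the distinct count
  dup <- scg_table(data.frame(contig_id = c("c1", "c1", "c1", "c2", "c3"),
                              marker_id = c("mA", "mA", "mA", "mB", "mB")))
  expect_equal(pick_seed_marker(dup), "mB")
})

make_clique_graph <- function() {
  # two 5-cliques, no connecting edges
  ed <- expand.grid(i = 1:5, j = 1:5)
  ed <- ed[ed$i < ed$j, ]
  edges <- rbind(ed, ed + 5L)
  edges$d2 <- 0.01
  g <- structure(list(edges = edges, ids = paste0("c", 1:10), n = 10L, k = 4L),
                 class = "knn_graph")
  to_similarity(g, 0.1)
}

test_that("Leiden separates disconnected cliques and honors fixed members", {
  sg <- make_clique_graph()
  lens <- setNames(rep(2000L, 10), sg$ids)
  asg <- leiden_cluster(sg, resolution = 1, contig_lengths = lens, seed = 7)
  expect_equal(length(asg$bin_sizes), 2L)
  expect_equal(length(unique(asg$labels[1:5])), 1L)
  expect_equal(length(unique(asg$labels[6:10])), 1L)
  expect_false(asg$labels[[1]] == asg$labels[[6]])
  expect_equal(unname(asg$bin_sizes), c(10000, 10000), ignore_attr = TRUE)

  # two fixed contigs inside one clique can never merge
  asg2 <- leiden_cluster(sg, 1, lens, fixed_contigs = c("c1", "c2"), seed = 7)
  expect_false(asg2$labels[["c1"]] == asg2$labels[["c2"]])
  # determinism under a fixed seed
  asg3 <- leiden_cluster(sg, 1, lens, fixed_contigs = c("c1", "c2"), seed = 7)
  expect_identical(asg2$labels, asg3$labels)
})

test_that("bin count does not decrease from low to very high resolution", {
  set.seed(43)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  rownames(X) <- paste0("n", 1:60)
  lens <- setNames(rep(1500L, 60), rownames(X))
  sg <- to_similarity(knn_graph(X, k = 8), 0.2)
  n_bins <- sapply(c(0.1, 50, 5000), function(res) {
    length(leiden_cluster(sg, res, lens, seed = 3)$bin_sizes)
  })
  expect_lte(n_bins[1], n_bins[2])
  expect_lte(n_bins[2], n_bins[3])
})

test_that("SCG quality estimates follow the distinct/duplicate marker formula", {
  lens <- setNames(rep(1000L, 12), paste0("c", 1:12))
  universe <- sprintf("m%02d", 1:10)
  # bin A: all 10 markers once; bin B: 5 markers, one duplicated
  hits <- data.frame(
    contig_id = c(paste0("c", 1:10), "c11", "c11", "c12", "c12", "c12", "c12"),
    marker_id = c(universe, "m01", "m01", "m02", "m03", "m04", "m05"))
  scg <- scg_table(hits, marker_universe = universe)
  labels <- setNames(c(rep("A", 10), rep("B", 2)), paste0("c", 1:12))
  q <- estimate_quality(bin_assignment(labels, lens), scg)
  pa <- q$per_bin[q$per_bin$bin_id == "A", ]
  pb <- q$per_bin[q$per_bin$bin_id == "B", ]
  expect_equal(c(pa$completeness, pa$contamination), c(100, 0))
  expect_equal(c(pb$completeness, pb$contamination), c(50, 10))
  # A passes all six thresholds; B passes none (50 is not > 50)
  expect_equal(q$score, 6L + 0L)
  # relabeling bins leaves the score unchanged
  labels2 <- setNames(c(rep("zz", 10), rep("aa", 2)), paste0("c", 1:12))
  expect_equal(estimate_quality(bin_assignment(labels2, lens), scg)$score,
               q$score)
  # empty universe: zero estimates with a warning
  empty <- scg_table(data.frame(contig_id = character(0),
                                marker_id = character(0)),
                     marker_universe = character(0))
  expect_warning(q0 <- estimate_quality(bin_assignment(labels, lens), empty),
                 "empty marker universe")
  expect_equal(q0$score, 0L)
})

test_that("quality thresholds are strict as printed", {
  lens <- setNames(rep(1000L, 40), paste0("c", 1:40))
  universe <- sprintf("m%02d", 1:20)
  # exactly 50% completeness, 5% contamination: passes only cont<10 cells? no:
  # completeness must EXCEED 50 -> fails all completeness gates
  hits <- data.frame(contig_id = rep("c1", 11),
                     marker_id = c(universe[1:10], "m01"))
  scg <- scg_table(hits, marker_universe = universe)
  q <- estimate_quality(bin_assignment(setNames("A", "c1"), lens), scg)
  expect_equal(q$per_bin$completeness, 50)
  expect_equal(q$per_bin$contamination, 5)
  expect_equal(q$score, 0L)
})

test_that("small bins are removed strictly below the threshold", {
  lens <- c(a = 150000, b = 120000, c = 130000, d = 80000, e = 200000)
  labels <- setNames(c("x", "y", "y", "z", "w"), names(lens))
  asg <- bin_assignment(labels, lens)
  filt <- filter_small_bins(asg, lens)
  # x: 150k dropped; y: 250k kept; z: 80k dropped; w: exactly 200k kept
  expect_setequal(names(filt$bin_sizes), c("y", "w"))
  expect_setequal(names(filt$labels), c("b", "c", "e"))
  empty <- bin_assignment(setNames(character(0), character(0)), lens)
  expect_equal(length(filter_small_bins(empty, lens)$labels), 0L)
})

test_that("selection is a deterministic argmax over cached partitions", {
  lens <- setNames(rep(60000L, 10), paste0("c", 1:10))
  universe <- sprintf("m%02d", 1:5)
  hits <- data.frame(contig_id = paste0("c", 1:5), marker_id = universe)
  scg <- scg_table(hits, marker_universe = universe)
  good <- bin_assignment(setNames(rep("A", 5), paste0("c", 1:5)), lens,
                         params = list(sigma = 0.1, resolution = 1, edge_ratio = 1))
  bad <- bin_assignment(setNames(c("A", "A", "B", "B", "B"), paste0("c", 1:5)),
                        lens,
                        params = list(sigma = 0.2, resolution = 5, edge_ratio = 1))
  sel <- select_best(list(bad, good), scg)
  expect_equal(sel$best, 2L)
  # bad: bin A 40% complete, bin B 60%/0% passes two cells
  expect_equal(sel$scores, c(2L, 6L))
  # rerunning on the cached partitions reproduces the choice
  expect_equal(select_best(list(bad, good), scg)$best, 2L)
  # tie -> first in sweep order
  sel2 <- select_best(list(good, good), scg)
  expect_equal(sel2$best, 1L)
  # no SCG hits anywhere: all scores zero, first combination with a warning
  no_hits <- scg_table(data.frame(contig_id = character(0),
                                  marker_id = character(0)),
                       marker_universe = universe)
  expect_warning(sel3 <- select_best(list(bad, good), no_hits),
                 "score 0 everywhere")
  expect_equal(sel3$best, 1L)
})
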