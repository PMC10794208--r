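test_that("temperature follows the N50 rule", {
  expect_equal(tau_from_n50(50000), 0.07)
  expect_equal(tau_from_n50(10001), 0.07)
  expect_equal(tau_from_n50(10000), 0.15)
  expect_equal(tau_from_n50(5000), 0.15)
})

test_that("encoder forward has the contracted shapes and is deterministic in eval mode", {
  cfg <- small_encoder(latent = 32)
  params <- contrabin:::encoder_init(cfg, dim_cov = 6, dim_com = 136)
  # combine network input width = cov_out_dim + composition dim
  expect_equal(nrow(params$combine$W[[1]]), cfg$cov_out_dim + 136L)
  x_cov <- matrix(runif(10 * 6, 0.1, 1), 10, 6)
  x_com <- matrix(runif(10 * 136, 0.001, 0.02), 10, 136)
  z1 <- encoder_forward(params, x_cov, x_com)
  z2 <- encoder_forward(params, x_cov, x_com)
  expect_equal(dim(z1), c(10L, 32L))
  expect_identical(z1, z2)
  expect_true(all(is.finite(z1)))
  expect_error(encoder_forward(params, x_cov[, 1:3], x_com), "do not match")
})

test_that("encoder backprop matches finite differences through both networks", {
  set.seed(90)
  cfg <- encoder_config(cov_hidden = c(7, 6), cov_out_dim = 5,
                        combine_hidden = c(8, 7), latent_dim = 4, dropout = 0)
  params <- contrabin:::encoder_init(cfg, dim_cov = 4, dim_com = 6)
  N <- 3; V <- 2
  x_cov <- matrix(runif(N * V * 4, 0.1, 1), N * V, 4)
  x_com <- matrix(runif(N * V * 6, 0.01, 0.1), N * V, 6)
  fwd <- encoder_forward(params, x_cov, x_com, training = TRUE)
  lg <- contrabin:::multiview_loss_grad(fwd$z, 0.15, V)
  g <- contrabin:::encoder_backward(params, fwd, lg$grad)
  flat <- contrabin:::encoder_flatten(params)
  gflat <- contrabin:::grads_flatten(g)
  lossfn <- function(p) loss_multiview(encoder_forward(p, x_cov, x_com), 0.15, V)
  eps <- 1e-6
  for (pi in seq_along(flat)) {
    for (ii in sample(length(flat[[pi]]), 3)) {
      fp <- flat; fp[[pi]][ii] <- fp[[pi]][ii] + eps
      fm <- flat; fm[[pi]][ii] <- fm[[pi]][ii] - eps
      fd <- (lossfn(contrabin:::encoder_unflatten(params, fp)) -
             lossfn(contrabin:::encoder_unflatten(params, fm))) / (2 * eps)
      expect_lt(abs(gflat[[pi]][ii] - fd), 1e-5)
    }
  }
})

comm_train <- tiny_community(seed = 17, n_genomes = 4, genome_length = 60000,
                             n_samples = 3)
views_train <- augment_contigs(comm_train$contigs, seed = 4)
feats_train <- build_features(views_train, comm_train$depth_tracks)

test_that("training reduces the contrastive loss and is seed-reproducible", {
  tcfg <- train_config(epochs = 12, batch_size = 64, seed = 5,
                       early_stop_patience = 12)
  m1 <- train_encoder(feats_train, small_encoder(), tcfg,
                      assembly_n50 = comm_train$contigs$n50)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  expect_equal(m1$tau, 0.15)   # N50 well below 10 kbp
  m2 <- train_encoder(feats_train, small_encoder(), tcfg,
                      assembly_n50 = comm_train$contigs$n50)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params$combine$W[[3]], m2$params$combine$W[[3]])
})

test_that("embeddings separate genomes: intra-genome cosine exceeds inter-genome", {
  tcfg <- train_config(epochs = 40, batch_size = 128, seed = 6)
  model <- train_encoder(feats_train, small_encoder(), tcfg,
                         assembly_n50 = comm_train$contigs$n50)
  Z <- embed_contigs(model, feats_train)
  expect_equal(nrow(Z), length(comm_train$contigs))
  expect_identical(Z, embed_contigs(model, feats_train))
  lab <- comm_train$truth[rownames(Z)]
  Zn <- Z / sqrt(rowSums(Z^2))
  S <- tcrossprod(Zn)
  same <- outer(lab, lab, "==")
  diag(S) <- NA
  expect_gt(mean(S[same], na.rm = TRUE), mean(S[!same]))

  # parameter-recovery smoke check at this reduced scale; the full-strength
  # k-means bound runs on the canonical community in the acceptance suite
  km <- stats::kmeans(Z, centers = 4, nstart = 10)
  expect_gte(ari(km$cluster, lab), 0.75)

  # checkpoint round-trip preserves the model
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  expect_identical(embed_contigs(load_checkpoint(ck), feats_train), Z)
  expect_error(embed_contigs(structure(list(), class = "list"), feats_train),
               "not a trained encoder")
})
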