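#' Default contrastive temperature from assembly N50
#'
#' Fragmented assemblies (low N50) produce noisier views, so a softer
#' temperature is used: `tau = 0.07` when `N50 > 10000` bp, else `0.15`.
#'
#' @param n50 Assembly N50 in bp.
#' @return Temperature value.
#' @export
tau_from_n50 <- function(n50) {
  if (n50 > 10000) 0.07 else 0.15
}

#' Training configuration
#'
#' @param tau Temperature; `NULL` selects it from the assembly N50 via
#'   [tau_from_n50()] at training time.
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Contigs per batch (default 1024); each batch carries
#'   all `V` views of its contigs. Capped at the number of contigs.
#' @param lr Peak Adam learning rate.
#' @param lr_schedule `"cosine"` (default) decays the learning rate from
#'   `lr` to 0 over `epochs` with a half-cosine — high early for cluster
#'   cohesion, vanishing late so prolonged training cannot collapse the
#'   genome structure into contrastive uniformity; `"constant"` keeps `lr`
#'   fixed.
#' @param early_stop_patience Stop when the epoch-mean loss has not improved
#'   by more than `min_delta` for this many epochs.
#' @param min_delta Minimum improvement counted by early stopping.
#' @param seed Integer seed; fully determines initialization, shuffling and
#'   dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(tau = NULL, epochs = 200L, batch_size = 1024L,
                         lr = 1e-3, lr_schedule = c("cosine", "constant"),
                         early_stop_patience = 10L,
                         min_delta = 1e-4, seed = 1L) {
  stopifnot(is.null(tau) || tau > 0, epochs >= 1, batch_size >= 1, lr > 0)
  lr_schedule <- match.arg(lr_schedule)
  structure(list(tau = tau, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = lr_schedule, optimizer = "adam",
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the contrastive encoders
#'
#' Minimizes the multi-view NT-Xent objective over mini-batches of contigs:
#' each batch samples `batch_size` contigs, gathers all `V` of their views,
#' embeds them with the coverage/combine encoder pair and applies an Adam
#' step on the analytic gradient. Contig order is reshuffled every epoch; a
#' final incomplete batch is dropped (the loss needs a fixed negative-set
#' structure), except when fewer contigs than `batch_size` exist, in which
#' case the whole set forms one batch. Training stops early when the
#' epoch-mean loss plateaus.
#'
#' @param features A `feature_block` covering all views (see
#'   [build_features()]).
#' @param encoder_cfg An [encoder_config()].
#' @param train_cfg A [train_config()].
#' @param assembly_n50 Assembly N50 in bp, used to pick `tau` when
#'   `train_cfg$tau` is `NULL`.
#' @param verbose Log per-epoch losses.
#' @return A `trained_encoder`: list with `params`, `loss_history` (one
#'   epoch-mean loss per epoch run), `tau`, both configs and the feature
#'   column metadata needed at inference.
#' @export
train_encoder <- function(features, encoder_cfg = encoder_config(),
                          train_cfg = train_config(), assembly_n50 = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(features, "feature_block"))
  tau <- train_cfg$tau
  if (is.null(tau)) {
    if (is.null(assembly_n50)) {
      stop("provide assembly_n50 or an explicit tau in train_config()")
    }
    tau <- tau_from_n50(assembly_n50)
  }
  vi <- features$views$view_index
  V <- max(vi) + 1L
  if (V < 2) stop("need at least 2 views per contig to train")
  contig_ids <- unique(features$views$parent_id)
  N <- length(contig_ids)
  # row indices of each contig's views, in view order
  ord <- order(match(features$views$parent_id, contig_ids), vi)
  row_of <- matrix(ord, nrow = V)   # V x N: column j = rows of contig j

  bs <- min(train_cfg$batch_size, N)
  params <- with_seed(derive_seed(train_cfg$seed, "init"),
                      encoder_init(encoder_cfg, ncol(features$x_cov),
                                   ncol(features$x_com)))
  opt <- adam_init(encoder_flatten(params))
  loss_history <- numeric(0)
  best <- Inf
  stale <- 0L

  set.seed(derive_seed(train_cfg$seed, "epochs"))
  sched <- if (identical(train_cfg$lr_schedule, "constant")) {
    rep(train_cfg$lr, train_cfg$epochs)
  } else {
    train_cfg$lr * 0.5 *
      (1 + cos(pi * (seq_len(train_cfg$epochs) - 1L) / train_cfg$epochs))
  }
  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample.int(N)
    n_batches <- max(1L, N %/% bs)
    batch_losses <- numeric(0)
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * bs + 1L):(b * bs)]
      rows <- as.vector(row_of[, idx])   # grouped by contig, V rows each
      fwd <- encoder_forward(params,
                             features$x_cov[rows, , drop = FALSE],
                             features$x_com[rows, , drop = FALSE],
                             training = TRUE)
      lg <- multiview_loss_grad(fwd$z, tau, V)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d batch %d; try a lower lr",
                     epoch, b))
      }
      g <- encoder_backward(params, fwd, lg$grad)
      st <- adam_step(encoder_flatten(params), grads_flatten(g), opt,
                      lr = sched[epoch])
      params <- encoder_unflatten(params, st$params)
      opt <- st$state
      batch_losses <- c(batch_losses, lg$loss)
    }
    epoch_loss <- mean(batch_losses)
    loss_history <- c(loss_history, epoch_loss)
    if (verbose) cb_log("train", "epoch %d: loss %.5f", epoch, epoch_loss)
    if (epoch_loss < best - train_cfg$min_delta) {
      best <- epoch_loss
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$early_stop_patience) {
        if (verbose) cb_log("train", "early stop at epoch %d", epoch)
        break
      }
    }
  }
  structure(list(params = params, loss_history = loss_history, tau = tau,
                 encoder_cfg = encoder_cfg, train_cfg = train_cfg,
                 feature_meta = list(dim_cov = ncol(features$x_cov),
                                     dim_com = ncol(features$x_com),
                                     divisors = features$divisors,
                                     M = features$M),
                 version = 1L),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("trained_encoder: latent %d, tau %.2f, %d epochs, final loss %.4f\n",
              x$encoder_cfg$latent_dim, x$tau, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Embed the original contigs
#'
#' Runs the trained encoders in evaluation mode (no dropout) on the
#' original-contig views only (`view_index == 0`); the resulting matrix is
#' the clustering input.
#'
#' @param model A `trained_encoder`.
#' @param features The `feature_block` the model was trained on (or one
#'   built with the same column layout and divisors).
#' @return Numeric matrix `N x latent_dim`, rownames = contig ids.
#' @export
embed_contigs <- function(model, features) {
  if (!inherits(model, "trained_encoder")) {
    stop("`model` is not a trained encoder; run train_encoder() first")
  }
  orig <- features$views$view_index == 0L
  Z <- encoder_forward(model$params,
                       features$x_cov[orig, , drop = FALSE],
                       features$x_com[orig, , drop = FALSE],
                       training = FALSE)
  rownames(Z) <- features$views$parent_id[orig]
  Z
}

#' Save / load a trained encoder checkpoint
#'
#' @param model A `trained_encoder`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "trained_encoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_encoder") || is.null(model$version)) {
    stop("not a valid checkpoint: ", path)
  }
  model
}
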