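# Three-layer feed-forward networks on plain matrices. Each network is a
# list of weight matrices W[[l]] (d_in x d_out) and bias vectors b[[l]];
# hidden layers use LeakyReLU and (inverted) dropout, the final layer is
# affine. Forward passes cache activations for the analytic backward pass.

LEAKY_SLOPE <- 0.01

mlp_init <- function(d_in, hidden, d_out) {
  sizes <- c(d_in, hidden, d_out)
  stopifnot(length(sizes) == 4, all(sizes >= 1))  # 3 affine layers
  W <- vector("list", 3)
  b <- vector("list", 3)
  for (l in 1:3) {
    # He-normal initialization, suited to rectifier activations
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

leaky_relu <- function(x) ifelse(x > 0, x, LEAKY_SLOPE * x)

mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  cache <- list(X = X, pre = vector("list", 3), act = vector("list", 3),
                mask = vector("list", 3))
  H <- X
  for (l in 1:3) {
    A <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    cache$pre[[l]] <- A
    if (l < 3) {
      H <- leaky_relu(A)
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                    nrow(H), ncol(H))
        cache$mask[[l]] <- m
        H <- H * m
      }
    } else {
      H <- A
    }
    cache$act[[l]] <- H
  }
  list(out = H, cache = cache)
}

mlp_backward <- function(net, cache, dOut) {
  gW <- vector("list", 3)
  gb <- vector("list", 3)
  dH <- dOut
  for (l in 3:1) {
    if (l < 3) {
      if (!is.null(cache$mask[[l]])) dH <- dH * cache$mask[[l]]
      A <- cache$pre[[l]]
      dH <- dH * ifelse(A > 0, 1, LEAKY_SLOPE)
    }
    Hin <- if (l == 1) cache$X else cache$act[[l - 1]]
    gW[[l]] <- crossprod(Hin, dH)
    gb[[l]] <- colSums(dH)
    dH <- tcrossprod(dH, net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = dH)
}

# Adam optimizer state over a flat list of parameter matrices/vectors.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Encoder configuration
#'
#' Architecture of the two three-layer feed-forward encoders. The coverage
#' network embeds the `2M`-dimensional coverage vector; its output is
#' L2-normalized and concatenated with the 136-dimensional composition
#' vector as input to the combine network, whose output is the contig
#' embedding used both in the contrastive objective and for clustering (no
#' separate projection head). Layer widths are package defaults exposed here
#' for tuning; smaller widths are adequate for small communities.
#'
#' @param cov_hidden Two hidden widths of the coverage network.
#' @param cov_out_dim Coverage embedding size.
#' @param combine_hidden Two hidden widths of the combine network.
#' @param latent_dim Final embedding size.
#' @param dropout Dropout rate on hidden layers during training.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(cov_hidden = c(2048L, 2048L), cov_out_dim = 2048L,
                           combine_hidden = c(2048L, 2048L), latent_dim = 128L,
                           dropout = 0.2) {
  stopifnot(length(cov_hidden) == 2, length(combine_hidden) == 2,
            all(c(cov_hidden, combine_hidden, cov_out_dim, latent_dim) >= 1),
            dropout >= 0, dropout < 1)
  structure(list(cov_hidden = as.integer(cov_hidden),
                 cov_out_dim = as.integer(cov_out_dim),
                 combine_hidden = as.integer(combine_hidden),
                 latent_dim = as.integer(latent_dim),
                 activation = "leaky_relu", dropout = dropout),
            class = "encoder_config")
}

# Initialize both networks for given input dims.
encoder_init <- function(cfg, dim_cov, dim_com) {
  list(cov = mlp_init(dim_cov, cfg$cov_hidden, cfg$cov_out_dim),
       combine = mlp_init(cfg$cov_out_dim + dim_com, cfg$combine_hidden,
                          cfg$latent_dim),
       dim_cov = dim_cov, dim_com = dim_com, cfg = cfg)
}

#' Forward pass through the encoder pair
#'
#' `z = f_combine( [ l2norm(f_cov(x_cov)), x_com ] )`. Deterministic when
#' `training = FALSE` (no dropout).
#'
#' @param params Encoder parameters (from [train_encoder()] or internal
#'   initialization).
#' @param x_cov Coverage feature matrix (`n x 2M`).
#' @param x_com Composition feature matrix (`n x T`).
#' @param training Apply dropout and cache activations for backprop.
#' @return If `training = FALSE`, the `n x latent_dim` embedding matrix;
#'   otherwise a list with `z` and the forward caches.
#' @export
encoder_forward <- function(params, x_cov, x_com, training = FALSE) {
  if (ncol(x_cov) != params$dim_cov || ncol(x_com) != params$dim_com) {
    stop(sprintf("feature dims (%d, %d) do not match encoder (%d, %d)",
                 ncol(x_cov), ncol(x_com), params$dim_cov, params$dim_com))
  }
  p <- params$cfg$dropout
  fc <- mlp_forward(params$cov, x_cov, dropout = p, training = training)
  nrm <- sqrt(rowSums(fc$out^2))
  if (any(nrm == 0)) stop("zero coverage embedding; cannot normalize")
  cov_n <- fc$out / nrm
  inp <- cbind(cov_n, x_com)
  fm <- mlp_forward(params$combine, inp, dropout = p, training = training)
  if (!training) return(fm$out)
  list(z = fm$out, cov_cache = fc$cache, combine_cache = fm$cache,
       cov_out = fc$out, cov_norm = nrm, cov_n = cov_n)
}

# Backward: gradient of loss wrt all encoder parameters given dL/dz.
encoder_backward <- function(params, fwd, dZ) {
  bc <- mlp_backward(params$combine, fwd$combine_cache, dZ)
  dCovN <- bc$dX[, seq_len(params$cfg$cov_out_dim), drop = FALSE]
  # back through row L2 normalization of the coverage embedding
  dCov <- (dCovN - fwd$cov_n * rowSums(fwd$cov_n * dCovN)) / fwd$cov_norm
  cc <- mlp_backward(params$cov, fwd$cov_cache, dCov)
  list(cov = cc, combine = bc)
}

# Flatten/unflatten parameters for the optimizer.
encoder_flatten <- function(params) c(params$cov$W, params$cov$b,
                                      params$combine$W, params$combine$b)

encoder_unflatten <- function(params, flat) {
  params$cov$W <- flat[1:3]
  params$cov$b <- flat[4:6]
  params$combine$W <- flat[7:9]
  params$combine$b <- flat[10:12]
  params
}

grads_flatten <- function(g) c(g$cov$gW, g$cov$gb, g$combine$gW, g$combine$gb)
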