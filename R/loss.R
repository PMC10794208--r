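#' Cosine similarity
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return `a . b / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Row-normalize a matrix to unit L2 norm.
l2_normalize_rows <- function(Z) {
  nrm <- sqrt(rowSums(Z * Z))
  if (any(nrm == 0)) stop("zero embedding row; cannot normalize")
  Z / nrm
}

#' NT-Xent loss for one ordered view pair
#'
#' The normalized temperature-scaled cross-entropy for anchor view `k` and
#' positive view `k2` of contig `i` in a batch of `N_bs` contigs with two
#' views each. The denominator sums, over all contigs `s`, the anchor's
#' similarity to view `k` of `s` (excluded when `s == i`) and to view `k2`
#' of `s` (included for all `s`, so the positive term itself appears once).
#'
#' @param Z List of two `N_bs x d` matrices, one per view (row `i` of each
#'   is the embedding of the corresponding view of contig `i`).
#' @param i Anchor contig index (1-based).
#' @param k,k2 Anchor and positive view indices (1 or 2), `k != k2`.
#' @param tau Temperature (> 0).
#' @return The scalar loss term.
#' @export
ntxent_pair <- function(Z, i, k, k2, tau) {
  stopifnot(tau > 0, k != k2, is.list(Z), length(Z) == 2)
  Zk <- Z[[k]]
  Zk2 <- Z[[k2]]
  n <- nrow(Zk)
  anchor <- Zk[i, ]
  num <- exp(cosine(anchor, Zk2[i, ]) / tau)
  den <- 0
  for (s in seq_len(n)) {
    if (s != i) den <- den + exp(cosine(anchor, Zk[s, ]) / tau)
    den <- den + exp(cosine(anchor, Zk2[s, ]) / tau)
  }
  -log(num / den)
}

#' Two-view NT-Xent batch loss
#'
#' Symmetric average of [ntxent_pair()] over both orderings of the two views
#' of every contig in the batch.
#'
#' @inheritParams ntxent_pair
#' @return Scalar loss.
#' @export
loss_2view <- function(Z, tau) {
  stopifnot(is.list(Z))
  if (length(Z) != 2) stop("loss_2view requires exactly 2 views")
  n <- nrow(Z[[1]])
  total <- 0
  for (i in seq_len(n)) {
    total <- total + ntxent_pair(Z, i, 1, 2, tau) + ntxent_pair(Z, i, 2, 1, tau)
  }
  total / (2 * n)
}

#' Multi-view NT-Xent batch loss
#'
#' Extension of the two-view loss to `V` views per contig: in a batch of
#' `N_bs` contigs, all `V(V-1)` ordered view pairs of a contig are positive
#' pairs, and for an anchor view the negatives are all `V` views of every
#' other contig in the batch (the anchor contig's remaining views are not in
#' the denominator). With `V = 2` this reduces exactly to [loss_2view()].
#'
#' @param Z Numeric matrix `(N_bs * V) x d`, rows grouped by contig (views
#'   of contig 1, then contig 2, ...), or an `N_bs x V x d` array.
#' @param tau Temperature (> 0).
#' @param V Number of views per contig (>= 2).
#' @return Scalar loss (0 when `N_bs == 1`: the negative sum is empty and
#'   each positive term is its own denominator).
#' @export
loss_multiview <- function(Z, tau, V) {
  stopifnot(tau > 0, V >= 2)
  if (length(dim(Z)) == 3) {
    d <- dim(Z)
    Z <- matrix(aperm(Z, c(2, 1, 3)), nrow = d[1] * d[2])
  }
  n_rows <- nrow(Z)
  if (n_rows %% V != 0) stop("rows of Z not a multiple of V")
  N <- n_rows %/% V
  contig <- rep(seq_len(N), each = V)
  Zn <- l2_normalize_rows(Z)
  E <- exp(tcrossprod(Zn) / tau)               # E[a, b] = exp(cos/tau)
  same <- outer(contig, contig, "==")
  neg_sum <- rowSums(E * !same)                # all views of other contigs
  total <- 0
  for (i in seq_len(N)) {
    rows <- which(contig == i)
    for (v in rows) {
      for (v1 in rows) {
        if (v1 == v) next
        total <- total - log(E[v, v1] / (E[v, v1] + neg_sum[v]))
      }
    }
  }
  total / (N * V * (V - 1))
}

# Loss and gradient of the multi-view NT-Xent objective with respect to the
# raw (unnormalized) embedding rows. Vectorized over the full batch; used by
# the training loop. Returns list(loss, grad) with grad the same shape as Z.
multiview_loss_grad <- function(Z, tau, V) {
  n_rows <- nrow(Z)
  N <- n_rows %/% V
  stopifnot(n_rows == N * V, N >= 1, V >= 2)
  contig <- rep(seq_len(N), each = V)
  nrm <- sqrt(rowSums(Z * Z))
  Zn <- Z / nrm
  S <- tcrossprod(Zn)
  E <- exp(S / tau)
  same <- outer(contig, contig, "==")
  pos_mask <- same
  diag(pos_mask) <- FALSE
  neg_sum <- rowSums(E * !same)

  # D[a, p] = E[a, p] + neg_sum[a] for positive pairs (a, p)
  cden <- 1 / (N * V * (V - 1))
  loss <- 0
  # gradient wrt S
  G <- matrix(0, n_rows, n_rows)
  inv_sum <- numeric(n_rows)   # sum over positives p of 1/D[a, p]
  for (a in seq_len(n_rows)) {
    prows <- which(pos_mask[a, ])
    D <- E[a, prows] + neg_sum[a]
    loss <- loss - sum(log(E[a, prows] / D))
    inv_sum[a] <- sum(1 / D)
    G[a, prows] <- (cden / tau) * (E[a, prows] / D - 1)
  }
  loss <- loss * cden
  G <- G + (cden / tau) * (E * !same) * inv_sum  # negatives, row-broadcast
  # back through S = Zn Zn^T, then through row normalization
  dZn <- G %*% Zn + crossprod(G, Zn)
  grad <- (dZn - Zn * rowSums(Zn * dZn)) / nrm
  list(loss = loss, grad = grad)
}
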