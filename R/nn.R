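# Low-level numerical core of the tiny3d classifier.
#
# The network consumes a 64^3 instance, min-max normalized to [0, 1]:
#   fixed 4x average pool  -> 16^3 x 1
#   conv 3^3 (1 -> C1), pad 1, ReLU
#   2x average pool        -> 8^3 x C1
#   conv 3^3 (C1 -> C2), pad 1, ReLU
#   global average pool    -> C2
#   fully connected        -> 2 logits (normal, anomalous)
# Convolutions are evaluated as im2col gathers followed by one BLAS matrix
# multiplication per layer; batches are laid out as (n * voxels) x channels
# matrices with the sample index fastest.

# cache of index vectors, keyed by grid size / batch size
.nn_cache <- new.env(parent = emptyenv())

# linear 1-based indices into the zero-padded (D+2)^3 grid for each of the
# 27 kernel offsets, rows ordered like the voxels of the D^3 grid (x fastest)
im2col_index <- function(D) {
  key <- paste0("idx", D)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Dp <- D + 2L
  g <- expand.grid(x = 0:(D - 1), y = 0:(D - 1), z = 0:(D - 1))
  off <- expand.grid(dx = 0:2, dy = 0:2, dz = 0:2)
  idx <- matrix(0L, D^3, 27L)
  for (o in seq_len(27)) {
    idx[, o] <- 1L + (g$x + off$dx[o]) + (g$y + off$dy[o]) * Dp +
      (g$z + off$dz[o]) * Dp^2
  }
  .nn_cache[[key]] <- idx
  idx
}

# X: (n * D^3) x Cin matrix, sample index fastest within each voxel block.
# Returns (n * D^3) x (27 * Cin) column matrix M with M %*% W performing the
# 3^3 convolution (zero padding, stride 1).
im2col3d <- function(X, n, D, Cin) {
  Dp <- D + 2L
  pad <- array(0, c(n, Dp, Dp, Dp, Cin))
  pad[, 2:(Dp - 1), 2:(Dp - 1), 2:(Dp - 1), ] <- array(X, c(n, D, D, D, Cin))
  padm <- matrix(pad, nrow = n)                 # n x (Dp^3 * Cin)
  idx <- im2col_index(D)
  # columns ordered (voxel within offset within channel); channel-major blocks
  bigidx <- integer(0)
  for (c in seq_len(Cin) - 1L) for (o in seq_len(27))
    bigidx <- c(bigidx, idx[, o] + c * Dp^3)
  M <- padm[, bigidx, drop = FALSE]
  dim(M) <- c(n * D^3, 27L * Cin)
  M
}

# scatter-add adjoint of im2col3d: dM is (n * D^3) x (27 * Cin);
# returns gradient w.r.t. the unpadded input, (n * D^3) x Cin
col2im3d <- function(dM, n, D, Cin) {
  Dp <- D + 2L
  idx <- im2col_index(D)
  dpadm <- matrix(0, n, Dp^3 * Cin)
  for (c in seq_len(Cin) - 1L) {
    for (o in seq_len(27)) {
      col <- c * 27L + o
      block <- matrix(dM[, col], n, D^3)        # n x D^3 slab for this offset
      target <- idx[, o] + c * Dp^3
      dpadm[, target] <- dpadm[, target] + block
    }
  }
  dpad <- array(dpadm, c(n, Dp, Dp, Dp, Cin))
  dX <- dpad[, 2:(Dp - 1), 2:(Dp - 1), 2:(Dp - 1), , drop = FALSE]
  dim(dX) <- c(n * D^3, Cin)
  dX
}

# 2x average pooling on (n * D^3) x C -> (n * (D/2)^3) x C; also returns the
# parent map used by the backward pass
pool_children <- function(D) {
  key <- paste0("pool", D)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  h <- D / 2L
  g <- expand.grid(x = 0:(D - 1), y = 0:(D - 1), z = 0:(D - 1))
  parent <- 1L + (g$x %/% 2L) + (g$y %/% 2L) * h + (g$z %/% 2L) * h^2
  .nn_cache[[key]] <- parent                    # length D^3, values in 1..h^3
  parent
}

avgpool2_fwd <- function(A, n, D, C) {
  h <- D %/% 2L
  parent <- pool_children(D)
  out <- matrix(0, n * h^3, C)
  for (v in seq_len(D^3)) {
    rows_src <- ((v - 1L) * n + 1L):(v * n)
    rows_dst <- ((parent[v] - 1L) * n + 1L):(parent[v] * n)
    out[rows_dst, ] <- out[rows_dst, ] + A[rows_src, ]
  }
  out / 8
}

# vectorized forward pool: reshape route (much faster than the loop above)
avgpool2_fast <- function(A, n, D, C) {
  h <- D %/% 2L
  a <- array(A, c(n, 2L, h, 2L, h, 2L, h, C))
  a <- aperm(a, c(1, 3, 5, 7, 2, 4, 6, 8))     # n, h, h, h, 2,2,2, C
  dim(a) <- c(n * h^3, 8L * C)
  out <- matrix(0, n * h^3, C)
  for (j in seq_len(8))
    out <- out + a[, seq.int(j, by = 8L, length.out = C), drop = FALSE]
  out / 8
}

avgpool2_bwd <- function(dOut, n, D, C) {
  h <- D %/% 2L
  parent <- pool_children(D)
  rowidx <- rep((parent - 1L) * n, each = n) + rep.int(seq_len(n), D^3)
  dOut[rowidx, , drop = FALSE] / 8
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# --- parameter initialization ------------------------------------------------

tiny3d_init <- function(c1 = 8L, c2 = 16L, seed = NULL) {
  with_seed(seed, {
    he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    list(W1 = he(27, 27L, c1), b1 = numeric(c1),
         W2 = he(27 * c1, 27L * c1, c2), b2 = numeric(c2),
         Wf = he(c2, c2, 2L), bf = numeric(2L),
         c1 = c1, c2 = c2)
  })
}

# --- forward / backward ------------------------------------------------------

# X: n x 4096 matrix of pooled 16^3 features (one row per instance)
tiny3d_forward <- function(par, X, keep = FALSE) {
  n <- nrow(X)
  c1 <- par$c1; c2 <- par$c2
  # rows must be sample-fastest within voxel: column v of X -> rows (v-1)n+1..vn,
  # which is exactly the column-major flattening of the n x 4096 matrix
  X0 <- matrix(X, n * 4096L, 1L)
  M1 <- im2col3d(X0, n, 16L, 1L)
  Z1 <- sweep(M1 %*% par$W1, 2, par$b1, "+")
  A1 <- relu(Z1)
  P1 <- avgpool2_fast(A1, n, 16L, c1)           # (n*512) x c1
  M2 <- im2col3d(P1, n, 8L, c1)
  Z2 <- sweep(M2 %*% par$W2, 2, par$b2, "+")
  A2 <- relu(Z2)                                # (n*512) x c2
  g <- matrix(0, n, c2)                         # global average pool
  for (c in seq_len(c2)) g[, c] <- rowSums(matrix(A2[, c], n, 512L)) / 512
  logits <- sweep(g %*% par$Wf, 2, par$bf, "+")
  out <- list(logits = logits, probs = softmax_rows(logits))
  if (keep) out <- c(out, list(M1 = M1, Z1 = Z1, P1 = P1, M2 = M2, Z2 = Z2,
                               A2 = A2, g = g, n = n))
  out
}

# cross-entropy loss and parameter gradients for one batch.
# y: integer vector of 0/1 labels (1 = anomalous = class column 2)
tiny3d_backward <- function(par, cache, y) {
  n <- cache$n
  c1 <- par$c1; c2 <- par$c2
  Y <- matrix(c(1 - y, y), ncol = 2L)
  dlogits <- (cache$probs - Y) / n
  dWf <- crossprod(cache$g, dlogits)
  dbf <- colSums(dlogits)
  dg <- dlogits %*% t(par$Wf)                   # n x c2
  dA2 <- dg[rep.int(seq_len(n), 512L), , drop = FALSE] / 512
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(par$W2)
  dP1 <- col2im3d(dM2, n, 8L, c1)
  dA1 <- avgpool2_bwd(dP1, n, 16L, c1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$M1, dZ1)
  db1 <- colSums(dZ1)
  eps <- 1e-12
  loss <- -mean(log(pmax(ifelse(y == 1, cache$probs[, 2], cache$probs[, 1]), eps)))
  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wf = dWf, bf = dbf))
}

tiny3d_loss <- function(par, X, y) {
  p <- tiny3d_forward(par, X)$probs
  eps <- 1e-12
  -mean(log(pmax(ifelse(y == 1, p[, 2], p[, 1]), eps)))
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(par) {
  nm <- c("W1", "b1", "W2", "b2", "Wf", "bf")
  list(m = lapply(par[nm], function(w) w * 0),
       v = lapply(par[nm], function(w) w * 0), t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Replays the training learning-rate policy over a sequence of validation
#' losses: the rate is divided by `factor` whenever the validation loss has
#' failed to improve on its running best for `patience` consecutive epochs
#' (the failure counter resets after each reduction). Exposed so the policy
#' can be audited independently of a training run.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param lr0 initial learning rate.
#' @param patience epochs without improvement before a reduction (default 5).
#' @param factor divisor applied at each reduction (default 10).
#' @return Numeric vector: the learning rate in effect after observing each
#'   epoch's validation loss.
#' @examples
#' plateau_schedule(rep(1, 11), lr0 = 1e-4)  # two reductions -> 1e-6
#' @export
plateau_schedule <- function(val_losses, lr0, patience = 5L, factor = 10) {
  stopifnot(length(val_losses) >= 1, lr0 > 0, patience >= 1, factor > 1)
  lr <- lr0; best <- Inf; bad <- 0L
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) { best <- val_losses[e]; bad <- 0L }
    else {
      bad <- bad + 1L
      if (bad >= patience) { lr <- lr / factor; bad <- 0L }
    }
    out[e] <- lr
  }
  out
}
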