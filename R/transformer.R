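# From-scratch transformer encoder for per-token binary classification.
#
# Pre-LayerNorm architecture: per block, x + MHA(LN(x)) then x + FFN(LN(x)),
# a final LayerNorm and a scalar logit head per token. All matmuls go through
# BLAS; gradients are hand-derived and verified against finite differences in
# the test suite. Matrix convention: activations are (n_tokens x d_model),
# weights multiply on the right.

.ln_eps <- 1e-5

.gelu <- function(x) x * pnorm(x)
.gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# broadcast a length-d vector across rows of an n x d matrix
.rowvec <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

.ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .ln_eps)
  xhat <- xc * inv
  list(y = xhat * .rowvec(g, nrow(x)) + .rowvec(b, nrow(x)),
       xhat = xhat, inv = inv)
}

.ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * .rowvec(g, nrow(dy))
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

#' Initialize transformer parameters
#'
#' @param vocab_size Token vocabulary size (content k-mers + UNK + PAD).
#' @param d_model Embedding width.
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads (`d_model %% n_heads == 0`).
#' @param d_ff Feed-forward hidden width.
#' @param max_len Maximum window length (positional embedding table size).
#' @param seed RNG seed for the Gaussian init (sd 0.02).
#' @return Nested parameter list.
#' @keywords internal
transformer_init <- function(vocab_size, d_model = 64L, n_layers = 2L,
                             n_heads = 4L, d_ff = 4L * d_model,
                             max_len = 512L, seed = 1L) {
  stopifnot(d_model %% n_heads == 0L)
  set.seed(seed)
  rn <- function(r, c) matrix(rnorm(r * c, sd = 0.02), r, c)
  layer <- function() list(
    ln1_g = rep(1, d_model), ln1_b = rep(0, d_model),
    Wq = rn(d_model, d_model), bq = rep(0, d_model),
    Wk = rn(d_model, d_model), bk = rep(0, d_model),
    Wv = rn(d_model, d_model), bv = rep(0, d_model),
    Wo = rn(d_model, d_model), bo = rep(0, d_model),
    ln2_g = rep(1, d_model), ln2_b = rep(0, d_model),
    W1 = rn(d_model, d_ff), b1 = rep(0, d_ff),
    W2 = rn(d_ff, d_model), b2 = rep(0, d_model))
  params <- list(emb = rn(vocab_size, d_model), pos = rn(max_len, d_model),
                 layers = lapply(seq_len(n_layers), function(i) layer()),
                 lnf_g = rep(1, d_model), lnf_b = rep(0, d_model),
                 w_out = rnorm(d_model, sd = 0.02), b_out = 0)
  attr(params, "dims") <- list(vocab_size = vocab_size, d_model = d_model,
                               n_layers = n_layers, n_heads = n_heads,
                               d_ff = d_ff, max_len = max_len)
  params
}

#' Transformer forward pass over one token window
#'
#' @param params Parameters from [transformer_init()].
#' @param tokens Integer token ids (length <= `max_len`).
#' @param key_mask Logical; `FALSE` positions (PAD) are excluded as
#'   attention keys.
#' @param want One of `"probs"`, `"cache"` (for backprop) or `"attention"`.
#' @return For `"probs"`, the per-token sigmoid probabilities; for
#'   `"cache"`, list(p, cache); for `"attention"`, list(p, attention) where
#'   attention is a list (layers) of lists (heads) of n x n matrices.
#' @keywords internal
transformer_forward <- function(params, tokens, key_mask = NULL,
                                want = c("probs", "cache", "attention")) {
  want <- match.arg(want)
  dims <- attr(params, "dims")
  n <- length(tokens)
  H <- dims$n_heads
  dh <- dims$d_model %/% H
  if (is.null(key_mask)) key_mask <- rep(TRUE, n)
  x <- params$emb[tokens, , drop = FALSE] + params$pos[seq_len(n), , drop = FALSE]
  caches <- if (want == "cache") vector("list", dims$n_layers)
  attn_out <- if (want == "attention") vector("list", dims$n_layers)
  masked_cols <- which(!key_mask)
  for (li in seq_len(dims$n_layers)) {
    L <- params$layers[[li]]
    c1 <- .ln_forward(x, L$ln1_g, L$ln1_b)
    h <- c1$y
    Q <- h %*% L$Wq + .rowvec(L$bq, n)
    K <- h %*% L$Wk + .rowvec(L$bk, n)
    V <- h %*% L$Wv + .rowvec(L$bv, n)
    O <- matrix(0, n, dims$d_model)
    A_list <- vector("list", H)
    for (hd in seq_len(H)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      if (length(masked_cols)) S[, masked_cols] <- -1e9
      # scalar-max stabilization (cheap); fall back to per-row on underflow
      A <- exp(S - max(S))
      rs <- rowSums(A)
      if (any(rs == 0)) {
        rmax <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
        A <- exp(S - rmax)
        rs <- rowSums(A)
      }
      A <- A / rs
      A_list[[hd]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    attn <- O %*% L$Wo + .rowvec(L$bo, n)
    x_mid <- x + attn
    c2 <- .ln_forward(x_mid, L$ln2_g, L$ln2_b)
    h1 <- c2$y %*% L$W1 + .rowvec(L$b1, n)
    a <- .gelu(h1)
    x <- x_mid + a %*% L$W2 + .rowvec(L$b2, n)
    if (want == "cache")
      caches[[li]] <- list(x_in = x_mid - attn, c1 = c1, h = h, Q = Q, K = K,
                           V = V, A = A_list, O = O, x_mid = x_mid, c2 = c2,
                           h1 = h1, a = a)
    if (want == "attention") attn_out[[li]] <- A_list
  }
  cf <- .ln_forward(x, params$lnf_g, params$lnf_b)
  logits <- drop(cf$y %*% params$w_out) + params$b_out
  p <- 1 / (1 + exp(-logits))
  if (want == "probs") return(p)
  if (want == "attention") return(list(p = p, attention = attn_out))
  list(p = p, logits = logits,
       cache = list(layers = caches, cf = cf, x_final = x, tokens = tokens,
                    n = n, key_mask = key_mask))
}

# Backward pass; dlogits is the per-token gradient of the loss wrt logits.
# Returns a gradient tree with the same shape as params.
transformer_backward <- function(params, fwd, dlogits) {
  dims <- attr(params, "dims")
  ca <- fwd$cache
  n <- ca$n
  H <- dims$n_heads
  dh <- dims$d_model %/% H
  grads <- list(emb = matrix(0, dims$vocab_size, dims$d_model),
                pos = matrix(0, dims$max_len, dims$d_model),
                layers = vector("list", dims$n_layers),
                lnf_g = NULL, lnf_b = NULL, w_out = NULL, b_out = NULL)
  # head
  grads$w_out <- drop(crossprod(ca$cf$y, dlogits))
  grads$b_out <- sum(dlogits)
  dy <- tcrossprod(dlogits, params$w_out)      # n x d
  lb <- .ln_backward(dy, ca$cf, params$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dx <- lb$dx
  for (li in rev(seq_len(dims$n_layers))) {
    L <- params$layers[[li]]
    cl <- ca$layers[[li]]
    g <- list()
    # FFN block: x = x_mid + gelu(LN2(x_mid) W1 + b1) W2 + b2
    dW2in <- dx                                  # grad wrt (a W2 + b2)
    g$W2 <- crossprod(cl$a, dW2in)
    g$b2 <- colSums(dW2in)
    da <- tcrossprod(dW2in, L$W2)
    dh1 <- da * .gelu_grad(cl$h1)
    g$W1 <- crossprod(cl$c2$y, dh1)
    g$b1 <- colSums(dh1)
    dln2y <- tcrossprod(dh1, L$W1)
    lb2 <- .ln_backward(dln2y, cl$c2, L$ln2_g)
    g$ln2_g <- lb2$dg; g$ln2_b <- lb2$db
    dx_mid <- dx + lb2$dx
    # attention block: x_mid = x_in + (concat_h A_h V_h) Wo + bo
    dattn <- dx_mid
    g$Wo <- crossprod(cl$O, dattn)
    g$bo <- colSums(dattn)
    dO <- tcrossprod(dattn, L$Wo)
    dQ <- matrix(0, n, dims$d_model)
    dK <- matrix(0, n, dims$d_model)
    dV <- matrix(0, n, dims$d_model)
    for (hd in seq_len(H)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      A <- cl$A[[hd]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cl$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cl$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cl$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- crossprod(cl$h, dQ); g$bq <- colSums(dQ)
    g$Wk <- crossprod(cl$h, dK); g$bk <- colSums(dK)
    g$Wv <- crossprod(cl$h, dV); g$bv <- colSums(dV)
    dhh <- tcrossprod(dQ, L$Wq) + tcrossprod(dK, L$Wk) + tcrossprod(dV, L$Wv)
    lb1 <- .ln_backward(dhh, cl$c1, L$ln1_g)
    g$ln1_g <- lb1$dg; g$ln1_b <- lb1$db
    dx <- dx_mid + lb1$dx
    # keep field order identical to params for flat-vector optimizers
    grads$layers[[li]] <- g[c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk",
                              "Wv", "bv", "Wo", "bo", "ln2_g", "ln2_b",
                              "W1", "b1", "W2", "b2")]
  }
  # embeddings
  idx <- ca$tokens
  agg <- rowsum(dx, group = idx)
  grads$emb[as.integer(rownames(agg)), ] <- agg
  grads$pos[seq_len(n), ] <- dx
  grads
}

# masked binary cross-entropy; returns loss and dlogits
.bce_loss <- function(p, logits, labels, mask) {
  m <- which(mask)
  if (!length(m)) return(list(loss = 0, dlogits = numeric(length(p))))
  pm <- pmin(pmax(p[m], 1e-12), 1 - 1e-12)
  y <- labels[m]
  loss <- -mean(y * log(pm) + (1 - y) * log(1 - pm))
  dl <- numeric(length(p))
  dl[m] <- (p[m] - y) / length(m)
  list(loss = loss, dlogits = dl)
}

# one-cycle learning-rate schedule: linear warmup to lr_max over
# warmup_fraction of total steps, then cosine anneal to lr_max/1000
.one_cycle_lr <- function(step, total_steps, lr_max, warmup_fraction = 0.3) {
  w <- max(1, round(warmup_fraction * total_steps))
  if (step <= w) return(lr_max * step / w)
  frac <- (step - w) / max(1, total_steps - w)
  lr_min <- lr_max / 1000
  lr_min + (lr_max - lr_min) * (1 + cos(pi * frac)) / 2
}

# Adam on flat parameter vectors
.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
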