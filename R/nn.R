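# Compact self-attention binary classifier used by the localization model.
# Per-position scalar scores (or 6-mer identities) are lifted to an m-wide
# embedding with sinusoidal positional encoding, a learned CLS row is
# prepended, a small stack of pre-activation residual blocks
# (multi-head self-attention + ReLU feed-forward, no layer norm at this
# depth) transforms the matrix, and a linear head on the CLS row yields the
# nuclear-class logit. Forward, backward and the Adam update are written
# out explicitly in base matrix algebra.

sinusoidal_pe <- function(T, m) {
  pos <- seq_len(T) - 1L
  i <- seq_len(m %/% 2L) - 1L
  div <- 10000^(2 * i / m)
  ang <- outer(pos, 1 / div)
  pe <- matrix(0, T, m)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

nn_init <- function(m, n_layers, n_heads, hidden, mode, seed) {
  stopifnot(m %% n_heads == 0L)
  withr::local_seed(seed)
  rn <- function(r, c, sd = 0.02) matrix(rnorm(r * c, sd = sd), r, c)
  p <- list(cls = rnorm(m, sd = 0.02),
            w_out = rnorm(m, sd = 0.02), b_out = 0)
  if (mode == "baseline_kmer") {
    p$E <- rn(4096L, m, sd = 0.1)
  } else {
    p$w_emb <- rnorm(m, sd = 0.5)
    p$b_emb <- rnorm(m, sd = 0.02)
  }
  p$layers <- lapply(seq_len(n_layers), function(l) {
    list(Wq = rn(m, m), Wk = rn(m, m), Wv = rn(m, m), Wo = rn(m, m),
         bo = numeric(m),
         W1 = rn(m, hidden), b1 = numeric(hidden),
         W2 = rn(hidden, m), b2 = numeric(m))
  })
  p
}

nn_forward <- function(p, x, mode, n_heads, keep_cache = FALSE) {
  m <- length(p$cls)
  T <- length(x)
  pe <- sinusoidal_pe(T, m)
  X <- if (mode == "baseline_kmer") {
    p$E[x, , drop = FALSE] + pe
  } else {
    outer(x, p$w_emb) + matrix(p$b_emb, T, m, byrow = TRUE) + pe
  }
  X <- rbind(p$cls, X)
  d <- m %/% n_heads
  cache <- if (keep_cache) list(X0 = X, layers = vector("list", length(p$layers)))
  for (l in seq_along(p$layers)) {
    ly <- p$layers[[l]]
    Q <- X %*% ly$Wq
    K <- X %*% ly$Wk
    V <- X %*% ly$Wv
    O <- matrix(0, nrow(X), m)
    As <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * d + 1L):(h * d)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(d)
      S <- S - apply(S, 1L, max)
      A <- exp(S)
      A <- A / rowSums(A)
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      if (keep_cache) As[[h]] <- A
    }
    attn <- O %*% ly$Wo + matrix(ly$bo, nrow(X), m, byrow = TRUE)
    Xa <- X + attn
    Z <- Xa %*% ly$W1 + matrix(ly$b1, nrow(X), ncol(ly$W1), byrow = TRUE)
    H <- pmax(Z, 0)
    Fo <- H %*% ly$W2 + matrix(ly$b2, nrow(X), m, byrow = TRUE)
    Xn <- Xa + Fo
    if (keep_cache) {
      cache$layers[[l]] <- list(X = X, Q = Q, K = K, V = V, O = O, As = As,
                                Xa = Xa, Z = Z, H = H)
    }
    X <- Xn
  }
  logit <- sum(X[1L, ] * p$w_out) + p$b_out
  if (keep_cache) {
    cache$Xout <- X
    list(logit = logit, cache = cache)
  } else {
    logit
  }
}

nn_backward <- function(p, x, mode, n_heads, fw, dlogit) {
  m <- length(p$cls)
  d <- m %/% n_heads
  cache <- fw$cache
  g <- nn_zero_like(p)
  g$w_out <- dlogit * cache$Xout[1L, ]
  g$b_out <- dlogit
  dX <- matrix(0, nrow(cache$Xout), m)
  dX[1L, ] <- dlogit * p$w_out
  for (l in rev(seq_along(p$layers))) {
    ly <- p$layers[[l]]
    cl <- cache$layers[[l]]
    # feed-forward block (residual): Xn = Xa + relu(Xa W1 + b1) W2 + b2
    dFo <- dX
    g$layers[[l]]$W2 <- crossprod(cl$H, dFo)
    g$layers[[l]]$b2 <- colSums(dFo)
    dH <- tcrossprod(dFo, ly$W2)
    dZ <- dH * (cl$Z > 0)
    g$layers[[l]]$W1 <- crossprod(cl$Xa, dZ)
    g$layers[[l]]$b1 <- colSums(dZ)
    dXa <- dX + tcrossprod(dZ, ly$W1)
    # attention block (residual): Xa = X + (softmax(QK'/sqrt(d)) V) Wo + bo
    dAttn <- dXa
    g$layers[[l]]$Wo <- crossprod(cl$O, dAttn)
    g$layers[[l]]$bo <- colSums(dAttn)
    dO <- tcrossprod(dAttn, ly$Wo)
    dQ <- matrix(0, nrow(dX), m)
    dK <- matrix(0, nrow(dX), m)
    dV <- matrix(0, nrow(dX), m)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * d + 1L):(h * d)
      A <- cl$As[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, cl$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cl$K[, idx, drop = FALSE] / sqrt(d)
      dK[, idx] <- crossprod(dS, cl$Q[, idx, drop = FALSE]) / sqrt(d)
    }
    g$layers[[l]]$Wq <- crossprod(cl$X, dQ)
    g$layers[[l]]$Wk <- crossprod(cl$X, dK)
    g$layers[[l]]$Wv <- crossprod(cl$X, dV)
    dX <- dXa + tcrossprod(dQ, ly$Wq) + tcrossprod(dK, ly$Wk) +
      tcrossprod(dV, ly$Wv)
  }
  g$cls <- dX[1L, ]
  dX0 <- dX[-1L, , drop = FALSE]
  if (mode == "baseline_kmer") {
    g$E <- matrix(0, 4096L, m)
    for (t in seq_along(x)) g$E[x[t], ] <- g$E[x[t], ] + dX0[t, ]
  } else {
    g$w_emb <- as.numeric(crossprod(dX0, x))
    g$b_emb <- colSums(dX0)
  }
  g
}

# binary cross-entropy with logits, numerically stable
bce_loss <- function(logit, y) {
  pmax(logit, 0) - logit * y + log1p(exp(-abs(logit)))
}

nn_zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

tree_map2 <- function(f, a, b) {
  if (is.list(a))

    purrr::map2(a, b, function(x, y) tree_map2(f, x, y))
  else f(a, b)
}

adam_init <- function(p) list(m = nn_zero_like(p), v = nn_zero_like(p), t = 0)

adam_step <- function(p, g, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, gg) beta1 * m + (1 - beta1) * gg, state$m, g)
  state$v <- tree_map2(function(v, gg) beta2 * v + (1 - beta2) * gg^2, state$v, g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  p <- tree_map2(`-`, p, upd)
  list(params = p, state = state)
}
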