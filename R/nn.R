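## Neural-network primitives for the correlation model: 1-D convolutions
## (im2col), parametric ReLU, dense layers, layer normalization, multi-head
## self-attention and the row-normalized Gram head, each with a hand-derived
## backward pass, plus the Adam optimizer. Activations over reads are stored
## as (n*l) x channels matrices with rows ordered position-fast within read
## (row (i-1)*l + p), so convolution along the genome axis is a gather on
## row indices followed by one BLAS matrix multiply.

.addBias <- function(M, b) M + rep(b, each = nrow(M))

## cached row-index sets for the zero-padded patch gathers (keyed on the
## geometry, which repeats every mini-batch)
.convIdxCache <- new.env(parent = emptyenv())

.convIdx <- function(n, l, w) {
  key <- paste(n, l, w, sep = "_")
  hit <- .convIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  h <- (w - 1L) %/% 2L
  posvec <- rep.int(seq_len(l), n)
  idx <- lapply(seq_len(w), function(j) {
    o <- j - h - 1L
    valid <- which(posvec + o >= 1L & posvec + o <= l)
    list(valid = valid, src = valid + o)
  })
  .convIdxCache[[key]] <- idx
  idx
}

## gather patches of width w around every position; zero-padded at the ends
.im2col <- function(M, n, l, w) {
  C <- ncol(M)
  idx <- .convIdx(n, l, w)
  out <- matrix(0, n * l, w * C)
  for (j in seq_len(w)) {
    out[idx[[j]]$valid, ((j - 1L) * C + 1L):(j * C)] <-
      M[idx[[j]]$src, , drop = FALSE]
  }
  out
}

.col2im <- function(dCol, n, l, w, C) {
  idx <- .convIdx(n, l, w)
  dM <- matrix(0, n * l, C)
  for (j in seq_len(w)) {
    dM[idx[[j]]$src, ] <- dM[idx[[j]]$src, ] +
      dCol[idx[[j]]$valid, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dM
}

.convForward <- function(M, n, l, W, b, w) {
  col <- .im2col(M, n, l, w)
  list(out = .addBias(col %*% W, b), col = col)
}

.convBackward <- function(dOut, col, W, n, l, w, Cin) {
  list(dW = crossprod(col, dOut),
       db = colSums(dOut),
       dM = .col2im(dOut %*% t(W), n, l, w, Cin))
}

## y = x for x > 0, a*x otherwise, written branch-free
.preluForward <- function(X, a) {
  0.5 * ((1 + a) * X + (1 - a) * abs(X))
}

.preluBackward <- function(dY, X, a) {
  list(dX = dY * (0.5 * (1 + a) + 0.5 * (1 - a) * sign(X)),
       da = sum(dY * pmin(X, 0)))
}

.layerNormForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = .addBias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

.layerNormBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dXhat <- dY * rep(g, each = nrow(dY))
  dX <- (dXhat - rowMeans(dXhat) - xhat * rowMeans(dXhat * xhat)) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.softmaxRows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

## one transformer encoder layer: multi-head self-attention over the n reads,
## add & layer-normalize, position-wise feed-forward, add & layer-normalize
.tfLayerForward <- function(Z, p, pre, nHeads) {
  n <- nrow(Z); dR <- ncol(Z)
  dH <- dR %/% nHeads
  Q <- .addBias(Z %*% p[[paste0(pre, ".Wq")]], p[[paste0(pre, ".bq")]])
  K <- .addBias(Z %*% p[[paste0(pre, ".Wk")]], p[[paste0(pre, ".bk")]])
  V <- .addBias(Z %*% p[[paste0(pre, ".Wv")]], p[[paste0(pre, ".bv")]])
  A <- vector("list", nHeads)
  O <- matrix(0, n, dR)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dH + 1L):(h * dH)
    A[[h]] <- .softmaxRows(tcrossprod(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE]) / sqrt(dH))
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  Z2 <- .addBias(O %*% p[[paste0(pre, ".Wo")]], p[[paste0(pre, ".bo")]])
  ln1 <- .layerNormForward(Z + Z2, p[[paste0(pre, ".g1")]], p[[paste0(pre, ".h1")]])
  U <- ln1$out
  F1 <- .addBias(U %*% p[[paste0(pre, ".W1")]], p[[paste0(pre, ".c1")]])
  F1r <- pmax(F1, 0)
  F2 <- .addBias(F1r %*% p[[paste0(pre, ".W2")]], p[[paste0(pre, ".c2")]])
  ln2 <- .layerNormForward(U + F2, p[[paste0(pre, ".g2")]], p[[paste0(pre, ".h2")]])
  list(out = ln2$out,
       cache = list(Z = Z, Q = Q, K = K, V = V, A = A, O = O,
                    ln1 = ln1, U = U, F1 = F1, F1r = F1r, ln2 = ln2))
}

.tfLayerBackward <- function(dOut, cache, p, pre, nHeads, grads) {
  Z <- cache$Z
  dR <- ncol(Z); dH <- dR %/% nHeads
  b2 <- .layerNormBackward(dOut, cache$ln2, p[[paste0(pre, ".g2")]])
  grads[[paste0(pre, ".g2")]] <- b2$dg
  grads[[paste0(pre, ".h2")]] <- b2$db
  dU <- b2$dX                                    # residual branch
  dF2 <- b2$dX
  grads[[paste0(pre, ".W2")]] <- crossprod(cache$F1r, dF2)
  grads[[paste0(pre, ".c2")]] <- colSums(dF2)
  dF1r <- dF2 %*% t(p[[paste0(pre, ".W2")]])
  dF1 <- dF1r * (cache$F1 > 0)
  grads[[paste0(pre, ".W1")]] <- crossprod(cache$U, dF1)
  grads[[paste0(pre, ".c1")]] <- colSums(dF1)
  dU <- dU + dF1 %*% t(p[[paste0(pre, ".W1")]])
  b1 <- .layerNormBackward(dU, cache$ln1, p[[paste0(pre, ".g1")]])
  grads[[paste0(pre, ".g1")]] <- b1$dg
  grads[[paste0(pre, ".h1")]] <- b1$db
  dZ <- b1$dX                                    # residual into Z
  dZ2 <- b1$dX
  grads[[paste0(pre, ".Wo")]] <- crossprod(cache$O, dZ2)
  grads[[paste0(pre, ".bo")]] <- colSums(dZ2)
  dO <- dZ2 %*% t(p[[paste0(pre, ".Wo")]])
  dQ <- matrix(0, nrow(Z), dR); dK <- dQ; dV <- dQ
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dH + 1L):(h * dH)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dH)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dH)
  }
  grads[[paste0(pre, ".Wq")]] <- crossprod(Z, dQ)
  grads[[paste0(pre, ".bq")]] <- colSums(dQ)
  grads[[paste0(pre, ".Wk")]] <- crossprod(Z, dK)
  grads[[paste0(pre, ".bk")]] <- colSums(dK)
  grads[[paste0(pre, ".Wv")]] <- crossprod(Z, dV)
  grads[[paste0(pre, ".bv")]] <- colSums(dV)
  dZ <- dZ + dQ %*% t(p[[paste0(pre, ".Wq")]]) +
    dK %*% t(p[[paste0(pre, ".Wk")]]) + dV %*% t(p[[paste0(pre, ".Wv")]])
  list(dZ = dZ, grads = grads)
}

## reshape (n*l) x C activations to n x (l*C) per-read feature vectors
.flattenReads <- function(M, n, l) {
  C <- ncol(M)
  t(matrix(aperm(array(M, dim = c(l, n, C)), c(1L, 3L, 2L)), l * C, n))
}

.unflattenReads <- function(dXf, n, l, C) {
  matrix(aperm(array(t(dXf), dim = c(l, C, n)), c(1L, 3L, 2L)), l * n, C)
}

## Adam with the standard moment defaults
.adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
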