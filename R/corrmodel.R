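## The learnable correlation model: a convolutional read encoder followed by
## a transformer encoder whose output, after row normalization, yields the
## read-correlation kernel Sigma = Qt %*% t(Qt). Also the measured (overlap)
## correlations and the contrastive / consistency / sparsity loss terms.

#' Encoder architecture configuration
#'
#' The default architecture embeds each one-hot encoded read with three
#' convolutional layers (kernel widths 5, 5 and 3 along the genome axis; the
#' first layer consumes the 4-channel nucleotide axis) with 32, 64 and 128
#' filters, a parametric ReLU after each, and a dense layer to a
#' `dR = 128`-dimensional embedding. A transformer encoder with `nLayers = 3`
#' layers of `nHeads = 4` attention heads each then maps the embeddings to an
#' n x `dQ` matrix (`dQ = dR/2`) whose row-normalized Gram product is the
#' learned correlation matrix. `dR` may be reduced (e.g. 32) for small
#' problems; filter counts scale as `dR/4, dR/2, dR` and the position-wise
#' feed-forward width as `4*dR`.
#'
#' @param dR embedding dimension (default 128).
#' @param filters three convolutional filter counts.
#' @param kernelWidths three kernel widths along the genome axis.
#' @param nLayers number of transformer encoder layers.
#' @param nHeads attention heads per layer; must divide `dR`.
#' @param dQ output dimension of the correlation head (default `dR/2`).
#' @param dFF width of the position-wise feed-forward layer (default `4*dR`).
#' @return an `encoderConfig` list.
#' @export
encoderConfig <- function(dR = 128L, filters = c(dR / 4L, dR / 2L, dR),
                          kernelWidths = c(5L, 5L, 3L),
                          nLayers = 3L, nHeads = 4L,
                          dQ = dR / 2L, dFF = 4L * dR) {
  stopifnot(dR %% nHeads == 0L, length(filters) == 3L, length(kernelWidths) == 3L)
  structure(list(dR = as.integer(dR), filters = as.integer(filters),
                 kernelWidths = as.integer(kernelWidths),
                 nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
                 dQ = as.integer(dQ), dFF = as.integer(dFF)),
            class = "encoderConfig")
}

#' @export
print.encoderConfig <- function(x, ...) {
  cat(sprintf(
    "encoderConfig: dR %d, filters %s, kernels %s, %d transformer layers x %d heads, dQ %d\n",
    x$dR, paste(x$filters, collapse = "/"),
    paste(x$kernelWidths, collapse = "/"), x$nLayers, x$nHeads, x$dQ))
  invisible(x)
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a correlation model
#'
#' Parameters are Glorot-initialized; biases start at zero, layer-norm gains
#' at one and parametric-ReLU slopes at 0.25. The dense layer after the
#' convolutional stack depends on the block length, so a model is bound to a
#' fixed number of SNP columns `l`.
#'
#' @param cfg an [encoderConfig()].
#' @param l number of SNP columns the model operates on.
#' @param seed integer seed for the random initialization.
#' @return a `corrModel` list with elements `params`, `cfg` and `l`.
#' @export
initCorrModel <- function(cfg, l, seed = 1L) {
  stopifnot(inherits(cfg, "encoderConfig"))
  if (l < max(cfg$kernelWidths)) stop("haplotype block too short")
  set.seed(seed)
  f <- cfg$filters; w <- cfg$kernelWidths
  p <- list()
  cin <- c(4L, f[1L], f[2L])
  for (i in 1:3) {
    pre <- paste0("c", i)
    p[[paste0(pre, ".W")]] <- .glorot(cin[i] * w[i], f[i])
    p[[paste0(pre, ".b")]] <- numeric(f[i])
    p[[paste0(pre, ".a")]] <- 0.25
  }
  p[["d1.W"]] <- .glorot(l * f[3L], cfg$dR)
  p[["d1.b"]] <- numeric(cfg$dR)
  for (t in seq_len(cfg$nLayers)) {
    pre <- paste0("t", t)
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pre, ".", nm)]] <- .glorot(cfg$dR, cfg$dR)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0(pre, ".", nm)]] <- numeric(cfg$dR)
    p[[paste0(pre, ".g1")]] <- rep(1, cfg$dR)
    p[[paste0(pre, ".h1")]] <- numeric(cfg$dR)
    p[[paste0(pre, ".W1")]] <- .glorot(cfg$dR, cfg$dFF)
    p[[paste0(pre, ".c1")]] <- numeric(cfg$dFF)
    p[[paste0(pre, ".W2")]] <- .glorot(cfg$dFF, cfg$dR)
    p[[paste0(pre, ".c2")]] <- numeric(cfg$dR)
    p[[paste0(pre, ".g2")]] <- rep(1, cfg$dR)
    p[[paste0(pre, ".h2")]] <- numeric(cfg$dR)
  }
  p[["d2.W"]] <- .glorot(cfg$dR, cfg$dQ)
  p[["d2.b"]] <- numeric(cfg$dQ)
  structure(list(params = p, cfg = cfg, l = as.integer(l)),
            class = "corrModel")
}

#' @export
print.corrModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("corrModel: l = %d, dR = %d, %s parameters\n",
              x$l, x$cfg$dR, format(np, big.mark = ",")))
  invisible(x)
}

#' Save / load a correlation model checkpoint
#' @param model a `corrModel`.
#' @param path checkpoint file path.
#' @export
saveCorrModel <- function(model, path) saveRDS(model, path)

#' @rdname saveCorrModel
#' @export
loadCorrModel <- function(path) readRDS(path)

## ---- forward / backward over the full model ----

## X: (n*l) x 4 flat one-hot; returns all caches needed for the backward pass
.modelForward <- function(X, n, l, params, cfg) {
  f <- cfg$filters; w <- cfg$kernelWidths
  cv <- vector("list", 3L)
  act <- X
  cin <- c(4L, f[1L], f[2L])
  for (i in 1:3) {
    pre <- paste0("c", i)
    conv <- .convForward(act, n, l, params[[paste0(pre, ".W")]],
                         params[[paste0(pre, ".b")]], w[i])
    a <- params[[paste0(pre, ".a")]]
    cv[[i]] <- list(col = conv$col, preact = conv$out, input = act)
    act <- .preluForward(conv$out, a)
  }
  Xf <- .flattenReads(act, n, l)
  Z <- .addBias(Xf %*% params[["d1.W"]], params[["d1.b"]])
  E <- Z
  tf <- vector("list", cfg$nLayers)
  for (t in seq_len(cfg$nLayers)) {
    step <- .tfLayerForward(E, params, paste0("t", t), cfg$nHeads)
    tf[[t]] <- step$cache
    E <- step$out
  }
  Q2 <- .addBias(E %*% params[["d2.W"]], params[["d2.b"]])
  norms <- sqrt(rowSums(Q2 * Q2))
  ok <- norms >= 1e-8
  Qt <- Q2
  Qt[ok, ] <- Q2[ok, , drop = FALSE] / norms[ok]
  Qt[!ok, ] <- 0
  Sigma <- tcrossprod(Qt)
  diag(Sigma) <- 1
  list(Z = Z, E = E, Q2 = Q2, Qt = Qt, norms = norms, ok = ok, Sigma = Sigma,
       Xf = Xf, cv = cv, tf = tf, n = n, l = l, cin = cin)
}

## dSigma: matrix of partials w.r.t. Sigma entries (diagonal ignored)
.modelBackward <- function(dSigma, fw, params, cfg) {
  n <- fw$n; l <- fw$l
  diag(dSigma) <- 0
  grads <- list()
  dQt <- (dSigma + t(dSigma)) %*% fw$Qt
  dQ2 <- (dQt - fw$Qt * rowSums(dQt * fw$Qt))
  dQ2[fw$ok, ] <- dQ2[fw$ok, , drop = FALSE] / fw$norms[fw$ok]
  dQ2[!fw$ok, ] <- 0
  grads[["d2.W"]] <- crossprod(fw$E, dQ2)
  grads[["d2.b"]] <- colSums(dQ2)
  dE <- dQ2 %*% t(params[["d2.W"]])
  for (t in rev(seq_len(cfg$nLayers))) {
    bk <- .tfLayerBackward(dE, fw$tf[[t]], params, paste0("t", t),
                           cfg$nHeads, grads)
    grads <- bk$grads
    dE <- bk$dZ
  }
  grads[["d1.W"]] <- crossprod(fw$Xf, dE)
  grads[["d1.b"]] <- colSums(dE)
  dXf <- dE %*% t(params[["d1.W"]])
  dAct <- .unflattenReads(dXf, n, l, cfg$filters[3L])
  w <- cfg$kernelWidths
  for (i in 3:1) {
    pre <- paste0("c", i)
    pb <- .preluBackward(dAct, fw$cv[[i]]$preact, params[[paste0(pre, ".a")]])
    grads[[paste0(pre, ".a")]] <- pb$da
    cb <- .convBackward(pb$dX, fw$cv[[i]]$col, params[[paste0(pre, ".W")]],
                        n, l, w[i], fw$cin[i])
    grads[[paste0(pre, ".W")]] <- cb$dW
    grads[[paste0(pre, ".b")]] <- cb$db
    dAct <- cb$dM
  }
  grads
}

#' Embed one-hot encoded reads with the convolutional encoder
#'
#' Three convolution + parametric-ReLU layers (the first kernel spans the
#' full nucleotide axis; "same" padding keeps the genome axis at length l),
#' a flatten and an affine map produce one `dR`-dimensional embedding per
#' read. Deterministic given the model parameters.
#'
#' @param reads an n x 4 x l one-hot array (from [oneHot()]) or a
#'   [FragmentMatrix-class].
#' @param model a `corrModel` from [initCorrModel()].
#' @return n x `dR` embedding matrix.
#' @export
encodeReads <- function(reads, model) {
  stopifnot(inherits(model, "corrModel"))
  if (is(reads, "FragmentMatrix")) {
    X <- .oneHotFlat(reads@fragments)
    n <- nReads(reads); l <- nSnps(reads)
  } else {
    stopifnot(length(dim(reads)) == 3L, dim(reads)[2] == 4L)
    n <- dim(reads)[1]; l <- dim(reads)[3]
    X <- .oneHotFlat(decodeOneHot(reads)@fragments)
  }
  if (n < 1L) stop("no reads")
  if (l < max(model$cfg$kernelWidths)) stop("haplotype block too short")
  if (l != model$l) stop("model was initialized for l = ", model$l,
                         " columns, got ", l)
  fw <- .modelForward(X, n, l, model$params, model$cfg)
  fw$Z
}

#' Learned read-correlation matrix from embeddings
#'
#' Applies the transformer encoder layers to the embedding matrix, maps to
#' the `dQ`-dimensional correlation head, row-normalizes and forms the Gram
#' product. The result is symmetric positive semi-definite with unit
#' diagonal, hence a valid kernel.
#'
#' @param Z n x `dR` embedding matrix (from [encodeReads()]).
#' @param model a `corrModel`.
#' @return n x n correlation matrix Sigma.
#' @export
correlationForward <- function(Z, model) {
  stopifnot(inherits(model, "corrModel"))
  params <- model$params; cfg <- model$cfg
  E <- Z
  for (t in seq_len(cfg$nLayers))
    E <- .tfLayerForward(E, params, paste0("t", t), cfg$nHeads)$out
  Q2 <- .addBias(E %*% params[["d2.W"]], params[["d2.b"]])
  norms <- sqrt(rowSums(Q2 * Q2))
  ok <- norms >= 1e-8
  Qt <- Q2
  Qt[ok, ] <- Q2[ok, , drop = FALSE] / norms[ok]
  Qt[!ok, ] <- 0
  Sigma <- tcrossprod(Qt)
  diag(Sigma) <- 1
  Sigma
}

#' Measured pairwise read correlations
#'
#' For each pair of reads, `kSim` counts the positions covered by both reads
#' where their alleles agree and `kDissim` those where they differ; the
#' correlation is `(kSim - kDissim) / (kSim + kDissim)`. Pairs with no
#' shared covered position get correlation 0; the diagonal is 1.
#'
#' @param m a [FragmentMatrix-class].
#' @return symmetric n x n matrix with entries in \[-1, 1\].
#' @export
measuredCorrelations <- function(m) {
  stopifnot(is(m, "FragmentMatrix"))
  f <- m@fragments
  cov <- (f != .UNCOVERED) * 1
  overlap <- tcrossprod(cov)
  agree <- matrix(0, nrow(f), nrow(f))
  for (b in 1:4) agree <- agree + tcrossprod((f == b) * 1)
  C <- matrix(0, nrow(f), nrow(f))
  nz <- overlap > 0
  C[nz] <- (2 * agree[nz] - overlap[nz]) / overlap[nz]
  diag(C) <- 1
  C
}

#' Pair indicator matrix induced by a cluster assignment
#'
#' @param labels integer vector of cluster labels in 1..k.
#' @return symmetric binary n x n matrix with `p[i,j] = 1` iff reads i and j
#'   share a label; diagonal 1.
#' @export
pairIndicator <- function(labels) {
  outer(labels, labels, `==`) * 1
}

#' Contrastive loss over read pairs
#'
#' Sums `p[i,j]*(1-Sigma[i,j])^2 + (1-p[i,j])*(1+Sigma[i,j])^2` over
#' unordered pairs i < j: zero exactly when same-cluster pairs reach
#' correlation +1 and different-cluster pairs reach -1.
#'
#' @param Sigma n x n correlation matrix.
#' @param p pair indicator matrix (see [pairIndicator()]).
#' @return non-negative scalar.
#' @export
contrastiveLoss <- function(Sigma, p) {
  stopifnot(all(dim(Sigma) == dim(p)))
  ut <- upper.tri(Sigma)
  sum(p[ut] * (1 - Sigma[ut])^2 + (1 - p[ut]) * (1 + Sigma[ut])^2)
}

#' Consistency regularizer against measured correlations
#'
#' Frobenius norm of `Sigma - C` restricted to the entries where the
#' measured correlation is non-zero (i.e. to overlapping read pairs).
#'
#' @param Sigma learned correlation matrix.
#' @param C measured correlation matrix (see [measuredCorrelations()]).
#' @return non-negative scalar.
#' @export
consistencyRegularizer <- function(Sigma, C) {
  stopifnot(all(dim(Sigma) == dim(C)))
  d <- (Sigma - C)[C != 0]
  sqrt(sum(d * d))
}

#' Sparsity regularizer
#'
#' Sum of absolute off-diagonal entries of Sigma (both orderings), promoting
#' correlation matrices in which each read is strongly correlated with only
#' a small subset of reads.
#'
#' @param Sigma square correlation matrix.
#' @return non-negative scalar.
#' @export
sparsityRegularizer <- function(Sigma) {
  sum(abs(Sigma)) - sum(abs(diag(Sigma)))
}

#' Total training loss
#'
#' `contrastiveLoss + lambdaR * consistencyRegularizer + lambdaS *
#' sparsityRegularizer` with the default weights `lambdaR = 100`,
#' `lambdaS = 10`.
#'
#' @param Sigma,C,p as in the individual terms.
#' @param lambdaR,lambdaS regularization weights.
#' @return scalar loss.
#' @export
totalLoss <- function(Sigma, C, p, lambdaR = 100, lambdaS = 10) {
  contrastiveLoss(Sigma, p) + lambdaR * consistencyRegularizer(Sigma, C) +
    lambdaS * sparsityRegularizer(Sigma)
}

## loss value and matrix of partials w.r.t. Sigma (diagonal excluded)
.lossGradSigma <- function(Sigma, C, p, lambdaR, lambdaS) {
  ut <- upper.tri(Sigma)
  lc <- sum(p[ut] * (1 - Sigma[ut])^2 + (1 - p[ut]) * (1 + Sigma[ut])^2)
  G <- matrix(0, nrow(Sigma), ncol(Sigma))
  G[ut] <- -2 * p[ut] * (1 - Sigma[ut]) + 2 * (1 - p[ut]) * (1 + Sigma[ut])
  mask <- C != 0
  diff <- (Sigma - C) * mask
  lr <- sqrt(sum(diff * diff))
  if (lr > 0) G <- G + lambdaR * diff / lr
  ls <- sum(abs(Sigma)) - sum(abs(diag(Sigma)))
  Gs <- sign(Sigma)
  diag(Gs) <- 0
  G <- G + lambdaS * Gs
  diag(G) <- 0
  list(loss = lc + lambdaR * lr + lambdaS * ls, lc = lc, lr = lr, ls = ls,
       dSigma = G)
}

## full loss + parameter gradients for one set of reads (used per mini-batch
## during training and by the finite-difference gradient check)
.corrModelLossGrad <- function(X, n, l, C, p, params, cfg,
                               lambdaR = 100, lambdaS = 10) {
  fw <- .modelForward(X, n, l, params, cfg)
  lg <- .lossGradSigma(fw$Sigma, C, p, lambdaR, lambdaS)
  grads <- .modelBackward(lg$dSigma, fw, params, cfg)
  list(loss = lg$loss, lc = lg$lc, lr = lg$lr, ls = lg$ls,
       Sigma = fw$Sigma, grads = grads)
}
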