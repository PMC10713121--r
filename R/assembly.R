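## The alternating optimization engine: mini-batch training of the
## correlation model against the current read attribution, kernel k-means
## re-clustering on the learned kernel, consensus haplotype calling and
## best-of-restarts model selection by MEC.

#' Training configuration
#'
#' Defaults are the full-scale settings the method is calibrated to: Adam
#' with learning rate 1e-5 over 2000 epochs, mini-batches of `ceiling(n/5)`
#' reads, loss weights `lambdaR = 100` and `lambdaS = 10`, and 5 random
#' restarts with the lowest-MEC model selected. For small problems (tens of
#' SNPs, reduced `dR`) far fewer epochs with a proportionally larger
#' learning rate reach the same fixed points; see the package vignette.
#'
#' @param epochs training epochs.
#' @param learningRate Adam learning rate.
#' @param batchSize reads per mini-batch; `NULL` means `ceiling(n/5)`.
#' @param restarts independent random restarts in [assembleHaplotypes()].
#' @param lambdaR,lambdaS loss weights.
#' @param init initial read attribution: `"measured"` clusters the measured
#'   correlation matrix (PSD-repaired), `"random"` draws random labels.
#' @param seed master seed; all randomness (initialization, k-means
#'   restarts, batching) derives from it.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(epochs = 2000L, learningRate = 1e-5, batchSize = NULL,
                        restarts = 5L, lambdaR = 100, lambdaS = 10,
                        init = c("measured", "random"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(epochs >= 1L, learningRate > 0, restarts >= 1L)
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = if (is.null(batchSize)) NULL else as.integer(batchSize),
                 restarts = as.integer(restarts), lambdaR = lambdaR,
                 lambdaS = lambdaS, init = init, seed = as.integer(seed)),
            class = "trainConfig")
}

#' @export
print.trainConfig <- function(x, ...) {
  cat(sprintf(
    "trainConfig: %d epochs, lr %g, batch %s, %d restarts, lambdaR %g, lambdaS %g, seed %d\n",
    x$epochs, x$learningRate,
    if (is.null(x$batchSize)) "ceiling(n/5)" else x$batchSize,
    x$restarts, x$lambdaR, x$lambdaS, x$seed))
  invisible(x)
}

#' Clip negative eigenvalues of a nominally PSD kernel
#'
#' Measured correlation matrices are generally indefinite; eigenvalues are
#' clipped at zero when the smallest falls below `-1e-6` times the largest.
#'
#' @param K symmetric matrix.
#' @return PSD-repaired matrix.
#' @export
psdRepair <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= -1e-6 * max(abs(e$values))) return(K)
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Kernel k-means clustering
#'
#' Standard kernel k-means: assignments minimize the within-cluster distance
#' in the feature space implied by the kernel, computed from kernel entries
#' as `K[i,i] - 2*mean(K[i, cluster]) + mean(K[cluster, cluster])`. Several
#' random-label restarts are run and the assignment with the lowest
#' objective is kept; a cluster that empties is reseeded with the point
#' farthest from its current centroid.
#'
#' @param K symmetric kernel matrix (PSD, or repaired with [psdRepair()]).
#' @param k number of clusters (2 <= k <= n; k = 1 returns one cluster).
#' @param nstart random restarts (default 10).
#' @param maxIter maximum sweeps per restart.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param init optional integer label vector used as one additional warm
#'   start (still competing on the objective with the random restarts);
#'   the alternating trainer passes the previous epoch's assignment here to
#'   damp oscillation between near-tied clusterings.
#' @return list with `labels` (integer in 1..k) and `objective`.
#' @export
kernelKmeans <- function(K, k, nstart = 10L, maxIter = 100L, seed = NULL,
                         init = NULL) {
  n <- nrow(K)
  if (k > n) stop("k must not exceed the number of reads")
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    obj <- sum(diag(K)) - 2 * sum(K) / n + sum(K) / n
    return(list(labels = rep(1L, n), objective = obj))
  }
  dK <- diag(K)
  best <- NULL
  starts <- nstart + !is.null(init)
  for (s in seq_len(starts)) {
    if (!is.null(init) && s == 1L) {
      labels <- as.integer(init)
    } else {
      labels <- sample.int(k, n, replace = TRUE)
      labels[sample.int(n, k)] <- seq_len(k)    # guarantee non-empty start
    }
    for (iter in seq_len(maxIter)) {
      repeat {
        Zm <- matrix(0, n, k)
        Zm[cbind(seq_len(n), labels)] <- 1
        sizes <- colSums(Zm)
        if (all(sizes > 0)) break
        ## reseed each empty cluster with the point farthest from its centroid
        E <- K %*% Zm
        occ <- sizes > 0
        d <- dK - 2 * E[cbind(seq_len(n), labels)] / sizes[labels] +
          (colSums(Zm * E) / sizes^2)[labels]
        labels[which.max(d)] <- which(!occ)[1L]
      }
      E <- K %*% Zm                             # n x k sums over clusters
      within <- colSums(Zm * E) / sizes^2       # centroid norms
      D <- dK - 2 * sweep(E, 2L, sizes, "/") + rep(within, each = n)
      newLabels <- max.col(-D, ties.method = "first")
      if (all(newLabels == labels)) break
      labels <- newLabels
    }
    Zm <- matrix(0, n, k)
    Zm[cbind(seq_len(n), labels)] <- 1
    sizes <- pmax(colSums(Zm), 1)
    E <- K %*% Zm
    within <- colSums(Zm * E) / sizes^2
    D <- dK - 2 * sweep(E, 2L, sizes, "/") + rep(within, each = n)
    obj <- sum(D[cbind(seq_len(n), labels)])
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(labels = labels, objective = obj)
  }
  best
}

#' Consensus haplotypes from a read attribution
#'
#' For every cluster and SNP column, the majority allele among the covering
#' reads of that cluster is called. Ties are broken by the allele's count
#' across all reads, then by lexicographic base order; a column with no
#' covering read in a cluster is imputed with the all-reads majority allele.
#'
#' @param m a [FragmentMatrix-class].
#' @param labels integer read attribution in 1..k.
#' @param k ploidy (defaults to `max(labels)`).
#' @return a [Haplotypes-class] with k rows.
#' @export
consensusHaplotypes <- function(m, labels, k = max(labels)) {
  stopifnot(is(m, "FragmentMatrix"), length(labels) == nReads(m))
  f <- m@fragments
  l <- ncol(f)
  lab <- factor(labels, levels = seq_len(k))
  hap <- matrix(0L, k, l)
  global <- vapply(1:4, function(b) colSums(f == b), numeric(l))  # l x 4
  for (b in 1:4) {
    cnt <- rowsum((f == b) * 1, lab)                              # k x l
    ## lexicographic ranking: cluster votes, then global votes, then base order
    sc <- cnt * 1e9 + rep(global[, b], each = k) + (4 - b) * 1e-3
    if (b == 1L) score <- array(sc, dim = c(k, l, 4L)) else score[, , b] <- sc
  }
  pick <- max.col(matrix(score, k * l, 4L), ties.method = "first")
  hap[] <- as.integer(pick)
  Haplotypes(hap, snpPositions = m@snpPositions)
}

#' Minimum error correction score
#'
#' Number of allele changes needed to make every read consistent with its
#' closest haplotype: the Hamming distance of each read to each haplotype is
#' computed over the read's covered columns only, and the per-read minimum
#' is summed.
#'
#' @param m a [FragmentMatrix-class].
#' @param h a [Haplotypes-class] with the same number of columns.
#' @return non-negative integer.
#' @export
mec <- function(m, h) {
  stopifnot(is(m, "FragmentMatrix"), is(h, "Haplotypes"),
            nSnps(m) == nSnps(h))
  f <- m@fragments
  hp <- h@alleles
  d <- vapply(seq_len(nrow(hp)), function(j) {
    rowSums((f != rep(hp[j, ], each = nrow(f))) & f != .UNCOVERED)
  }, numeric(nrow(f)))
  if (nrow(f) == 1L) d <- matrix(d, nrow = 1L)
  sum(apply(d, 1L, min))
}

## Sigma for all reads under the current parameters (no gradient bookkeeping)
.fullSigma <- function(X, n, l, params, cfg) {
  .modelForward(X, n, l, params, cfg)$Sigma
}

#' Train the correlation model and assemble haplotypes (single run)
#'
#' Alternating optimization. The read attribution is initialized by kernel
#' k-means on the (PSD-repaired) measured correlation matrix. Each epoch
#' then (1) performs one pass of Adam updates over mini-batches of reads,
#' minimizing the total loss with the pair indicator fixed at the previous
#' epoch's attribution (loss pairs are restricted to reads within the same
#' mini-batch), and (2) recomputes the learned kernel on all reads and
#' refreshes the attribution with kernel k-means. After the last epoch the
#' consensus haplotypes and the MEC score are computed. The entire run is
#' reproducible from `tcfg$seed`.
#'
#' @param m a filtered [FragmentMatrix-class].
#' @param k ploidy (>= 2).
#' @param tcfg a [trainConfig()].
#' @param ecfg an [encoderConfig()].
#' @return a [PhasingResult-class]; `history` holds per-epoch loss terms and
#'   MEC (epoch 0 is the initial clustering).
#' @export
fitHaplotypes <- function(m, k, tcfg = trainConfig(), ecfg = encoderConfig()) {
  stopifnot(is(m, "FragmentMatrix"), k >= 2L)
  n <- nReads(m); l <- nSnps(m)
  if (k > n) stop("ploidy exceeds read count")
  set.seed(tcfg$seed)
  X <- .oneHotFlat(m@fragments)
  C <- measuredCorrelations(m)
  labels <- if (tcfg$init == "measured") {
    kernelKmeans(psdRepair(C), k, nstart = 10L)$labels
  } else {
    sample.int(k, n, replace = TRUE)
  }
  model <- initCorrModel(ecfg, l, seed = sample.int(.Machine$integer.max, 1L))
  params <- model$params
  state <- .adamInit(params)
  bs <- if (is.null(tcfg$batchSize)) ceiling(n / 5) else tcfg$batchSize
  rowIdx <- function(b) as.vector(outer(seq_len(l), (b - 1L) * l, `+`))

  hap <- consensusHaplotypes(m, labels, k)
  history <- data.frame(epoch = 0L, lc = NA_real_, lr = NA_real_,
                        ls = NA_real_, loss = NA_real_, mec = mec(m, hap))
  for (epoch in seq_len(tcfg$epochs)) {
    p <- pairIndicator(labels)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    tot <- c(loss = 0, lc = 0, lr = 0, ls = 0)
    for (b in batches) {
      lg <- .corrModelLossGrad(X[rowIdx(b), , drop = FALSE], length(b), l,
                               C[b, b, drop = FALSE], p[b, b, drop = FALSE],
                               params, model$cfg, tcfg$lambdaR, tcfg$lambdaS)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", epoch, "; try a smaller learning rate")
      up <- .adamStep(params, lg$grads, state, tcfg$learningRate)
      params <- up$params
      state <- up$state
      tot <- tot + c(lg$loss, lg$lc, lg$lr, lg$ls)
    }
    Sigma <- .fullSigma(X, n, l, params, model$cfg)
    labels <- kernelKmeans(Sigma, k, nstart = 10L, init = labels)$labels
    hap <- consensusHaplotypes(m, labels, k)
    history <- rbind(history,
                     data.frame(epoch = epoch, lc = tot[["lc"]],
                                lr = tot[["lr"]], ls = tot[["ls"]],
                                loss = tot[["loss"]], mec = mec(m, hap)))
  }
  model$params <- params
  new("PhasingResult", haplotypes = hap, labels = as.integer(labels),
      sigma = Sigma, mec = history$mec[nrow(history)],
      history = history, phaseSets = list(seq_len(l)))
}

#' Assemble haplotypes with multiple restarts, selecting by MEC
#'
#' Runs [fitHaplotypes()] `tcfg$restarts` times with independent seeds
#' derived from `tcfg$seed` and returns the result with the lowest MEC
#' score; ties are broken by the lower final training loss.
#'
#' @inheritParams fitHaplotypes
#' @return the best [PhasingResult-class]; the per-restart MEC scores are
#'   recorded in `history` attribute column `restart`.
#' @export
assembleHaplotypes <- function(m, k, tcfg = trainConfig(),
                               ecfg = encoderConfig()) {
  best <- NULL
  for (r in seq_len(tcfg$restarts)) {
    rcfg <- tcfg
    rcfg$seed <- tcfg$seed + (r - 1L) * 1009L
    rcfg$restarts <- 1L
    fit <- fitHaplotypes(m, k, rcfg, ecfg)
    finalLoss <- fit@history$loss[nrow(fit@history)]
    if (is.null(best) || fit@mec < best$fit@mec ||
        (fit@mec == best$fit@mec && finalLoss < best$loss)) {
      best <- list(fit = fit, loss = finalLoss)
    }
  }
  best$fit
}
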