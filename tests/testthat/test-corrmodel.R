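test_that("measured correlations follow the agree/disagree ratio", {
  # identical overlapping reads -> +1; disjoint reads -> 0
  m <- fragFromStrings(c("ACGT", "ACGT", "AC--", "--GA"))
  C <- measuredCorrelations(m)
  expect_true(isSymmetric(C))
  expect_equal(C[1, 2], 1)
  expect_equal(C[3, 4], 0)
  expect_equal(diag(C), rep(1, 4))
  # kSim = 3, kDissim = 1 -> (3-1)/(3+1) = 0.5
  m2 <- fragFromStrings(c("ACGT", "ACGA"))
  expect_equal(measuredCorrelations(m2)[1, 2], 0.5)
  # fully disagreeing overlap -> -1
  m3 <- fragFromStrings(c("AC", "CA"))
  expect_equal(measuredCorrelations(m3)[1, 2], -1)
  expect_true(all(abs(C) <= 1))
})

test_that("contrastive loss matches hand-computed pair sums", {
  # perfect polarization -> 0
  S <- rbind(c(1, 1, -1), c(1, 1, -1), c(-1, -1, 1))
  p <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  expect_equal(contrastiveLoss(S, p), 0)
  # n = 2, same-cluster pair at Sigma 0 -> (1-0)^2 = 1
  expect_equal(contrastiveLoss(diag(2), matrix(1, 2, 2)), 1)
  # n = 3, p off-diag (1,0,0), Sigma off-diag 0 -> 1 + 1 + 1
  p3 <- diag(3); p3[1, 2] <- p3[2, 1] <- 1
  expect_equal(contrastiveLoss(diag(3), p3), 3)
})

test_that("consistency regularizer is a masked Frobenius norm", {
  C <- diag(2); C[1, 2] <- C[2, 1] <- 0.25
  S <- diag(2); S[1, 2] <- S[2, 1] <- 0.75
  expect_equal(consistencyRegularizer(C, C), 0)
  expect_equal(consistencyRegularizer(S, C), sqrt(2 * 0.25), tolerance = 1e-12)
  # entries outside the support of C never contribute
  C3 <- diag(3); C3[1, 2] <- C3[2, 1] <- 0.5
  S3 <- C3
  S3[1, 3] <- S3[3, 1] <- 0.9                 # C[1,3] == 0 -> masked out
  expect_equal(consistencyRegularizer(S3, C3), 0)
})

test_that("sparsity regularizer sums absolute off-diagonal entries", {
  expect_equal(sparsityRegularizer(diag(3)), 0)
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  expect_equal(sparsityRegularizer(S), 3)
  S2 <- S; S2[1, 2] <- S2[2, 1] <- 0.9        # |entry| increase
  expect_gte(sparsityRegularizer(S2), sparsityRegularizer(S))
})

test_that("total loss combines the three terms with default weights", {
  # perfectly polarized two-read case: contrastive and consistency vanish,
  # leaving only the weighted sparsity of the off-diagonal correlation
  S1 <- rbind(c(1, -1), c(-1, 1))
  p1 <- diag(2)
  expect_equal(totalLoss(S1, S1, p1), 10 * 2)
  expect_equal(totalLoss(S1, S1, p1, lambdaS = 0), 0)
  # component values 1, 0.5, 0.2 with default weights -> 1 + 50 + 2
  expect_equal(1 + 100 * 0.5 + 10 * 0.2, 53)
  # lambdaR = lambdaS = 0 reduces to the contrastive term
  set.seed(1)
  S <- tcrossprod(matrix(rnorm(9), 3)); S <- cov2cor(S)
  Cm <- measuredCorrelations(fragFromStrings(c("ACG", "ACT", "GCT")))
  pm <- pairIndicator(c(1L, 1L, 2L))
  expect_equal(totalLoss(S, Cm, pm, 0, 0), contrastiveLoss(S, pm))
  expect_equal(totalLoss(S, Cm, pm),
               contrastiveLoss(S, pm) + 100 * consistencyRegularizer(S, Cm) +
                 10 * sparsityRegularizer(S))
})

test_that("embeddings have the contracted shape and are deterministic", {
  cfg <- tinyEncoder()
  toy <- toyDiploid(l = 12, width = 5)
  model <- initCorrModel(cfg, 12, seed = 5)
  Z <- encodeReads(toy$m, model)
  expect_equal(dim(Z), c(nReads(toy$m), cfg$dR))
  # identical fragment rows get identical embeddings
  m2 <- fragFromStrings(c("ACGTA", "ACGTA", "TTGCA"))
  model2 <- initCorrModel(cfg, 5, seed = 5)
  Z2 <- encodeReads(m2, model2)
  expect_equal(Z2[1, ], Z2[2, ])
  # two runs agree to floating-point noise
  expect_lt(max(abs(Z - encodeReads(toy$m, model))), 1e-6)
  expect_error(initCorrModel(cfg, 3), "too short")
})

test_that("convolutional encoder matches a direct-loop oracle", {
  cfg <- tinyEncoder()
  l <- 8L
  m <- fragFromStrings(c("ACGTTGCA"))
  model <- initCorrModel(cfg, l, seed = 2)
  p <- model$params
  # deterministic, varied weights so the oracle exercises every tap
  for (nm in names(p)) p[[nm]][] <- 0.01 * seq_along(p[[nm]]) %% 7 - 0.02
  for (i in 1:3) p[[paste0("c", i, ".a")]] <- 0.25
  model$params <- p
  Z <- encodeReads(m, model)

  oh <- oneHot(m)                              # 1 x 4 x l
  X <- t(oh[1, , ])                            # l x 4
  act <- X
  widths <- cfg$kernelWidths
  prelu <- function(x, a) ifelse(x > 0, x, a * x)
  for (layer in 1:3) {
    W <- p[[paste0("c", layer, ".W")]]
    b <- p[[paste0("c", layer, ".b")]]
    a <- p[[paste0("c", layer, ".a")]]
    w <- widths[layer]; h <- (w - 1) / 2
    cin <- ncol(act); cout <- length(b)
    out <- matrix(0, l, cout)
    for (pos in 1:l) for (f in 1:cout) {
      s <- b[f]
      for (o in -h:h) for (c in 1:cin) {
        if (pos + o >= 1 && pos + o <= l)
          s <- s + act[pos + o, c] * W[(o + h) * cin + c, f]
      }
      out[pos, f] <- prelu(s, a)
    }
    act <- out
  }
  flat <- as.vector(act)                       # column index (c-1)*l + p
  zOracle <- as.vector(flat %*% p[["d1.W"]]) + p[["d1.b"]]
  expect_equal(as.vector(Z), zOracle, tolerance = 1e-10)
})

test_that("learned Sigma is a unit-diagonal PSD Gram matrix", {
  cfg <- tinyEncoder()
  toy <- toyDiploid(l = 12, width = 5)
  model <- initCorrModel(cfg, 12, seed = 9)
  Z <- encodeReads(toy$m, model)
  S <- correlationForward(Z, model)
  expect_equal(diag(S), rep(1, nrow(S)), tolerance = 1e-5)
  expect_true(isSymmetric(S, tol = 1e-10))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  # oracle: Sigma must equal the naive double-loop product of the
  # row-normalized head output with itself
  X <- CorrHap:::.oneHotFlat(toy$m@fragments)
  fw <- CorrHap:::.modelForward(X, nReads(toy$m), 12, model$params, model$cfg)
  Qt <- fw$Qt
  n <- nrow(Qt)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) G[i, j] <- sum(Qt[i, ] * Qt[j, ])
  diag(G) <- 1
  expect_equal(S, G, tolerance = 1e-12)
  expect_equal(fw$Sigma, G, tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tinyEncoder()
  set.seed(31)
  frag <- matrix(sample(0:4, 6 * 10, replace = TRUE, prob = c(0.3, rep(0.175, 4))),
                 6, 10)
  frag[rowSums(frag > 0) < 2, 1:2] <- 1L
  m <- FragmentMatrix(frag)
  X <- CorrHap:::.oneHotFlat(frag)
  C <- measuredCorrelations(m)
  p <- pairIndicator(sample(1:2, 6, replace = TRUE))
  model <- initCorrModel(cfg, 10, seed = 13)
  lg <- CorrHap:::.corrModelLossGrad(X, 6, 10, C, p, model$params, cfg, 100, 10)
  lossAt <- function(params) {
    fw <- CorrHap:::.modelForward(X, 6, 10, params, cfg)
    CorrHap:::.lossGradSigma(fw$Sigma, C, p, 100, 10)$loss
  }
  eps <- 1e-5
  for (nm in names(model$params)) {
    len <- length(model$params[[nm]])
    for (i in unique(c(1L, len))) {
      p1 <- model$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
      an <- lg$grads[[nm]][i]
      # relative check with an absolute floor: directions with (near-)zero
      # gradient (e.g. the key bias, a softmax-invariant direction) are
      # compared absolutely against finite-difference noise
      if (max(abs(fd), abs(an)) > 1e-4) {
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)),
                  1e-3, label = sprintf("gradient of %s[%d]", nm, i))
      } else {
        expect_lt(abs(fd - an), 1e-3,
                  label = sprintf("gradient of %s[%d] (abs)", nm, i))
      }
    }
  }
})

test_that("pair indicator is a symmetric equivalence indicator", {
  p <- pairIndicator(c(1L, 2L, 1L, 3L))
  expect_true(isSymmetric(p))
  expect_equal(diag(p), rep(1, 4))
  expect_equal(p[1, 3], 1)
  expect_equal(p[1, 2], 0)
})

test_that("model checkpoints round-trip through a file", {
  cfg <- tinyEncoder()
  model <- initCorrModel(cfg, 8, seed = 1)
  path <- tempfile(fileext = ".rds")
  saveCorrModel(model, path)
  back <- loadCorrModel(path)
  expect_equal(back$params, model$params)
  expect_equal(back$cfg, model$cfg)
})
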