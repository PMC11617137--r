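# Independent oracles used across the suite.  These deliberately avoid
# the package's Fisher-scoring path: they exploit the fact that the
# component contrasts are Walsh functions of the 2x2x2 factorial, so
# every model covariance is diagonal in the (scaled) Walsh basis and
# the Gaussian likelihood has a closed form in the 8 diagonal
# coordinates.

# orthonormal Walsh basis: mean, 6 components, three-way interaction
walshBasis <- function() {
  tt <- trialTypes()
  V <- cbind(mean = rep(1, 8),
             sapply(c("HT_dist", "ET_dist", "HE_dist",
                      "T_dir", "H_dir", "E_dir"),
                    contrastVector),
             three_way = tt$hand * tt$target * tt$gaze)
  V / sqrt(8)
}

# closed-form log-likelihood of n i.i.d. voxels with diagonal (Walsh)
# model eigenvalues lam given the Walsh-diagonal s of the sample second
# moment; off-diagonal energy of S never enters because Sigma^{-1} is
# diagonal in this basis.
walshLogLik <- function(s, lam, n) {
  -0.5 * n * sum(log(2 * pi) + log(lam) + s / lam)
}

# brute-force profile-likelihood ML over (w_components, sigma2): for a
# fixed sigma2 each included direction's optimal eigenvalue is
# max(s_d, sigma2); sigma2 is then found on a fine log grid.
gridSearchML <- function(U, compNames, nGrid = 4000) {
  V <- walshBasis()
  n <- ncol(U)
  S <- tcrossprod(U) / n
  s <- diag(t(V) %*% S %*% V)
  inc <- colnames(V) %in% compNames
  sig <- exp(seq(log(min(s) / 10), log(max(s) * 2), length.out = nGrid))
  prof <- vapply(sig, function(s2) {
    lam <- ifelse(inc, pmax(s, s2), s2)
    walshLogLik(s, lam, n)
  }, numeric(1))
  i <- which.max(prof)
  s2 <- sig[i]
  w <- pmax(s[compNames] - s2, 0)
  list(w = w, sigma2 = s2, logLik = prof[i])
}

# moment estimator of a planted weight: projection of the sample second
# moment on the component direction, minus a noise estimate taken from
# the two Walsh directions no component occupies.
projectionEstimate <- function(U, comp) {
  V <- walshBasis()
  S <- tcrossprod(U) / ncol(U)
  s <- diag(t(V) %*% S %*% V)
  sigma2 <- mean(s[c("mean", "three_way")])
  unname(s[comp] - sigma2)
}

# a single-component ComponentSet for toy problems
singleComponent <- function(name) {
  new("ComponentSet",
      contrasts = contrastMatrix(componentModels())[, name, drop = FALSE],
      conditionLabels = conditionLabels())
}

# quick synthetic U without the PatternSet scaffolding
drawU <- function(weights, noiseVar, nVoxels, seed) {
  set.seed(seed)
  Sigma <- diag(noiseVar, 8)
  Gs <- modelMatrices(componentModels())
  for (nm in names(weights)) Sigma <- Sigma + weights[[nm]] * Gs[[nm]]
  e <- eigen(Sigma, symmetric = TRUE)
  U <- (e$vectors %*% diag(sqrt(pmax(e$values, 0)), 8)) %*%
    matrix(rnorm(8 * nVoxels), 8, nVoxels)
  rownames(U) <- conditionLabels()
  U
}

# manufacture a NullEvidence with prescribed real/null values
fakeNull <- function(real, null) {
  new("NullEvidence", real = real, null = null,
      perms = matrix(rep(1:8, nrow(null)), nrow(null), 8, byrow = TRUE),
      seed = 0L, nSubjects = 1L)
}
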