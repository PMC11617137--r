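test_that("generative specs validate their inputs", {
  expect_error(generativeSpec(weights = c(ET_dist = 0), noiseVar = 0),
               "positive")
  expect_error(generativeSpec(weights = c(bogus = 1)), "named by component")
  expect_error(generativeSpec(weights = c(ET_dist = -1)), "non-negative")
  expect_error(generativeSpec(nVoxels = 0), ">= 1")
})

test_that("pattern generation is deterministic under the spec seed", {
  sp <- generativeSpec(nVoxels = 50, nSubjects = 2, nRuns = 2, seed = 99)
  a <- generatePatterns(sp)
  b <- generatePatterns(sp)
  expect_identical(lapply(assayNames(a), function(nm) assay(a, nm)),
                   lapply(assayNames(b), function(nm) assay(b, nm)))
  c <- generatePatterns(generativeSpec(nVoxels = 50, nSubjects = 2,
                                       nRuns = 2, seed = 100))
  expect_false(identical(assay(a, "s01_r1"), assay(c, "s01_r1")))
})

test_that("the sample second moment converges to the generative covariance", {
  # noise-only: sample covariance approaches the identity as voxels grow
  err <- vapply(c(200, 2000, 20000), function(nv) {
    U <- drawU(c(), 1, nv, seed = nv)
    norm(tcrossprod(U) / nv - diag(8), "F")
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.15)
  # a planted weight is recovered by projection on its component
  U <- drawU(c(ET_dist = 4), 1, 10000, seed = 7)
  expect_lt(abs(projectionEstimate(U, "ET_dist") - 4) / 4, 0.10)
})

test_that("per-subject true G matches the weighted component sum", {
  sp <- generativeSpec(weights = c(HT_dist = 3), noiseVar = 2,
                       nVoxels = 10, nSubjects = 1, nRuns = 1)
  ps <- generatePatterns(sp)
  Gs <- modelMatrices(componentModels())
  expect_equal(metadata(ps)$trueG[[1]], 3 * Gs$HT_dist + diag(2, 8),
               ignore_attr = TRUE)
})

test_that("simulated BOLD obeys OLS theory", {
  run <- sampleRun(seed = 21)
  X <- buildDesignMatrix(run, "early")
  amp <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(conditionLabels(), NULL))
  # noiseless generation-estimation identity
  y <- generateBold(run, list(early = amp), noiseSd = 0)
  expect_equal(estimateBetas(y, X), amp, tolerance = 1e-8)
  # zero amplitudes: betas centred on zero, with the sampling
  # covariance sigma^2 (X'X)^{-1} (each voxel is one replicate)
  y0 <- generateBold(run, list(early = matrix(0, 8, 500)), noiseSd = 2,
                     seed = 22)
  B <- estimateBetas(y0, X, conditionsOnly = FALSE)
  expect_lt(max(abs(rowMeans(B[conditionLabels(), ]))), 0.5)
  theo <- 4 * diag(chol2inv(chol(crossprod(designMatrix(X)))))
  names(theo) <- colnames(designMatrix(X))
  emp <- apply(B[conditionLabels(), ], 1, var)
  expect_lt(max(abs(emp / theo[conditionLabels()] - 1)), 0.15)
  # dimension / epoch validation
  expect_error(generateBold(run, list(middle = amp)), "unknown epoch")
  expect_error(generateBold(run, list(early = amp[1:4, , drop = FALSE])),
               "8 condition rows")
})

test_that("fixtures have the documented dimensions", {
  tiny <- makeFixture("tiny", seed = 2)
  expect_equal(length(subjectIds(tiny)), 4L)
  expect_equal(length(assayNames(tiny)), 4L * 2L)
  expect_equal(ncol(assay(tiny, "s01_r1")), 200L)
  sp <- metadata(makeFixture("tiny", seed = 2))$spec
  expect_equal(sp$nSubjects, 4L)
  # study-scale profile mirrors the experiment: 27 subjects, 6 runs
  spPaper <- generativeSpec()
  expect_equal(spPaper$nSubjects, 27L)
  expect_equal(spPaper$nRuns, 6L)
})
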