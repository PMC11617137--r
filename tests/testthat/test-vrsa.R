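test_that("the second moment matches hand computation and edge cases", {
  U <- rbind(c(1, 2), c(3, 4))
  expect_equal(secondMomentMatrix(secondMoment(U, center = FALSE,
                                               normalize = FALSE)),
               rbind(c(5, 11), c(11, 25)))
  expect_equal(secondMomentMatrix(secondMoment(matrix(0, 8, 5))),
               matrix(0, 8, 8))
  # orthonormal condition rows without normalisation: G = I
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(secondMomentMatrix(secondMoment(t(Q), center = FALSE,
                                               normalize = FALSE)),
               diag(5), tolerance = 1e-12)
  # centering removes each voxel's mean across conditions
  U2 <- matrix(rnorm(40), 8, 5)
  G <- secondMomentMatrix(secondMoment(U2, center = TRUE))
  expect_equal(max(abs(colSums(G))), 0, tolerance = 1e-10)
})

test_that("noise-only data yields unit noise and silent components", {
  U <- drawU(c(), 1, 10000, seed = 11)
  fit <- fitComponents(U)
  w <- hyperparameters(fit)
  expect_true(fit@converged)
  expect_lt(abs(w[["noise"]] - 1), 0.1)
  expect_true(all(w[setdiff(names(w), "noise")] < 0.05))
})

test_that("the variational fit matches the brute-force ML oracle on toy problems", {
  # one component + noise
  U <- drawU(c(ET_dist = 2), 1, 5000, seed = 12)
  fit <- fitComponents(U, singleComponent("ET_dist"), center = FALSE)
  oracle <- gridSearchML(U, "ET_dist")
  expect_lt(abs(hyperparameters(fit)[["ET_dist"]] / oracle$w[["ET_dist"]] - 1),
            0.10)
  expect_lt(abs(fit@logLik - oracle$logLik), 0.5)
  # free energy is bounded by the maximised likelihood
  expect_lt(fit@F, oracle$logLik)
})

test_that("free energy does not decrease over Fisher-scoring iterations", {
  U <- drawU(c(T_dir = 1.5), 1, 1000, seed = 13)
  F_by_iter <- vapply(c(1L, 2L, 4L, 8L, 128L), function(it)
    freeEnergy(fitComponents(U, maxIter = it)), numeric(1))
  expect_true(all(diff(F_by_iter) >= -1e-6))
})

test_that("removing a needed component costs evidence; an idle one costs ~nothing", {
  U <- drawU(c(ET_dist = 4), 1, 10000, seed = 14)
  fit <- fitComponents(U)
  for (m in c("bmr", "refit")) {
    d <- deltaF(componentEvidence(fit, method = m))
    expect_lt(d[["ET_dist"]], -10)
  }
  # the explicit-refit evidence for absent components is negligible
  d <- deltaF(componentEvidence(fit, method = "refit"))
  expect_true(all(abs(d[setdiff(names(d), "ET_dist")]) <= 3))
})

test_that("group evidence adds over subjects", {
  U <- drawU(c(ET_dist = 2), 1, 500, seed = 15)
  ev <- componentEvidence(fitComponents(U))
  expect_equal(deltaF(groupEvidence(list(ev))), deltaF(ev))
  g2 <- groupEvidence(list(ev, ev))
  expect_equal(deltaF(g2), 2 * deltaF(ev))
  expect_equal(g2@nSubjects, 2L)
  # same-sign evidence: the group is more extreme than any single subject
  evs <- lapply(1:4, function(s)
    componentEvidence(fitComponents(drawU(c(ET_dist = 2), 1, 500,
                                          seed = 20 + s))))
  g <- deltaF(groupEvidence(evs))[["ET_dist"]]
  expect_true(all(vapply(evs, function(e) deltaF(e)[["ET_dist"]], 1) > g))
  expect_error(groupEvidence(list()), "length")
})
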