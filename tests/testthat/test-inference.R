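test_that("the identity permutation reproduces the real pipeline bitwise", {
  ps <- makeFixture("tiny", seed = 41)
  nd <- shuffleNull(ps, K = 5, seed = 42)
  evs <- lapply(subjectIds(ps), function(s)
    componentEvidence(fitComponents(subjectPatterns(ps, s))))
  expect_identical(unname(realEvidence(nd)),
                   unname(deltaF(groupEvidence(evs))))
  # no shuffle is the identity, and shuffles are seed-reproducible
  expect_false(any(apply(nd@perms, 1, identical, y = 1:8)))
  nd2 <- shuffleNull(ps, K = 5, seed = 42)
  expect_identical(nullEvidence(nd), nullEvidence(nd2))
})

test_that("relabelling conditions preserves the second-moment spectrum", {
  U <- drawU(c(ET_dist = 2, H_dir = 1), 1, 300, seed = 43)
  G <- secondMomentMatrix(secondMoment(U))
  set.seed(44)
  for (k in 1:10) {
    p <- sample.int(8)
    Gp <- G[p, p]
    expect_equal(sum(diag(Gp)), sum(diag(G)))
    expect_equal(eigen(Gp, symmetric = TRUE, only.values = TRUE)$values,
                 eigen(G, symmetric = TRUE, only.values = TRUE)$values,
                 tolerance = 1e-9)
  }
})

test_that("log Bayes factors are shuffled-minus-real", {
  nd <- fakeNull(real = c(A = -12), null = matrix(-2, 5, 1,
                                                  dimnames = list(NULL, "A")))
  expect_equal(unname(logBayesFactors(nd)[, 1]), rep(10, 5))
  nd0 <- fakeNull(real = c(A = -7), null = matrix(-7, 5, 1,
                                                   dimnames = list(NULL, "A")))
  expect_equal(unname(logBayesFactors(nd0)[, 1]), rep(0, 5))
})

test_that("the credibility rule is ln(3) above the null quantile", {
  # symmetric null of K = 99 shuffles whose 95% strongest effect (the
  # ceiling(0.95 * 100) = 95th order statistic of strengths) is 2.0;
  # the real median LBF is 3.2, and 3.2 >= ln(3) + 2.0 is credible
  centred <- (-49:49) * (2 / 45)
  nd <- fakeNull(real = c(A = -3.2),
                 null = matrix(centred, ncol = 1,
                               dimnames = list(NULL, "A")))
  # median(LBF) = median(null) - real = 0 + 3.2
  fl <- credibility(nd, 0.95)
  expect_true(unname(fl))
  expect_equal(unname(attr(fl, "threshold")), log(3) + 2, tolerance = 1e-9)
  # just under the threshold: not credible
  nd2 <- fakeNull(real = c(A = -3.0),
                  null = matrix(centred, ncol = 1,
                                dimnames = list(NULL, "A")))
  expect_false(unname(credibility(nd2, 0.95)))
  # degenerate constant null: decided by median(LBF) >= ln(3)
  cons <- matrix(0, 30, 1, dimnames = list(NULL, "A"))
  expect_true(unname(credibility(fakeNull(c(A = -1.2), cons), 0.95)))
  expect_false(unname(credibility(fakeNull(c(A = -1.0), cons), 0.95)))
})

test_that("95% flags are a subset of 80% flags", {
  set.seed(45)
  for (k in 1:20) {
    nd <- fakeNull(real = setNames(rnorm(3, sd = 3), c("A", "B", "C")),
                   null = matrix(rnorm(150, sd = 3), 50, 3,
                                 dimnames = list(NULL, c("A", "B", "C"))))
    expect_true(all(credibility(nd, 0.80) | !credibility(nd, 0.95)))
  }
})

test_that("under pure noise the real evidence sits inside the null", {
  inside <- vapply(1:20, function(s) {
    ps <- makeFixture("tiny", seed = 300 + s, weights = c())
    nd <- shuffleNull(ps, K = 200, seed = 600 + s)
    lo <- apply(nullEvidence(nd), 2, quantile, 0.05)
    hi <- apply(nullEvidence(nd), 2, quantile, 0.95)
    sum(realEvidence(nd) >= lo & realEvidence(nd) <= hi)
  }, numeric(1))
  expect_gte(median(inside), 5)
})

test_that("reports flag a planted component only where it is planted", {
  psA <- makeFixture("tiny", seed = 46, weights = c(ET_dist = 2))
  psB <- makeFixture("tiny", seed = 47, weights = c())
  repA <- evidenceReport(shuffleNull(psA, K = 200, seed = 48))
  repB <- evidenceReport(shuffleNull(psB, K = 200, seed = 49))
  expect_true(repA$credible_95[repA$component == "ET_dist"])
  expect_false(repB$credible_95[repB$component == "ET_dist"])
  expect_named(repA, c("component", "median_lbf", "hdi_lower", "hdi_upper",
                       "threshold_80", "credible_80", "threshold_95",
                       "credible_95"))
  expect_true(all(repA$hdi_lower <= repA$median_lbf &
                    repA$median_lbf <= repA$hdi_upper))
  # the bar-plot rendering runs cleanly on a report
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plotEvidence(repA))
})

test_that("the empirical HDI is the shortest covering window", {
  set.seed(50)
  for (k in 1:10) {
    x <- rnorm(200)
    h <- hdi(x, 0.9)
    expect_gte(mean(x >= h[1] & x <= h[2]), 0.9)
    # brute force over all windows of the required size
    xs <- sort(x)
    m <- ceiling(0.9 * length(xs))
    widths <- xs[(m + 1):length(xs)] - xs[1:(length(xs) - m)]
    expect_equal(unname(h[2] - h[1]), min(widths))
  }
})
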