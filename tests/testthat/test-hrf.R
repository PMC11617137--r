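test_that("the canonical HRF peaks 5-6 s after onset and undershoots later", {
  t <- seq(0, 32, by = 0.01)
  h <- canonicalHrf(t)
  expect_gt(t[which.max(h)], 4.5)
  expect_lt(t[which.max(h)], 6.5)
  expect_lt(min(h), 0)           # undershoot
  expect_equal(canonicalHrf(-1), 0)
})

test_that("epoch windows sit at target onset (early) and before the cue (late)", {
  run <- sampleRun(seed = 3)
  tr <- run@trials
  i <- which(!tr$go)[1]
  early <- epochWindows(run, "early")
  late <- epochWindows(run, "late")
  # the windows belonging to trial i
  we <- early[early$column == tr$label[i] & early$on == tr$target_onset[i], ]
  wl <- late[late$column == tr$label[i] & late$off == tr$cue[i], ]
  expect_equal(nrow(we), 1L)
  expect_equal(we$off - we$on, 2)
  expect_equal(nrow(wl), 1L)
  expect_equal(wl$on, tr$cue[i] - 2)
  # a 4 s plan makes early and late boxcars adjacent, not overlapping
  j <- which(!tr$go & tr$plan == 4)[1]
  expect_equal(tr$target_onset[j] + 2, tr$cue[j] - 2)
})

test_that("design matrices have the contracted shape and no empty condition column", {
  run <- sampleRun(seed = 5)
  X <- buildDesignMatrix(run, "late")
  expect_true(validObject(X))
  M <- designMatrix(X)
  expect_equal(nrow(M), run@nScans)
  expect_setequal(colnames(M), c(conditionLabels(), "go_plan", "movement",
                                 "intercept"))
  expect_true(all(colSums(abs(M[, conditionLabels()])) > 0))
  expect_error(buildDesignMatrix(run, "middle"))
})

test_that("VIF matches its closed forms and detects collinearity", {
  # orthogonal columns: no inflation
  expect_equal(as.numeric(vif(diag(4))), 1)
  # two unit-norm columns at correlation r: VIF = 1 / (1 - r^2)
  for (r in c(0.3, 0.5, 0.8)) {
    X <- cbind(a = c(1, 0), b = c(r, sqrt(1 - r^2)))
    expect_equal(as.numeric(vif(X)), 1 / (1 - r^2))
  }
  # duplicated column: rank deficiency named
  expect_error(vif(cbind(x = 1:5, y = 2:6, z = 1:5)), "collinear")
  # VIF >= 1 for any full-rank design
  set.seed(1)
  for (k in 1:10) {
    X <- matrix(rnorm(60), 20, 3)
    expect_gte(as.numeric(vif(X)), 1)
  }
})
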