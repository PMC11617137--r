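test_that("largest-remainder allocation reproduces the study duration counts", {
  # delays: 40 * [.52 .26 .13 .06 .03] = [20.8 10.4 5.2 2.4 1.2];
  # floors leave 2 slots, remainders [.8 .4 .2 .4 .2]; the .8 goes to
  # 1 s and the .4 tie resolves toward the shorter duration (2 s)
  expect_equal(largestRemainder(c(0.52, 0.26, 0.13, 0.06, 0.03), 40),
               c(21L, 11L, 5L, 2L, 1L))
  expect_equal(largestRemainder(c(0.56, 0.30, 0.14), 40), c(22L, 12L, 6L))
  # allocation always sums to n
  for (k in 1:20) {
    p <- runif(5); p <- p / sum(p)
    expect_equal(sum(largestRemainder(p, 37)), 37L)
  }
})

test_that("sampled runs satisfy the composition invariants", {
  for (seed in seq_len(60)) {
    run <- sampleRun(seed = seed)
    tr <- run@trials
    expect_true(validObject(run))
    expect_equal(nrow(tr), 40L)
    expect_true(all(table(tr$label) == 5L))
    expect_equal(sum(tr$go), 24L)
    expect_equal(as.integer(table(tr$delay)[c("1", "2", "4", "8", "16")]),
                 c(21L, 11L, 5L, 2L, 1L))
    expect_equal(as.integer(table(tr$plan)[c("4", "6", "8")]),
                 c(22L, 12L, 6L))
    expect_equal(tr$cue, tr$target_onset + tr$plan)
    expect_true(all(diff(tr$onset) > 0))
  }
})

test_that("run sampling is bit-for-bit reproducible under a seed", {
  expect_identical(sampleRun(seed = 42), sampleRun(seed = 42))
  expect_false(identical(sampleRun(seed = 42)@trials,
                         sampleRun(seed = 43)@trials))
})

test_that("design search returns the single candidate when n = 1 and improves with more", {
  one <- optimizeDesign(nCandidates = 1, seed = 9)
  expect_s4_class(one$design, "RunDesign")
  expect_equal(one$achievedVIF, max(one$scores))
  # nested candidate streams under a fixed seed: min over a superset
  a <- optimizeDesign(nCandidates = 8, seed = 11)
  b <- optimizeDesign(nCandidates = 20, seed = 11)
  expect_equal(a$scores, b$scores[1:8])
  expect_lte(b$achievedVIF, a$achievedVIF)
})
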