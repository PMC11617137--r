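test_that("contrast signs encode side and distance as specified", {
  tt <- trialTypes()
  # gaze and target share a side on H=L, T=R, E=R: ET near (+1)
  expect_equal(contrastVector("ET_dist")[tt$label == "L-R-R"], 1)
  # left-sided target codes -1
  expect_equal(contrastVector("T_dir")[tt$label == "R-L-R"], -1)
  # a distance contrast is the product of its two direction contrasts
  expect_equal(contrastVector("HT_dist"),
               contrastVector("H_dir") * contrastVector("T_dir"))
  expect_equal(contrastVector("ET_dist"),
               contrastVector("E_dir") * contrastVector("T_dir"))
  expect_equal(contrastVector("HE_dist"),
               contrastVector("H_dir") * contrastVector("E_dir"))
  expect_error(contrastVector("XY_dist"), "unknown component")
})

test_that("model matrices are trace-one rank-one and sign-structured", {
  Gs <- modelMatrices(componentModels())
  expect_named(Gs, c("HT_dist", "ET_dist", "HE_dist",
                     "T_dir", "H_dir", "E_dir"))
  for (G in Gs) {
    expect_equal(sum(diag(G)), 1)
    expect_equal(qr(G)$rank, 1L)
    expect_equal(G, t(G))
    expect_true(all(diag(G) == diag(G)[1]))
  }
  # both L-R-R and R-L-L are ET-near: entry positive
  expect_gt(Gs$ET_dist["L-R-R", "R-L-L"], 0)
  # an ET-near and an ET-far condition disagree: entry negative
  expect_lt(Gs$ET_dist["L-R-R", "L-L-R"], 0)
})

test_that("the six components are mutually trace-orthogonal and complete the Hadamard basis", {
  Gs <- modelMatrices(componentModels())
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(sum(Gs[[i]] * Gs[[j]]), 0)
  # contrasts + ones + three-way product: complete orthogonal basis
  V <- walshBasis() * sqrt(8)
  expect_equal(crossprod(V), diag(8) * 8, ignore_attr = TRUE)
})

test_that("model matrices are invariant to flipping the left/right coding", {
  tt <- trialTypes()
  flipped <- tt
  flipped$hand <- -tt$hand; flipped$target <- -tt$target
  flipped$gaze <- -tt$gaze
  for (nm in c("HT_dist", "ET_dist", "HE_dist", "T_dir", "H_dir", "E_dir")) {
    v0 <- contrastVector(nm, tt)
    v1 <- contrastVector(nm, flipped)
    expect_equal(tcrossprod(v1) / sum(v1^2), tcrossprod(v0) / sum(v0^2))
  }
})
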