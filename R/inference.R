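#' Shuffle-label null distribution of group log evidences
#'
#' Repeats the full fit-and-score pipeline under random permutations of
#' the eight condition labels.  Per iteration one permutation is drawn
#' (with replacement from the 8! - 1 non-identity permutations) and
#' applied identically across all subjects; each subject's model is
#' refitted on the relabelled second-moment matrix, every component is
#' scored by Bayesian model reduction, and the per-subject `deltaF`
#' values are summed to the group level.  The identity permutation is
#' evaluated first and stored as the real evidence, so it reproduces
#' the unshuffled pipeline exactly.
#'
#' @param x a [PatternSet-class], or a list of per-subject
#'   conditions x voxels matrices.
#' @param components a [ComponentSet-class].
#' @param K number of shuffles (the study used 1000).
#' @param seed integer seed for the permutation draws.
#' @param pooling run pooling when `x` is a `PatternSet`.
#' @param center,priorMean,priorVar,tol,maxIter passed to the fit.
#' @param redMean,redVar the reduced ("off") prior used in scoring.
#' @return A [NullEvidence-class].
#' @export
#' @examples
#' ps <- makeFixture("tiny")
#' nd <- shuffleNull(ps, K = 20, seed = 1)
#' nd
shuffleNull <- function(x, components = componentModels(), K = 1000,
                        seed = 1, pooling = "average", center = TRUE,
                        priorMean = -3, priorVar = 16, tol = 1e-4,
                        maxIter = 128L, redMean = -32, redVar = 1e-6) {
  stopifnot(K >= 1)
  Us <- if (is(x, "PatternSet")) {
    lapply(subjectIds(x), function(s) subjectPatterns(x, s, pooling))
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    x
  }
  Ss <- lapply(Us, function(U) secondMoment(U, center = center))
  Scube <- array(unlist(lapply(Ss, secondMomentMatrix)),
                 dim = c(8, 8, length(Ss)))
  ns <- vapply(Ss, function(s) as.numeric(s@nVoxels), numeric(1))

  set.seed(seed)
  perms <- matrix(0L, K, 8L)
  for (k in seq_len(K)) {
    repeat {
      p <- sample.int(8L)
      if (!identical(p, 1:8)) break
    }
    perms[k, ] <- p
  }
  allperms <- rbind(1:8, perms)

  nm <- componentNames(components)
  m <- length(nm) + 1L
  pm <- .expand_prior(priorMean, m)
  pv <- .expand_prior(priorVar, m)
  B <- .contrast_basis(center)
  ## relabel and project in R so the identity row shares the exact
  ## floating-point path of fitComponents()
  nsub <- length(Ss)
  SP <- array(0, c(ncol(B), ncol(B), nrow(allperms) * nsub))
  for (r in seq_len(nrow(allperms))) {
    p <- allperms[r, ]
    for (s in seq_len(nsub))
      SP[, , (r - 1L) * nsub + s] <-
        crossprod(B, Scube[p, p, s] %*% B)
  }
  res <- .null_evidence_cpp(SP, ns,
                            .project_cube(.g_cube(components), B),
                            nrow(allperms), pm, pv, redMean, redVar,
                            tol, as.integer(maxIter))
  d <- res$deltaF
  colnames(d) <- nm
  if (res$nonConverged > 0)
    message(res$nonConverged, " fit(s) did not converge within maxIter")
  new("NullEvidence", real = setNames(d[1, ], nm),
      null = d[-1, , drop = FALSE], perms = perms,
      seed = as.integer(seed), nSubjects = length(Us))
}

#' Log Bayes factors against the shuffle null
#'
#' For each shuffle `k`, `LBF_k = deltaF_shuffled[k] - deltaF_real`.
#' Because more negative `deltaF` is stronger evidence, positive LBF
#' values mean the real labelling carries more evidence for the
#' component than the shuffled one.
#'
#' @param null a [NullEvidence-class].
#' @return K x components matrix of log Bayes factors.
#' @export
logBayesFactors <- function(null) {
  stopifnot(is(null, "NullEvidence"))
  sweep(null@null, 2, null@real)
}

#' Shortest interval holding a given mass of a sample
#'
#' Empirical highest-density interval: the shortest window over the
#' sorted sample containing `ceiling(mass * n)` points.
#'
#' @param x numeric sample.
#' @param mass interval mass in (0, 1].
#' @return c(lower, upper).
#' @export
hdi <- function(x, mass = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  w <- x[starts + m] - x[starts]
  i <- which.min(w)
  c(lower = x[i], upper = x[i + m])
}

#' The "three times more credible" decision rule
#'
#' A component is flagged credible at `level` when the real effect is
#' three times more credible (ln(3) on the log-evidence scale) than the
#' level-strongest effect of the shuffle null.  Strength is measured
#' against the null median: the real strength is `median(LBF)` and the
#' null strengths are `median_j(deltaF_shuf) - deltaF_shuf_k` (more
#' negative log evidence = stronger effect, so the strong tail of the
#' null is its most negative deltaF values).  The flag is
#' `median(LBF) >= ln(3) + nullStrength_(m)` with
#' `m = ceiling(level * (K + 1))`, the exact permutation-test order
#' statistic for a level-`level` reference (an interpolated sample
#' quantile of K draws sits below the population quantile and loses
#' exactness; the `K + 1` convention restores
#' `P(real >= threshold) <= 1 - level` under exchangeability).  A
#' degenerate (constant) null reduces the rule to
#' `median(LBF) >= ln(3)`.
#'
#' @param null a [NullEvidence-class].
#' @param level quantile of the null ("strongest effect"), typically
#'   0.80 or 0.95.
#' @return Named logical vector, one flag per component, with the
#'   per-component thresholds in attribute `"threshold"`.
#' @export
credibility <- function(null, level = 0.95) {
  lbf <- logBayesFactors(null)
  med <- apply(lbf, 2, median)
  ref <- sweep(-null@null, 2, -apply(null@null, 2, median))
  m <- min(ceiling(level * (nrow(ref) + 1)), nrow(ref))
  thr <- log(3) + apply(ref, 2, function(x) sort(x)[m])
  structure(med >= thr, threshold = thr)
}

#' Per-component evidence report
#'
#' Summarises a shuffle-null analysis as a figure-style table: median
#' log Bayes factor, highest-density interval, and credibility flags at
#' the 80% and 95% levels.
#'
#' @param null a [NullEvidence-class].
#' @param levels credibility levels.
#' @param hdiMass mass of the reported HDI.
#' @return data.frame with one row per component.
#' @export
#' @examples
#' ps <- makeFixture("tiny")
#' evidenceReport(shuffleNull(ps, K = 50, seed = 1))
evidenceReport <- function(null, levels = c(0.80, 0.95), hdiMass = 0.95) {
  lbf <- logBayesFactors(null)
  out <- data.frame(
    component = colnames(lbf),
    median_lbf = apply(lbf, 2, median),
    hdi_lower = apply(lbf, 2, function(x) hdi(x, hdiMass)[1]),
    hdi_upper = apply(lbf, 2, function(x) hdi(x, hdiMass)[2]),
    row.names = NULL, stringsAsFactors = FALSE)
  for (lv in levels) {
    fl <- credibility(null, lv)
    out[[sprintf("threshold_%d", round(100 * lv))]] <-
      as.numeric(attr(fl, "threshold"))
    out[[sprintf("credible_%d", round(100 * lv))]] <- as.logical(fl)
  }
  out
}

#' Bar plot of an evidence report
#'
#' Median log Bayes factors with HDI error bars; asterisks mark
#' components credible at the 95% (black) or 80% (grey) level.
#'
#' @param report output of [evidenceReport()].
#' @param main plot title.
#' @return Invisibly, the bar midpoints.
#' @export
plotEvidence <- function(report, main = "Component evidence") {
  ylim <- range(0, report$hdi_lower, report$hdi_upper)
  mids <- graphics::barplot(report$median_lbf,
                            names.arg = report$component,
                            ylab = "log Bayes factor", main = main,
                            ylim = ylim * 1.15, las = 2)
  graphics::arrows(mids, report$hdi_lower, mids, report$hdi_upper,
                   angle = 90, code = 3, length = 0.04)
  y <- max(report$hdi_upper) * 1.08
  if (any(report$credible_95))
    graphics::text(mids[report$credible_95], y, "*", cex = 1.6)
  if (any(report$credible_80 & !report$credible_95))
    graphics::text(mids[report$credible_80 & !report$credible_95], y, "*",
                   col = "grey50", cex = 1.6)
  invisible(mids)
}
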