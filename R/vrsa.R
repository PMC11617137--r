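#' Condition-by-condition second-moment matrix
#'
#' `G = U U^T / n_voxels` (voxel-count normalisation), optionally after
#' subtracting each voxel's mean across conditions.  Centering is the
#' default in the fitting pipeline because the shared-mean pattern is
#' not among the hypothesis components.
#'
#' @param U conditions x voxels matrix.
#' @param center subtract each voxel's mean across conditions first?
#' @param normalize divide by the voxel count?
#' @return A [SecondMoment-class].
#' @export
#' @examples
#' U <- matrix(c(1, 3, 2, 4), 2, 2)  # rows = conditions
#' secondMomentMatrix(secondMoment(U, center = FALSE, normalize = FALSE))
secondMoment <- function(U, center = TRUE, normalize = TRUE) {
  stopifnot(is.matrix(U), all(is.finite(U)))
  if (center) U <- sweep(U, 2, colMeans(U))
  G <- tcrossprod(U)
  if (normalize) G <- G / ncol(U)
  new("SecondMoment", G = G, nVoxels = ncol(U), centered = center)
}

.expand_prior <- function(x, m) {
  if (length(x) == 1L) rep(x, m) else {
    stopifnot(length(x) == m)
    x
  }
}

.g_cube <- function(components) {
  Gs <- modelMatrices(components)
  array(unlist(Gs), dim = c(8, 8, length(Gs)),
        dimnames = list(NULL, NULL, names(Gs)))
}

## Orthonormal basis of the fitted space.  Centered patterns are flat
## along the shared-mean direction, so the model is fitted in the
## 7-dimensional complement of the ones vector, where the projected
## noise component stays the identity; uncentered fits use all 8
## dimensions.
.contrast_basis <- function(centered) {
  if (!centered) return(diag(8))
  qr.Q(qr(cbind(rep(1, 8), diag(8))))[, 2:8]
}

.project_cube <- function(G, B) {
  m <- dim(G)[3]
  out <- array(0, dim = c(ncol(B), ncol(B), m))
  for (k in seq_len(m)) out[, , k] <- crossprod(B, G[, , k] %*% B)
  out
}

#' Fit covariance components by variational ReML
#'
#' Models each voxel's condition vector as zero-mean Gaussian with
#' \eqn{\Sigma(h) = \sum_c e^{h_c} G_c + e^{h_0} I}, and maximises the
#' free energy over the log hyperparameters `h` by Fisher scoring with
#' step halving, under independent Gaussian hyperpriors (default mean
#' -3, variance 16: weakly informative, positivity enforced by the log
#' parameterisation).  Non-convergence within `maxIter` is flagged on
#' the result, not raised.
#'
#' @param U conditions x voxels matrix, or a [SecondMoment-class].
#' @param components a [ComponentSet-class].
#' @param center passed to [secondMoment()] when `U` is a matrix.
#' @param priorMean,priorVar Gaussian hyperprior on the log
#'   hyperparameters; scalars recycle over components + noise.
#' @param tol convergence tolerance on the free-energy improvement.
#' @param maxIter maximum Fisher-scoring iterations.
#' @return A [ComponentFit-class].
#' @export
#' @examples
#' ps <- generatePatterns(generativeSpec(nVoxels = 500, nSubjects = 1, nRuns = 1))
#' fit <- fitComponents(subjectPatterns(ps, "s01"))
#' hyperparameters(fit)
fitComponents <- function(U, components = componentModels(), center = TRUE,
                          priorMean = -3, priorVar = 16, tol = 1e-4,
                          maxIter = 128L) {
  sm <- if (is(U, "SecondMoment")) U else secondMoment(U, center = center)
  nm <- c(componentNames(components), "noise")
  m <- length(nm)
  pm <- .expand_prior(priorMean, m)
  pv <- .expand_prior(priorVar, m)
  B <- .contrast_basis(sm@centered)
  S <- crossprod(B, sm@G %*% B)
  fit <- .reml_fit_cpp(S, sm@nVoxels,
                       .project_cube(.g_cube(components), B), pm, pv,
                       tol, as.integer(maxIter))
  new("ComponentFit",
      mean = setNames(as.numeric(fit$mean), nm),
      cov = fit$cov, F = fit$F, logLik = fit$logLik,
      iterations = as.integer(fit$iterations), converged = fit$converged,
      priorMean = pm, priorVar = pv, secondMoment = S, basis = B,
      nVoxels = sm@nVoxels, componentNames = nm)
}

#' Score each component's contribution by log evidence
#'
#' For every component, the change in log evidence `deltaF = F_reduced -
#' F_full` when that component's log hyperparameter is pinned off
#' (reduced prior mean -32, vanishing variance).  More negative values
#' are stronger evidence for the component.  `"bmr"` evaluates the
#' reduced evidence analytically from the full posterior (Gaussian
#' Bayesian model reduction); `"refit"` refits the model under each
#' reduced prior and differences the free energies.  BMR falls back to
#' an explicit refit for any component whose analytic reduction is
#' ill-conditioned.
#'
#' @param fit a converged [ComponentFit-class].
#' @param method `"bmr"` or `"refit"`.
#' @param redMean,redVar the reduced ("off") prior.
#' @return A [ComponentEvidence-class].
#' @export
componentEvidence <- function(fit, method = c("bmr", "refit"),
                              redMean = -32, redVar = 1e-6) {
  method <- match.arg(method)
  stopifnot(is(fit, "ComponentFit"))
  nm <- fit@componentNames
  comp <- nm[nm != "noise"]
  nc <- length(comp)
  Gs <- lapply(comp, function(cn) {
    v <- contrastVector(cn)
    tcrossprod(v) / sum(v^2)
  })
  Gcube <- .project_cube(array(unlist(Gs), dim = c(8, 8, nc)), fit@basis)
  refit_one <- function(k) {
    pm <- fit@priorMean; pm[k] <- redMean
    pv <- fit@priorVar; pv[k] <- redVar
    red <- .reml_fit_cpp(fit@secondMoment, fit@nVoxels, Gcube,
                         pm, pv, 1e-4, 128L)
    red$F - fit@F
  }
  if (method == "bmr") {
    d <- .bmr_cpp(fit@mean, fit@cov, fit@priorMean, fit@priorVar, nc,
                  redMean, redVar)
    if (anyNA(d)) {
      bad <- which(is.na(d))
      message("BMR ill-conditioned for ", length(bad),
              " component(s); refitting explicitly")
      for (k in bad) d[k] <- refit_one(k)
    }
  } else {
    d <- vapply(seq_len(nc), refit_one, numeric(1))
  }
  new("ComponentEvidence", deltaF = setNames(as.numeric(d), comp),
      method = method, nSubjects = 1L)
}

#' Combine per-subject evidence at the group level
#'
#' Fixed-effects combination: log evidences add over independent
#' datasets, so the group `deltaF` is the sum of the per-subject
#' `deltaF` values.
#'
#' @param evidences non-empty list of [ComponentEvidence-class]
#'   objects with matching components.
#' @return A [ComponentEvidence-class].
#' @export
groupEvidence <- function(evidences) {
  stopifnot(is.list(evidences), length(evidences) >= 1L)
  nm <- names(deltaF(evidences[[1]]))
  for (e in evidences)
    if (!identical(names(deltaF(e)), nm))
      stop("evidence objects have mismatched components", call. = FALSE)
  d <- Reduce(`+`, lapply(evidences, deltaF))
  new("ComponentEvidence", deltaF = d,
      method = evidences[[1]]@method,
      nSubjects = sum(vapply(evidences, function(e) e@nSubjects,
                             integer(1))))
}
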