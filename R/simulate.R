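#' Specification of a synthetic pattern dataset
#'
#' Defines the generative model for synthetic condition-by-voxel
#' patterns: each voxel's 8-vector is an independent draw from a
#' zero-mean Gaussian with covariance
#' \eqn{\Sigma = \sum_c w_c G_c + \sigma^2 I_8}, where the `G_c` are the
#' trace-one component model matrices.  Defaults mirror the study scale:
#' 27 subjects, 6 runs.
#'
#' @param weights named non-negative component variances `w_c`
#'   (names from [componentModels()]); unnamed components are 0.
#' @param noiseVar isotropic noise variance `sigma^2`.
#' @param nVoxels,nSubjects,nRuns dataset dimensions.
#' @param seed integer RNG seed.
#' @param subjectSd standard deviation of lognormal multipliers
#'   jittering the weights between subjects (0 = identical subjects).
#' @return A list of class `GenerativeSpec`.
#' @export
#' @examples
#' generativeSpec(weights = c(ET_dist = 2), nVoxels = 500)
generativeSpec <- function(weights = c(ET_dist = 2, T_dir = 1),
                           noiseVar = 1, nVoxels = 2000, nSubjects = 27,
                           nRuns = 6, seed = 1, subjectSd = 0) {
  w <- setNames(numeric(length(.component_names)), .component_names)
  if (length(weights)) {
    if (is.null(names(weights)) ||
        !all(names(weights) %in% .component_names))
      stop("weights must be named by component", call. = FALSE)
    w[names(weights)] <- weights
  }
  if (any(w < 0) || noiseVar < 0)
    stop("weights and noiseVar must be non-negative", call. = FALSE)
  if (all(w == 0) && noiseVar == 0)
    stop("at least one of weights/noiseVar must be positive", call. = FALSE)
  if (nVoxels < 1 || nSubjects < 1 || nRuns < 1)
    stop("counts must be >= 1", call. = FALSE)
  structure(list(weights = w, noiseVar = noiseVar,
                 nVoxels = as.integer(nVoxels),
                 nSubjects = as.integer(nSubjects),
                 nRuns = as.integer(nRuns), seed = as.integer(seed),
                 subjectSd = subjectSd),
            class = "GenerativeSpec")
}

.sigma_from_weights <- function(weights, noiseVar,
                                components = componentModels()) {
  Gs <- modelMatrices(components)
  S <- diag(noiseVar, 8)
  for (nm in names(weights)) S <- S + weights[[nm]] * Gs[[nm]]
  dimnames(S) <- list(conditionLabels(), conditionLabels())
  S
}

#' Generate synthetic condition-by-voxel patterns
#'
#' Draws one pattern matrix per subject and run under the spec's
#' covariance; draws are independent across voxels, runs and subjects
#' and reproducible under the spec's seed.  The per-subject true
#' second-moment matrix (after any between-subject weight jitter) is
#' stored in `metadata(x)$trueG`.
#'
#' @param spec a [generativeSpec()].
#' @param components the [ComponentSet-class] defining the `G_c`.
#' @return A [PatternSet-class].
#' @export
#' @examples
#' ps <- generatePatterns(generativeSpec(nVoxels = 100, nSubjects = 2, nRuns = 2))
#' ps
generatePatterns <- function(spec, components = componentModels()) {
  stopifnot(inherits(spec, "GenerativeSpec"))
  set.seed(spec$seed)
  lab <- conditionLabels()
  assays <- list()
  trueG <- list()
  for (s in seq_len(spec$nSubjects)) {
    w <- spec$weights
    if (spec$subjectSd > 0)
      w <- w * rlnorm(length(w), meanlog = -spec$subjectSd^2 / 2,
                      sdlog = spec$subjectSd)
    Sigma <- .sigma_from_weights(w, spec$noiseVar, components)
    e <- eigen(Sigma, symmetric = TRUE)
    A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 8)
    trueG[[s]] <- Sigma
    for (r in seq_len(spec$nRuns)) {
      U <- A %*% matrix(rnorm(8 * spec$nVoxels), 8, spec$nVoxels)
      rownames(U) <- lab
      assays[[sprintf("s%02d_r%d", s, r)]] <- U
    }
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(trialTypes(), row.names = lab))
  metadata(se)$spec <- unclass(spec)
  metadata(se)$trueG <- trueG
  new("PatternSet", se)
}

#' @describeIn generatePatterns Subject identifiers present in a
#'   PatternSet.
#' @param x a [PatternSet-class].
#' @export
subjectIds <- function(x) {
  unique(sub("_r[0-9]+$", "", assayNames(x)))
}

#' Extract one subject's pattern matrix, pooled across runs
#'
#' @param x a [PatternSet-class].
#' @param subject subject id (e.g. `"s01"`).
#' @param pooling `"average"` (mean beta pattern across runs) or
#'   `"concatenate"` (runs side by side as extra voxels).
#' @return 8 x voxels matrix with canonical row labels.
#' @export
subjectPatterns <- function(x, subject,
                            pooling = c("average", "concatenate")) {
  pooling <- match.arg(pooling)
  nm <- grep(paste0("^", subject, "_r[0-9]+$"), assayNames(x), value = TRUE)
  if (!length(nm)) stop("unknown subject: ", subject, call. = FALSE)
  assembleU(lapply(nm, function(a) assay(x, a)), pooling = pooling)
}

#' Generate BOLD time series from a run design
#'
#' `y = X beta + noise`, where `X` stacks the condition regressors of
#' both plan epochs (as generative truth) plus the go-planning and
#' movement nuisance regressors, and the noise is white Gaussian.
#'
#' @param run a [RunDesign-class].
#' @param amplitudes named list with 8 x voxels amplitude matrices for
#'   `early` and/or `late` condition regressors (missing epochs are
#'   silent).
#' @param noiseSd standard deviation of the white noise.
#' @param seed optional integer seed.
#' @param goAmplitude,moveAmplitude scalar amplitudes of the go-planning
#'   and movement nuisance events (applied to every voxel).
#' @return scans x voxels matrix of simulated BOLD.
#' @export
#' @examples
#' run <- sampleRun(seed = 1)
#' amp <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(conditionLabels(), NULL))
#' y <- generateBold(run, list(early = amp), noiseSd = 0.5, seed = 2)
generateBold <- function(run, amplitudes, noiseSd = 1, seed = NULL,
                         goAmplitude = 0, moveAmplitude = 0) {
  stopifnot(is(run, "RunDesign"), is.list(amplitudes))
  bad <- setdiff(names(amplitudes), c("early", "late"))
  if (length(bad)) stop("unknown epoch(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  nv <- unique(vapply(amplitudes, ncol, integer(1)))
  if (length(nv) != 1L)
    stop("amplitude matrices must share the voxel count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- matrix(0, run@nScans, nv)
  for (ep in names(amplitudes)) {
    amp <- amplitudes[[ep]]
    if (nrow(amp) != 8L) stop("amplitudes must have 8 condition rows",
                              call. = FALSE)
    X <- buildDesignMatrix(run, ep)@matrix
    y <- y + X[, conditionLabels(), drop = FALSE] %*% amp +
      outer(X[, "go_plan"], rep(goAmplitude, nv)) +
      outer(X[, "movement"], rep(moveAmplitude, nv))
  }
  if (noiseSd > 0) y <- y + matrix(rnorm(length(y), sd = noiseSd), nrow(y))
  y
}

#' Ready-made synthetic fixtures
#'
#' `"tiny"` is a seconds-scale fixture (4 subjects x 2 runs x 200
#' voxels) used throughout the test suite; `"paper_scale"` matches the
#' study dimensions (27 subjects x 6 runs x 2000 voxels).  Both plant
#' gaze-centric distance (`ET_dist`) and target-direction (`T_dir`)
#' structure on unit isotropic noise by default.
#'
#' @param profile `"tiny"` or `"paper_scale"`.
#' @param dir if non-`NULL`, also serialise the dataset there via
#'   [writePatternSet()].
#' @param seed RNG seed.
#' @param weights,noiseVar passed to [generativeSpec()].
#' @return A [PatternSet-class] (invisibly carrying `dir` in
#'   `metadata()$path` when written).
#' @export
makeFixture <- function(profile = c("tiny", "paper_scale"), dir = NULL,
                        seed = 1, weights = c(ET_dist = 2, T_dir = 1),
                        noiseVar = 1) {
  profile <- match.arg(profile)
  dims <- switch(profile,
                 tiny = c(subjects = 4L, runs = 2L, voxels = 200L),
                 paper_scale = c(subjects = 27L, runs = 6L, voxels = 2000L))
  spec <- generativeSpec(weights = weights, noiseVar = noiseVar,
                         nVoxels = dims[["voxels"]],
                         nSubjects = dims[["subjects"]],
                         nRuns = dims[["runs"]], seed = seed)
  ps <- generatePatterns(spec)
  if (!is.null(dir)) {
    writePatternSet(ps, dir)
    metadata(ps)$path <- dir
  }
  ps
}
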