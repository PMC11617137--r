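#' Canonical condition labels
#'
#' The eight trial types of the 2x2x2 hand/target/gaze factorial in the
#' package's canonical order: lexicographic over (hand, target, gaze) with
#' left before right.  Labels follow the `H-T-E` convention, e.g. `"L-R-L"`
#' means hand left, target right, gaze left.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' conditionLabels()
conditionLabels <- function() {
  g <- expand.grid(gaze = c("L", "R"), target = c("L", "R"),
                   hand = c("L", "R"), stringsAsFactors = FALSE)
  paste(g$hand, g$target, g$gaze, sep = "-")
}

## ---------------------------------------------------------------------------
## Run designs and design matrices
## ---------------------------------------------------------------------------

#' @title RunDesign: an ordered, timed sequence of 40 trials
#'
#' @description One functional run of the delayed reach-to-target task:
#' 40 trials (five per trial type), 24 go / 16 no-go, with delay and plan
#' durations allocated by largest-remainder rounding of the study
#' proportions.  Onsets accumulate trial durations plus the feedback
#' window and inter-trial gap.  Times are seconds from run start; all
#' intervals are half-open `[on, off)`.
#'
#' @slot trials data.frame with one row per trial: `label`, `hand`,
#'   `target`, `gaze` (+/-1 side codes), `go`, `delay`, `plan`, `onset`,
#'   `target_onset`, `cue`, `end`.
#' @slot tr repetition time in seconds.
#' @slot nScans number of volumes covering the run (plus an HRF tail).
#' @exportClass RunDesign
setClass("RunDesign",
         slots = c(trials = "data.frame", tr = "numeric", nScans = "integer"))

setValidity("RunDesign", function(object) {
  tr <- object@trials
  need <- c("label", "hand", "target", "gaze", "go", "delay", "plan",
            "onset", "target_onset", "cue", "end")
  if (!all(need %in% names(tr)))
    return(paste("trials must contain columns:", paste(need, collapse = ", ")))
  if (nrow(tr) != 40L) return("a run has exactly 40 trials")
  cnt <- table(factor(tr$label, levels = conditionLabels()))
  if (!all(cnt == 5L)) return("each of the 8 trial types occurs exactly 5 times")
  if (sum(tr$go) != 24L) return("exactly 24 go trials (60%)")
  if (any(abs(tr$cue - (tr$target_onset + tr$plan)) > 1e-9))
    return("cue time must equal target onset + plan duration")
  if (is.unsorted(tr$onset, strictly = TRUE)) return("onsets must be increasing")
  if (object@tr <= 0) return("tr must be positive")
  TRUE
})

#' @title DesignMatrix: HRF-convolved regressors for one plan epoch
#'
#' @description Predicted BOLD regressors sampled at the repetition time.
#' Condition columns model the 2 s planning epoch of no-go trials (one
#' column per trial type); go-trial planning and movement enter nuisance
#' columns; an intercept column is appended.
#'
#' @slot matrix numeric matrix, scans x regressors, named columns.
#' @slot epoch `"early"` or `"late"`.
#' @slot tr repetition time in seconds.
#' @slot role character vector parallel to the columns:
#'   `"condition"`, `"nuisance"` or `"intercept"`.
#' @slot windows data.frame of the unconvolved event windows
#'   (`column`, `on`, `off` in seconds) used to build the matrix.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
         slots = c(matrix = "matrix", epoch = "character", tr = "numeric",
                   role = "character", windows = "data.frame"))

setValidity("DesignMatrix", function(object) {
  if (!object@epoch %in% c("early", "late")) return("epoch must be 'early' or 'late'")
  if (length(object@role) != ncol(object@matrix))
    return("role must have one entry per column")
  if (anyDuplicated(colnames(object@matrix))) return("column names must be unique")
  cond <- object@matrix[, object@role == "condition", drop = FALSE]
  if (ncol(cond) && any(colSums(abs(cond)) == 0))
    return("a condition column is all zero")
  TRUE
})

## ---------------------------------------------------------------------------
## Component models
## ---------------------------------------------------------------------------

#' @title ComponentSet: hypothesis contrasts and their model matrices
#'
#' @description Each component is a +/-1 contrast over the eight
#' conditions; its model second-moment matrix is the trace-normalised
#' rank-one outer product of the contrast.  Direction components (`T_dir`,
#' `H_dir`, `E_dir`) carry the side code of one element (left = -1,
#' right = +1); distance components (`HT_dist`, `ET_dist`, `HE_dist`)
#' carry the product of two side codes (+1 = near, -1 = far).
#'
#' @slot contrasts 8 x m matrix of +/-1 contrasts, one column per
#'   component, rows in canonical condition order.
#' @slot conditionLabels length-8 character vector.
#' @exportClass ComponentSet
setClass("ComponentSet",
         slots = c(contrasts = "matrix", conditionLabels = "character"))

setValidity("ComponentSet", function(object) {
  if (nrow(object@contrasts) != length(object@conditionLabels))
    return("contrast rows must match condition labels")
  if (!all(object@contrasts %in% c(-1, 1)))
    return("contrasts must be +/-1")
  if (is.null(colnames(object@contrasts)) || anyDuplicated(colnames(object@contrasts)))
    return("components must have unique names")
  TRUE
})

## ---------------------------------------------------------------------------
## Patterns and second moments
## ---------------------------------------------------------------------------

#' @title PatternSet: condition-by-voxel patterns per subject and run
#'
#' @description A [SummarizedExperiment::SummarizedExperiment] with eight
#' rows (conditions in canonical order) and one column per voxel; each
#' assay holds one subject/run pattern matrix, named `s<subject>_r<run>`.
#' `metadata()` carries the generative specification (for synthetic data)
#' and, when known, the per-subject true second-moment matrices.
#'
#' @exportClass PatternSet
setClass("PatternSet", contains = "SummarizedExperiment")

setValidity("PatternSet", function(object) {
  if (nrow(object) != 8L) return("a PatternSet has 8 condition rows")
  if (!identical(rownames(object), conditionLabels()))
    return("rownames must be the canonical condition labels")
  if (length(assays(object)) < 1L) return("at least one subject/run assay")
  nm <- assayNames(object)
  if (is.null(nm) || !all(grepl("^s[0-9]+_r[0-9]+$", nm)))
    return("assay names must follow s<subject>_r<run>")
  TRUE
})

#' @title SecondMoment: condition-by-condition second-moment matrix
#'
#' @description `G = UU^T / n_voxels` (optionally after removing each
#' voxel's mean across conditions).  Off-diagonal magnitude reflects
#' pattern similarity between conditions.
#'
#' @slot G symmetric 8 x 8 (or k x k) matrix.
#' @slot nVoxels number of voxels entering the average.
#' @slot centered whether voxel means were removed.
#' @exportClass SecondMoment
setClass("SecondMoment",
         slots = c(G = "matrix", nVoxels = "integer", centered = "logical"))

setValidity("SecondMoment", function(object) {
  G <- object@G
  if (nrow(G) != ncol(G)) return("G must be square")
  if (max(abs(G - t(G))) > 1e-8 * (1 + max(abs(G)))) return("G must be symmetric")
  TRUE
})

## ---------------------------------------------------------------------------
## Fits and evidence
## ---------------------------------------------------------------------------

#' @title ComponentFit: variational ReML fit of covariance components
#'
#' @description Posterior over log-scale hyperparameters `h` of the model
#' \eqn{\Sigma(h) = \sum_c e^{h_c} G_c + e^{h_0} I}, fitted by Fisher
#' scoring with step halving on the free-energy objective.  The noise
#' hyperparameter is the last element, named `"noise"`.
#'
#' @slot mean posterior mean of the log hyperparameters (named).
#' @slot cov posterior covariance (Laplace) of the log hyperparameters.
#' @slot F variational free energy at the mode (natural log units).
#' @slot logLik Gaussian log-likelihood at the posterior mode.
#' @slot iterations,converged Fisher-scoring bookkeeping.
#' @slot priorMean,priorVar Gaussian hyperprior (per hyperparameter).
#' @slot secondMoment the second-moment matrix actually fitted (in the
#'   contrast subspace when the patterns were centered).
#' @slot basis the orthonormal basis mapping condition space to the
#'   fitted space: an 8 x 7 basis of the complement of the ones vector
#'   for centered fits (centered patterns carry no information along
#'   the shared mean, so the model lives in the 7-dimensional contrast
#'   subspace where the noise stays isotropic), or the 8 x 8 identity.
#' @slot nVoxels number of voxels behind `secondMoment`.
#' @slot componentNames component names, noise last.
#' @exportClass ComponentFit
setClass("ComponentFit",
         slots = c(mean = "numeric", cov = "matrix", F = "numeric",
                   logLik = "numeric", iterations = "integer",
                   converged = "logical", priorMean = "numeric",
                   priorVar = "numeric", secondMoment = "matrix",
                   basis = "matrix", nVoxels = "integer",
                   componentNames = "character"))

#' @title ComponentEvidence: per-component log evidence changes
#'
#' @description For each component, `deltaF = F_reduced - F_full`: the
#' change in log evidence when the component's log hyperparameter is
#' pinned "off" (prior mean -32, vanishing variance).  More negative
#' values are stronger evidence that the component contributes.
#'
#' @slot deltaF named numeric vector (one entry per component).
#' @slot method `"bmr"` (analytic Bayesian model reduction) or `"refit"`.
#' @slot nSubjects number of subjects combined (1 for a single fit;
#'   fixed-effects summation otherwise).
#' @exportClass ComponentEvidence
setClass("ComponentEvidence",
         slots = c(deltaF = "numeric", method = "character",
                   nSubjects = "integer"))

#' @title NullEvidence: shuffle-label null distribution of log evidences
#'
#' @description Group-level `deltaF` values recomputed under random
#' permutations of the eight condition labels (shared across subjects),
#' alongside the real (identity-permutation) values.
#'
#' @slot real named numeric vector of real group `deltaF` per component.
#' @slot null K x m matrix of shuffled group `deltaF` values.
#' @slot perms K x 8 matrix of the permutations used (1-based).
#' @slot seed RNG seed that produced the permutations.
#' @slot nSubjects number of subjects combined.
#' @exportClass NullEvidence
setClass("NullEvidence",
         slots = c(real = "numeric", null = "matrix", perms = "matrix",
                   seed = "integer", nSubjects = "integer"))

setValidity("NullEvidence", function(object) {
  if (ncol(object@null) != length(object@real))
    return("null columns must match the real evidence vector")
  if (nrow(object@null) < 1L) return("at least one permutation required")
  TRUE
})
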