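#' @name vrsa-accessors
#' @title Accessors for vrsa classes
#'
#' @description Slot accessors: `hyperparameters()` returns the fitted
#' component weights on the natural (exp) scale, `freeEnergy()` the
#' variational free energy, `deltaF()` per-component log-evidence
#' changes, `contrastMatrix()` and `modelMatrices()` the component
#' contrasts and their rank-one model matrices, `designMatrix()` the
#' numeric regressor matrix, and `realEvidence()` / `nullEvidence()` the
#' observed and shuffled group log evidences.
#'
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @return See each method's description.
NULL

#' @rdname vrsa-accessors
#' @export
setGeneric("hyperparameters", function(x) standardGeneric("hyperparameters"))

#' @rdname vrsa-accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname vrsa-accessors
#' @export
setGeneric("deltaF", function(x) standardGeneric("deltaF"))

#' @rdname vrsa-accessors
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname vrsa-accessors
#' @export
setGeneric("contrastMatrix", function(x) standardGeneric("contrastMatrix"))

#' @rdname vrsa-accessors
#' @export
setGeneric("modelMatrices", function(x) standardGeneric("modelMatrices"))

#' @rdname vrsa-accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname vrsa-accessors
#' @export
setGeneric("secondMomentMatrix", function(x) standardGeneric("secondMomentMatrix"))

#' @rdname vrsa-accessors
#' @export
setGeneric("realEvidence", function(x) standardGeneric("realEvidence"))

#' @rdname vrsa-accessors
#' @export
setGeneric("nullEvidence", function(x) standardGeneric("nullEvidence"))

## ------------------------------------------------------------------------

#' @rdname vrsa-accessors
#' @export
setMethod("hyperparameters", "ComponentFit", function(x)
  setNames(exp(x@mean), x@componentNames))

#' @rdname vrsa-accessors
#' @export
setMethod("freeEnergy", "ComponentFit", function(x) x@F)

#' @rdname vrsa-accessors
#' @export
setMethod("deltaF", "ComponentEvidence", function(x) x@deltaF)

#' @rdname vrsa-accessors
#' @export
setMethod("componentNames", "ComponentSet", function(x) colnames(x@contrasts))

#' @rdname vrsa-accessors
#' @export
setMethod("componentNames", "ComponentFit", function(x) x@componentNames)

#' @rdname vrsa-accessors
#' @export
setMethod("contrastMatrix", "ComponentSet", function(x) x@contrasts)

#' @rdname vrsa-accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) x@matrix)

#' @rdname vrsa-accessors
#' @export
setMethod("secondMomentMatrix", "SecondMoment", function(x) x@G)

#' @rdname vrsa-accessors
#' @export
setMethod("realEvidence", "NullEvidence", function(x) x@real)

#' @rdname vrsa-accessors
#' @export
setMethod("nullEvidence", "NullEvidence", function(x) x@null)

## ------------------------------------------------------------------------
## show methods

setMethod("show", "RunDesign", function(object) {
  tr <- object@trials
  cat(sprintf("RunDesign: %d trials (%d go / %d no-go), %.1f s, %d scans @ TR %.2f s\n",
              nrow(tr), sum(tr$go), sum(!tr$go), max(tr$end), object@nScans,
              object@tr))
  cat("  delays:", paste(names(table(tr$delay)), "s x",
                         as.vector(table(tr$delay)), collapse = ", "), "\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix (%s epoch): %d scans x %d regressors (%d condition, %d nuisance)\n",
              object@epoch, nrow(object@matrix), ncol(object@matrix),
              sum(object@role == "condition"), sum(object@role == "nuisance")))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components over %d conditions\n",
              ncol(object@contrasts), nrow(object@contrasts)))
  cat("  ", paste(colnames(object@contrasts), collapse = ", "), "\n")
})

setMethod("show", "SecondMoment", function(object) {
  cat(sprintf("SecondMoment: %dx%d G from %d voxels (%scentered)\n",
              nrow(object@G), ncol(object@G), object@nVoxels,
              if (object@centered) "" else "not "))
})

setMethod("show", "ComponentFit", function(object) {
  cat(sprintf("ComponentFit: %d components + noise, %d voxels\n",
              length(object@mean) - 1L, object@nVoxels))
  cat(sprintf("  F = %.2f, logLik = %.2f, %d iterations, %s\n",
              object@F, object@logLik, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  w <- hyperparameters(object)
  cat("  exp(h):", paste(sprintf("%s=%.3g", names(w), w), collapse = ", "), "\n")
})

setMethod("show", "ComponentEvidence", function(object) {
  cat(sprintf("ComponentEvidence (%s, %d subject%s): deltaF = F_reduced - F_full\n",
              object@method, object@nSubjects,
              if (object@nSubjects == 1L) "" else "s"))
  print(round(object@deltaF, 3))
})

setMethod("show", "NullEvidence", function(object) {
  cat(sprintf("NullEvidence: %d shuffles x %d components, %d subjects, seed %d\n",
              nrow(object@null), ncol(object@null), object@nSubjects,
              object@seed))
})
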