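#' Ordinary least squares beta estimation
#'
#' Fits `y = X beta + e` voxelwise by OLS.  Rank-deficient designs are
#' an error (no silent pseudo-inverse).  By default the eight no-go
#' condition betas are returned in canonical order; `conditionsOnly =
#' FALSE` returns all regressor rows.
#'
#' @param y scans x voxels matrix of time series.
#' @param X a [DesignMatrix-class] (or plain matrix with named
#'   columns).
#' @param conditionsOnly return only the condition rows?
#' @return betas: conditions (or regressors) x voxels matrix.
#' @export
#' @examples
#' run <- sampleRun(seed = 1)
#' X <- buildDesignMatrix(run, "early")
#' amp <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(conditionLabels(), NULL))
#' y <- generateBold(run, list(early = amp), noiseSd = 0)
#' max(abs(estimateBetas(y, X) - amp))   # ~ 0
estimateBetas <- function(y, X, conditionsOnly = TRUE) {
  Xm <- if (is(X, "DesignMatrix")) X@matrix else X
  stopifnot(is.matrix(y), nrow(y) == nrow(Xm))
  qx <- qr(Xm)
  if (qx$rank < ncol(Xm)) {
    dep <- colnames(Xm)[qx$pivot[(qx$rank + 1L):ncol(Xm)]]
    stop("rank-deficient design matrix; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qx, y)
  rownames(B) <- colnames(Xm)
  if (conditionsOnly) B <- B[conditionLabels(), , drop = FALSE]
  B
}

#' Assemble the condition-by-voxel pattern matrix U
#'
#' Pools per-run condition beta patterns into a single U for one
#' subject/ROI.  `"average"` takes the mean pattern per condition
#' across runs (the default); `"concatenate"` stacks runs side by side
#' as additional voxels.  Voxel columns containing any non-finite value
#' are dropped with a message.
#'
#' @param betas list of 8 x voxels matrices, one per run, with matching
#'   dimensions and canonical row labels.
#' @param pooling `"average"` or `"concatenate"`.
#' @return 8 x voxels matrix.
#' @export
assembleU <- function(betas, pooling = c("average", "concatenate")) {
  pooling <- match.arg(pooling)
  stopifnot(is.list(betas), length(betas) >= 1L)
  d <- vapply(betas, dim, integer(2))
  if (any(d[1, ] != 8L)) stop("each run must have 8 condition rows",
                              call. = FALSE)
  if (length(unique(d[2, ])) != 1L)
    stop("runs have mismatched voxel counts", call. = FALSE)
  U <- switch(pooling,
              average = Reduce(`+`, betas) / length(betas),
              concatenate = do.call(cbind, betas))
  rownames(U) <- conditionLabels()
  bad <- !apply(is.finite(U), 2, all)
  if (any(bad)) {
    message("dropping ", sum(bad), " voxel(s) with non-finite betas")
    U <- U[, !bad, drop = FALSE]
  }
  U
}
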