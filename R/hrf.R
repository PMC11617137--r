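#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used for convolution: a gamma density peaking about
#' 5 s post-onset minus a 16 s undershoot gamma scaled by 1/6.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,under_shape gamma shape parameters of the response
#'   and undershoot (rate 1).
#' @param ratio response:undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
#' @examples
#' t <- seq(0, 32, 0.1)
#' plot(t, canonicalHrf(t), type = "l")
canonicalHrf <- function(t, peak_shape = 6, under_shape = 16, ratio = 6) {
  h <- dgamma(t, shape = peak_shape, rate = 1) -
    dgamma(t, shape = under_shape, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Event windows modelled by a design matrix
#'
#' The unconvolved half-open `[on, off)` windows assigned to each
#' regressor for the given epoch: 2 s condition boxcars on no-go trials
#' (at target onset for `"early"`, ending at the cue for `"late"`),
#' plus the matching go-trial planning boxcars and the 1 s movement
#' window after the cue on go trials.
#'
#' @param run a [RunDesign-class].
#' @param epoch `"early"` or `"late"`.
#' @return data.frame with columns `column`, `on`, `off` (seconds).
#' @export
epochWindows <- function(run, epoch = c("early", "late")) {
  epoch <- match.arg(epoch)
  tr <- run@trials
  if (epoch == "early") {
    on <- tr$target_onset; off <- tr$target_onset + 2
  } else {
    on <- tr$cue - 2; off <- tr$cue
  }
  rbind(
    data.frame(column = tr$label[!tr$go], on = on[!tr$go], off = off[!tr$go]),
    data.frame(column = "go_plan", on = on[tr$go], off = off[tr$go]),
    data.frame(column = "movement", on = tr$cue[tr$go],
               off = tr$cue[tr$go] + .move_s))
}

#' Build the HRF-convolved design matrix for one plan epoch
#'
#' For every no-go trial a 2 s boxcar (`[target_onset, target_onset+2)`
#' for the early epoch, `[cue-2, cue)` for the late epoch) is assigned
#' to its condition column; go-trial planning epochs pool into one
#' nuisance column and go-trial movement (1 s after the cue) into
#' another; an intercept column is appended.  Boxcars are convolved with
#' the canonical HRF on an oversampled grid and sampled at the scan
#' times `0, tr, 2*tr, ...` (0-based volume indexing).
#'
#' @param run a [RunDesign-class].
#' @param epoch `"early"` or `"late"`.
#' @param oversample temporal oversampling factor relative to the TR.
#' @return A [DesignMatrix-class].
#' @export
#' @examples
#' X <- buildDesignMatrix(sampleRun(seed = 1), "early")
#' X
buildDesignMatrix <- function(run, epoch = c("early", "late"),
                              oversample = 16L) {
  epoch <- match.arg(epoch)
  win <- epochWindows(run, epoch)
  tr <- run@tr
  dt <- tr / oversample
  scan_t <- (seq_len(run@nScans) - 1L) * tr
  n_hi <- ceiling((max(scan_t) + tr) / dt) + 1L
  kern <- canonicalHrf(seq(0, 32, by = dt))

  cols <- c(conditionLabels(), "go_plan", "movement")
  X <- matrix(0, run@nScans, length(cols) + 1L,
              dimnames = list(NULL, c(cols, "intercept")))
  scan_idx <- round(scan_t / dt) + 1L
  ## FFT convolution on a padded power-of-two grid
  L <- stats::nextn(n_hi + length(kern))
  fk <- stats::fft(c(kern, numeric(L - length(kern))))
  for (cl in cols) {
    x <- numeric(L)
    w <- win[win$column == cl, , drop = FALSE]
    for (j in seq_len(nrow(w))) {
      i0 <- floor(w$on[j] / dt) + 1L
      i1 <- ceiling(w$off[j] / dt)
      x[i0:min(i1, n_hi)] <- 1
    }
    conv <- Re(stats::fft(stats::fft(x) * fk, inverse = TRUE)) / L * dt
    X[, cl] <- conv[scan_idx]
  }
  X[, "intercept"] <- 1
  role <- c(rep("condition", 8L), "nuisance", "nuisance", "intercept")
  new("DesignMatrix", matrix = X, epoch = epoch, tr = tr, role = role,
      windows = win)
}

#' Variance inflation factor of a design
#'
#' `VIF = var(E)/var(X)`: the mean, over the selected regressors, of the
#' estimation variance of each regression weight in the joint model
#' relative to its variance had the regressor been estimated in
#' isolation, i.e. `mean_i [(X'X)^{-1}]_ii * (X'X)_ii`.  Equals 1 iff
#' the selected columns are mutually orthogonal (given the other
#' columns); larger values flag multicollinearity.
#'
#' @param X a [DesignMatrix-class] or a plain numeric matrix.
#' @param columns which columns enter the mean.  For a `DesignMatrix`
#'   the default is the eight no-go condition regressors -- the
#'   estimated weights the analysis consumes.  Nuisance regressors stay
#'   in the joint model (so their collinearity still inflates the
#'   condition weights) but are excluded from the mean: the late plan
#'   epoch of a go trial always abuts the movement window, so a
#'   nuisance-including mean has an irreducible floor no ordering can
#'   optimise away.  For a matrix, all columns.
#' @return The mean VIF (scalar, >= 1 for full-rank designs), with the
#'   per-regressor values in attribute `"per_regressor"`.
#' @export
#' @examples
#' vif(cbind(a = c(1, 0, 0), b = c(0, 1, 0)))           # orthogonal: 1
#' r <- 0.5
#' vif(cbind(c(1, 0), c(r, sqrt(1 - r^2))))             # 1/(1-r^2)
vif <- function(X, columns = NULL) {
  if (is(X, "DesignMatrix")) {
    if (is.null(columns))
      columns <- colnames(X@matrix)[X@role == "condition"]
    X <- X@matrix
  }
  if (is.null(columns)) columns <- colnames(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(columns)) columns <- colnames(X)
  XtX <- crossprod(X)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear design: dependent column(s) ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  iv <- diag(chol2inv(chol(XtX))) * diag(XtX)
  names(iv) <- colnames(X)
  per <- iv[columns]
  structure(mean(per), per_regressor = per)
}
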