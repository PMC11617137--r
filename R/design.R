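## Study timing constants: delay and plan duration menus with their
## proportions of trials, post-cue feedback window and inter-trial gap.
.delay_levels <- c(1, 2, 4, 8, 16)
.delay_props  <- c(0.52, 0.26, 0.13, 0.06, 0.03)
.plan_levels  <- c(4, 6, 8)
.plan_props   <- c(0.56, 0.30, 0.14)
.feedback_s   <- 2.5   # cap on the no-movement feedback window after the cue
.gap_s        <- 1.0   # silence between feedback and the next trial
.move_s       <- 1.0   # nominal movement duration on go trials

#' Largest-remainder allocation of proportions to integer counts
#'
#' Allocates `n` slots to levels proportionally: floors first, then the
#' leftover slots go to the largest fractional remainders.  Remainder
#' ties are resolved toward the earlier (shorter-duration) level.
#'
#' @param props numeric proportions (need not sum exactly to 1).
#' @param n total count to allocate.
#' @return integer vector of counts summing to `n`.
#' @export
#' @examples
#' largestRemainder(c(0.52, 0.26, 0.13, 0.06, 0.03), 40)
largestRemainder <- function(props, n) {
  x <- props * n
  cnt <- floor(x)
  rem <- x - cnt
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

#' Sample one timed run of 40 trials
#'
#' Draws a random run respecting the study composition exactly: five
#' trials of each of the eight types; three go and two no-go trials per
#' type (24 go / 16 no-go overall, i.e. 60% go); delay durations
#' \{1,2,4,8,16\} s and plan durations \{4,6,8\} s with counts from
#' largest-remainder rounding of the stated proportions.  Trial order
#' and the assignment of durations and go labels to slots are
#' randomised.  Each trial runs delay, then target illumination for the
#' plan duration, then the go/no-go cue; no-go trials close with the
#' 2.5 s feedback window, go trials with a nominal 1 s movement, both
#' followed by a 1 s gap.
#'
#' @param seed optional integer seed (uses the current RNG stream when
#'   `NULL`, so successive calls draw successive candidates).
#' @param tr repetition time in seconds.
#' @param tail_s rest appended after the last trial so the HRF tail is
#'   sampled.
#' @return A [RunDesign-class] object.
#' @export
#' @examples
#' run <- sampleRun(seed = 1)
#' run
sampleRun <- function(seed = NULL, tr = 0.45, tail_s = 16) {
  if (!is.null(seed)) set.seed(seed)
  tt <- trialTypes()
  idx <- rep(seq_len(8L), each = 5L)
  ## stratified go assignment: 3 go + 2 no-go within each trial type,
  ## so every condition retains no-go events (no all-zero regressor)
  go <- unlist(lapply(seq_len(8L), function(i)
    sample(c(TRUE, TRUE, TRUE, FALSE, FALSE))))
  ord <- sample.int(40L)
  idx <- idx[ord]; go <- go[ord]
  delay <- sample(rep(.delay_levels, largestRemainder(.delay_props, 40L)))
  plan  <- sample(rep(.plan_levels,  largestRemainder(.plan_props, 40L)))

  post <- ifelse(go, .move_s + .gap_s, .feedback_s + .gap_s)
  dur <- delay + plan + post
  onset <- cumsum(c(0, dur[-40L]))
  target_onset <- onset + delay
  cue <- target_onset + plan
  end <- onset + dur

  trials <- data.frame(
    label = tt$label[idx], hand = tt$hand[idx], target = tt$target[idx],
    gaze = tt$gaze[idx], go = go, delay = delay, plan = plan,
    onset = onset, target_onset = target_onset, cue = cue, end = end,
    stringsAsFactors = FALSE)
  new("RunDesign", trials = trials, tr = tr,
      nScans = as.integer(ceiling((end[40L] + tail_s) / tr)))
}

#' Optimise a run design by minimising the VIF
#'
#' Samples candidate runs from the study composition and scores each by
#' the worse (maximum) of its early- and late-epoch design-matrix VIFs;
#' the best-scoring candidate is returned.  Candidates are drawn
#' sequentially from one RNG stream, so under a fixed seed the first `k`
#' candidates are the same for any `n >= k` and the achieved VIF is
#' non-increasing in `n`.
#'
#' @param nCandidates number of random candidates to score (>= 1).
#' @param seed optional integer seed.
#' @param tr repetition time in seconds.
#' @param epochs epochs entering the score.
#' @param bound the VIF level the study required designs to beat.
#' @return list with `design` (the best [RunDesign-class]),
#'   `achievedVIF` (its worse-epoch VIF), `belowBound`
#'   (`achievedVIF < bound`), and `scores` for all candidates.
#' @export
#' @examples
#' opt <- optimizeDesign(nCandidates = 5, seed = 1)
#' opt$achievedVIF
optimizeDesign <- function(nCandidates = 200, seed = NULL, tr = 0.45,
                           epochs = c("early", "late"), bound = 1.15) {
  stopifnot(nCandidates >= 1)
  if (!is.null(seed)) set.seed(seed)
  scores <- numeric(nCandidates)
  best <- NULL; bestScore <- Inf
  for (i in seq_len(nCandidates)) {
    run <- sampleRun(tr = tr)
    s <- max(vapply(epochs, function(e) vif(buildDesignMatrix(run, e)),
                    numeric(1)))
    scores[i] <- s
    if (s < bestScore) { bestScore <- s; best <- run }
  }
  list(design = best, achievedVIF = bestScore,
       belowBound = bestScore < bound, scores = scores)
}
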