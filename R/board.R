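#' Task-board geometry
#'
#' LED positions on the task board.  The two hand LEDs, two target LEDs
#' and two gaze LEDs are collinear on one horizontal axis, symmetric
#' about the board centre, so each LED sits at +/- separation / 2.
#' Defaults are the study board: hand LEDs 2.3 cm apart, target LEDs
#' 6.9 cm apart, gaze LEDs 32.9 cm apart.
#'
#' @param hand_sep,target_sep,gaze_sep LED separations in cm.
#' @return A list of class `BoardGeometry` with the separations and the
#'   derived signed positions (cm, left negative).
#' @export
#' @examples
#' boardGeometry()
boardGeometry <- function(hand_sep = 2.3, target_sep = 6.9, gaze_sep = 32.9) {
  seps <- c(hand = hand_sep, target = target_sep, gaze = gaze_sep)
  if (any(!is.finite(seps)) || any(seps <= 0))
    stop("invalid geometry: all LED separations must be positive", call. = FALSE)
  if (!(gaze_sep > target_sep && target_sep > hand_sep))
    stop("invalid geometry: need gaze_sep > target_sep > hand_sep", call. = FALSE)
  structure(list(
    hand_sep = hand_sep, target_sep = target_sep, gaze_sep = gaze_sep,
    positions = list(hand = c(L = -hand_sep / 2, R = hand_sep / 2),
                     target = c(L = -target_sep / 2, R = target_sep / 2),
                     gaze = c(L = -gaze_sep / 2, R = gaze_sep / 2))),
    class = "BoardGeometry")
}

#' Enumerate the eight factorial trial types
#'
#' All combinations of hand, target and gaze side (left/right), in
#' canonical lexicographic order over (hand, target, gaze).  Side codes
#' are -1 (left) / +1 (right).  Near/far levels are forced by side
#' equality: a pair is "near" iff its two elements share a side.
#'
#' @return data.frame with columns `label` (H-T-E, e.g. `"L-R-L"`),
#'   `hand`, `target`, `gaze` (+/-1), `ht_level`, `et_level`, `he_level`
#'   (`"near"`/`"far"`).
#' @export
#' @examples
#' trialTypes()
trialTypes <- function() {
  g <- expand.grid(gaze = c(-1, 1), target = c(-1, 1), hand = c(-1, 1))
  lvl <- function(a, b) ifelse(a == b, "near", "far")
  data.frame(
    label = conditionLabels(),
    hand = g$hand, target = g$target, gaze = g$gaze,
    ht_level = lvl(g$hand, g$target),
    et_level = lvl(g$gaze, g$target),
    he_level = lvl(g$hand, g$gaze),
    stringsAsFactors = FALSE)
}

#' Pairwise LED distances on the board
#'
#' Distances between the gaze/target (ET), hand/target (HT) and
#' hand/gaze (HE) LED pairs when the two elements are on the same side
#' ("near") or on opposite sides ("far"), computed as `|pos_a - pos_b|`
#' from the signed LED positions.
#'
#' @param geometry a [boardGeometry()] object.
#' @return data.frame with columns `pair`, `configuration`
#'   (`"same"`/`"opposite"`), `level` (`"near"`/`"far"`) and
#'   `distance_cm`.
#' @export
#' @examples
#' boardDistances()   # ET near 13.0 cm, ET far 19.9 cm, HT far 4.6 cm ...
boardDistances <- function(geometry = boardGeometry()) {
  stopifnot(inherits(geometry, "BoardGeometry"))
  p <- geometry$positions
  pairs <- list(ET = c("gaze", "target"), HT = c("hand", "target"),
                HE = c("hand", "gaze"))
  out <- do.call(rbind, lapply(names(pairs), function(nm) {
    a <- p[[pairs[[nm]][1]]]; b <- p[[pairs[[nm]][2]]]
    data.frame(pair = nm,
               configuration = c("same", "opposite"),
               level = c("near", "far"),
               distance_cm = c(abs(a["R"] - b["R"]), abs(a["R"] - b["L"])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
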