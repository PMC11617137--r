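.component_names <- c("HT_dist", "ET_dist", "HE_dist",
                      "T_dir", "H_dir", "E_dir")

#' Contrast vector for one hypothesis component
#'
#' Direction components carry the side code of the named element
#' (left = -1, right = +1); distance components carry the elementwise
#' product of the two relevant side codes, so +1 marks "near"
#' (same side) and -1 "far" (opposite sides).
#'
#' @param name one of `"HT_dist"`, `"ET_dist"`, `"HE_dist"`, `"T_dir"`,
#'   `"H_dir"`, `"E_dir"` (or `"mean"` for the all-ones vector).
#' @param types the trial-type table fixing the canonical condition
#'   order.
#' @return Length-8 vector of +/-1.
#' @export
#' @examples
#' contrastVector("ET_dist")
contrastVector <- function(name, types = trialTypes()) {
  switch(name,
         T_dir = types$target,
         H_dir = types$hand,
         E_dir = types$gaze,
         HT_dist = types$hand * types$target,
         ET_dist = types$gaze * types$target,
         HE_dist = types$hand * types$gaze,
         mean = rep(1, nrow(types)),
         stop("unknown component: ", name, call. = FALSE))
}

#' The six hypothesis components
#'
#' Builds the standard component set: three relative-distance
#' hypotheses (hand-target HT, gaze-target ET, hand-gaze HE) and three
#' direction hypotheses (target T, hand H, gaze E).  The six contrasts
#' are distinct main effects and two-way interactions of the 2x2x2
#' factorial, hence mutually orthogonal; together with the all-ones
#' vector and the three-way product they form a complete orthogonal
#' (Hadamard) basis of the 8-condition space.
#'
#' @param includeMean also append the all-ones "mean" component
#'   (shared pattern across conditions); off by default because the
#'   second-moment matrix is centered before fitting.
#' @return A [ComponentSet-class].
#' @export
#' @examples
#' cs <- componentModels()
#' contrastMatrix(cs)
componentModels <- function(includeMean = FALSE) {
  types <- trialTypes()
  nm <- .component_names
  if (includeMean) nm <- c(nm, "mean")
  C <- vapply(nm, contrastVector, numeric(8), types = types)
  new("ComponentSet", contrasts = C, conditionLabels = types$label)
}

#' @describeIn componentModels Rank-one model second-moment matrices
#'   `G_c = c c^T / trace(c c^T)` (trace 1) for each component; entry
#'   (i, j) is positive iff conditions i and j share the component's
#'   level.
#' @param x a [ComponentSet-class].
#' @export
setMethod("modelMatrices", "ComponentSet", function(x) {
  lab <- x@conditionLabels
  lapply(setNames(colnames(x@contrasts), colnames(x@contrasts)), function(nm) {
    v <- x@contrasts[, nm]
    G <- tcrossprod(v) / sum(v^2)
    dimnames(G) <- list(lab, lab)
    G
  })
})

#' Write component model matrices as TSV
#'
#' One 8 x 8 matrix per component, with the H-T-E condition labels as
#' header and row names.
#'
#' @param components a [ComponentSet-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
writeComponentMatrices <- function(components, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Gs <- modelMatrices(components)
  paths <- vapply(names(Gs), function(nm) {
    f <- file.path(dir, paste0("component_", nm, ".tsv"))
    write.table(Gs[[nm]], f, sep = "\t", quote = FALSE, col.names = NA)
    f
  }, character(1))
  invisible(paths)
}
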