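#' Serialise a PatternSet to plain-text files
#'
#' Writes one TSV per subject/run (conditions x voxels, canonical H-T-E
#' labels as row names) plus a `manifest.json` carrying the assay list,
#' the generative spec and seed, and any known true second-moment
#' matrices.
#'
#' @param x a [PatternSet-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writePatternSet <- function(x, dir) {
  stopifnot(is(x, "PatternSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- setNames(paste0("u_", assayNames(x), ".tsv"), assayNames(x))
  for (nm in assayNames(x))
    write.table(assay(x, nm), file.path(dir, files[[nm]]), sep = "\t",
                quote = FALSE, col.names = FALSE)
  manifest <- list(conditions = rownames(x),
                   assays = as.list(files),
                   spec = metadata(x)$spec,
                   trueG = metadata(x)$trueG)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a PatternSet written by [writePatternSet()]
#'
#' @param dir directory holding `manifest.json` and the per-assay TSVs.
#' @return A [PatternSet-class].
#' @export
readPatternSet <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  assays <- lapply(manifest$assays, function(f) {
    tab <- read.delim(file.path(dir, f), header = FALSE, row.names = 1)
    U <- as.matrix(tab)
    dimnames(U) <- list(conditionLabels(), NULL)
    U
  })
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(trialTypes(), row.names = conditionLabels()))
  metadata(se)$spec <- manifest$spec
  tg <- manifest$trueG
  if (!is.null(tg)) {
    if (is.array(tg) && length(dim(tg)) == 3L) {
      tg <- lapply(seq_len(dim(tg)[1]), function(s) tg[s, , ])
    } else {
      tg <- lapply(tg, function(g) matrix(unlist(g), 8, 8, byrow = TRUE))
    }
    metadata(se)$trueG <- tg
  }
  new("PatternSet", se)
}

#' Extract ROI voxel patterns from NIfTI beta images
#'
#' Reads one beta image per condition plus a mask on the same grid, and
#' returns the condition-by-voxel pattern matrix over mask-nonzero
#' voxels, flattened in the native (x-fastest) array order.
#'
#' @param betaFiles character vector of 8 NIfTI paths in canonical
#'   condition order (or named by the H-T-E labels).
#' @param maskFile NIfTI path of the ROI mask (nonzero = in ROI).
#' @return 8 x voxels matrix with canonical row labels.
#' @export
readRoiBetas <- function(betaFiles, maskFile) {
  lab <- conditionLabels()
  if (!is.null(names(betaFiles))) {
    if (!setequal(names(betaFiles), lab))
      stop("missing condition image(s): ",
           paste(setdiff(lab, names(betaFiles)), collapse = ", "),
           call. = FALSE)
    betaFiles <- betaFiles[lab]
  } else if (length(betaFiles) != 8L) {
    stop("need one beta image per condition (8)", call. = FALSE)
  }
  mask <- as.array(RNifti::readNifti(maskFile))
  keep <- which(mask != 0)
  if (!length(keep)) stop("empty mask: no nonzero voxels", call. = FALSE)
  U <- t(vapply(betaFiles, function(f) {
    img <- as.array(RNifti::readNifti(f))
    if (!identical(dim(img), dim(mask)))
      stop("grid mismatch between ", f, " and the mask", call. = FALSE)
    as.numeric(img[keep])
  }, numeric(length(keep))))
  rownames(U) <- lab
  U
}

#' Validated analysis configuration
#'
#' Bundles the inputs and settings of a full analysis: one or more
#' datasets (directories written by [writePatternSet()], keyed by a
#' dataset label such as ROI/epoch), the output directory, and the
#' fitting/permutation settings.
#'
#' @param datasets named character vector of dataset directories.
#' @param outDir output directory.
#' @param K number of label shuffles (>= 1).
#' @param seed master seed.
#' @param pooling,center fit settings.
#' @param levels credibility levels.
#' @return list of class `StudyConfig`.
#' @export
studyConfig <- function(datasets, outDir, K = 1000, seed = 1,
                        pooling = "average", center = TRUE,
                        levels = c(0.80, 0.95)) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be named", call. = FALSE)
  missing <- datasets[!dir.exists(datasets)]
  if (length(missing))
    stop("dataset directory not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (!all(levels > 0 & levels < 1)) stop("levels must be in (0,1)",
                                          call. = FALSE)
  structure(list(datasets = as.list(datasets), outDir = outDir,
                 K = as.integer(K), seed = as.integer(seed),
                 pooling = pooling, center = center, levels = levels),
            class = "StudyConfig")
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' For each configured dataset: assemble per-subject U matrices, fit
#' the component model, score components by Bayesian model reduction,
#' combine subjects, build the shuffle null, and apply the credibility
#' criterion.  Writes `report.tsv` and `report.json` (plus per-dataset
#' fit summaries) into the output directory; every output embeds the
#' config hash and master seed, and reruns with the same config are
#' byte-identical.
#'
#' @param config a [studyConfig()].
#' @param components a [ComponentSet-class].
#' @return Invisibly, the combined report data.frame.
#' @export
runPipeline <- function(config, components = componentModels()) {
  stopifnot(inherits(config, "StudyConfig"))
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  hash <- .config_hash(config)
  reports <- list()
  fits <- list()
  for (nm in names(config$datasets)) {
    ps <- tryCatch(readPatternSet(config$datasets[[nm]]),
                   error = function(e)
                     stop("[load:", nm, "] ", conditionMessage(e),
                          call. = FALSE))
    nd <- tryCatch(
      shuffleNull(ps, components = components, K = config$K,
                  seed = config$seed, pooling = config$pooling,
                  center = config$center),
      error = function(e)
        stop("[fit:", nm, "] ", conditionMessage(e), call. = FALSE))
    rep1 <- evidenceReport(nd, levels = config$levels)
    rep1 <- cbind(dataset = nm, rep1)
    reports[[nm]] <- rep1
    fits[[nm]] <- list(real_deltaF = as.list(realEvidence(nd)),
                       n_subjects = nd@nSubjects, K = config$K)
  }
  report <- do.call(rbind, c(reports, make.row.names = FALSE))
  write.table(report, file.path(config$outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config), config_hash = hash,
         seed = config$seed, fits = fits, report = report),
    file.path(config$outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Serialise a run design as JSON
#'
#' The trial list (onsets and event times in seconds, half-open
#' intervals), TR and scan count; 0-based scan indexing is implied by
#' scan times `0, tr, 2*tr, ...`.
#'
#' @param run a [RunDesign-class].
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
writeRunDesign <- function(run, path) {
  stopifnot(is(run, "RunDesign"))
  jsonlite::write_json(list(tr_s = run@tr, n_scans = run@nScans,
                            trials = run@trials),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @describeIn writeRunDesign Read a run design back from JSON.
#' @export
readRunDesign <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RunDesign", trials = as.data.frame(x$trials), tr = x$tr_s,
      nScans = as.integer(x$n_scans))
}

#' Write a design matrix as TSV with named header
#'
#' @param X a [DesignMatrix-class].
#' @param path output `.tsv` path.
#' @return Invisibly, `path`.
#' @export
writeDesignMatrix <- function(X, path) {
  stopifnot(is(X, "DesignMatrix"))
  write.table(X@matrix, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
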