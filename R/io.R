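#' Read and write regional time series as TSV
#'
#' The on-disk format is a tab-separated table, frames in rows, one column
#' per region with header `region_<id>`, preceded by a comment line
#' `# tr=<seconds>`. Round trips preserve values to within float-formatting
#' precision (better than 1e-12 relative).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param path file path.
#' @return `readTimeSeriesTsv()`: a [RoiTimeSeries-class];
#'   `writeTimeSeriesTsv()`: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeTimeSeriesTsv(RoiTimeSeries(matrix(rnorm(20), 5, 4), tr = 2), f)
#' readTimeSeriesTsv(f)
#' @export
writeTimeSeriesTsv <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.10g", ts@tr), con)
  df <- as.data.frame(ts@series)
  names(df) <- paste0("region_", ts@regionIds)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeriesTsv
#' @export
readTimeSeriesTsv <- function(path) {
  header <- readLines(path, n = 1L)
  tr <- suppressWarnings(as.numeric(sub("^#\\s*tr=", "", header)))
  if (!startsWith(header, "#") || is.na(tr))
    stop("missing '# tr=' header in ", path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  ids <- as.integer(sub("^region_", "", names(df)))
  if (anyNA(ids))
    stop("malformed region header in ", path)
  RoiTimeSeries(as.matrix(df), tr = tr, regionIds = ids)
}

#' Read and write motion-parameter files
#'
#' Six whitespace-delimited columns (tx, ty, tz in mm; rx, ry, rz
#' rotations), with the rotation unit declared in a leading comment line
#' `# rotation_unit: radians|degrees`. Reading a file without a declared
#' unit (and without a `unit` override) is an error, because frame-wise
#' displacement depends on it.
#'
#' @param m a [MotionTrace-class].
#' @param path file path.
#' @param unit override/declare the rotation unit when the file has no
#'   header comment.
#' @return `readMotionFile()`: a [MotionTrace-class].
#' @export
writeMotionFile <- function(m, path) {
  stopifnot(is(m, "MotionTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rotation_unit: ", m@unit), con)
  write.table(format(m@params, digits = 17, trim = TRUE,
                     scientific = FALSE),
              con, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeMotionFile
#' @export
readMotionFile <- function(path, unit = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*rotation_unit:", first)) {
    fileUnit <- trimws(sub("^#\\s*rotation_unit:", "", first))
    if (is.null(unit)) unit <- fileUnit
  }
  if (is.null(unit))
    stop("rotation unit undeclared in ", path,
         "; pass unit = 'radians' or 'degrees'")
  p <- as.matrix(read.table(path, comment.char = "#"))
  if (ncol(p) != 6L)
    stop("motion file ", path, " must have 6 columns, found ", ncol(p))
  MotionTrace(p, unit = unit)
}

#' Read a region-name table
#'
#' Tab-separated table with columns `id` (integer atlas label), `name`, and
#' optionally `category`. IDs must be unique.
#'
#' @param path file path.
#' @param requiredIds optional IDs that must all be covered.
#' @return data.frame with columns id, name, and category if present.
#' @export
readRegionTable <- function(path, requiredIds = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(df)))
    stop("region table ", path, " must have columns 'id' and 'name'")
  if (anyDuplicated(df$id))
    stop("duplicate region IDs in ", path)
  if (!is.null(requiredIds)) {
    missing <- setdiff(requiredIds, df$id)
    if (length(missing))
      stop("region table ", path, " is missing label(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Read NIfTI volumes for parcellation
#'
#' Thin wrappers over [RNifti::readNifti()]: `readVolume4d()` returns the
#' 4D functional array, `readAtlas3d()` the 3D integer label array.
#'
#' @param path NIfTI file path.
#' @return a plain numeric (or integer) array.
#' @export
readVolume4d <- function(path) {
  vol <- RNifti::readNifti(path)
  arr <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(arr)) != 4L)
    stop(path, " is not a 4D volume")
  arr
}

#' @rdname readVolume4d
#' @export
readAtlas3d <- function(path) {
  vol <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.numeric(vol))), dim = dim(vol))
  if (length(dim(arr)) != 3L)
    stop(path, " is not a 3D atlas")
  arr
}

#' Read and validate a study manifest
#'
#' The manifest is a TSV with columns `subject_id`, `session`
#' (`pre`/`post`), `label` (-1/+1), `path` (time-series or feature file,
#' relative paths resolved against the manifest's directory), and
#' optionally `motion` and `kind` (`timeseries`/`features`; all rows must
#' agree). Validation enforces: label -1 iff session pre, all paths exist,
#' and every subject appears exactly once per session.
#'
#' @param path manifest file path.
#' @return data.frame of validated rows with absolute paths and a `kind`
#'   attribute.
#' @export
readManifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (!all(df$session %in% c("pre", "post")))
    stop("manifest sessions must be 'pre' or 'post'")
  if (!all(df$label == ifelse(df$session == "pre", -1, 1)))
    stop("manifest labels must be -1 for pre and +1 for post")
  tab <- table(df$subject_id, df$session)
  if (any(tab != 1L))
    stop("unpaired subject(s) in manifest: ",
         paste(rownames(tab)[rowSums(tab != 1L) > 0], collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$path <- resolve(df$path)
  missing <- !file.exists(df$path)
  if (any(missing))
    stop("manifest path(s) do not exist: ",
         paste(df$path[missing], collapse = ", "))
  if ("motion" %in% names(df)) {
    hasMotion <- !is.na(df$motion) & nzchar(df$motion)
    df$motion[hasMotion] <- resolve(df$motion[hasMotion])
  }
  kind <- if ("kind" %in% names(df)) unique(df$kind) else "timeseries"
  if (length(kind) != 1L)
    stop("manifest mixes input kinds: ", paste(kind, collapse = ", "))
  if (!kind %in% c("timeseries", "features"))
    stop("unknown input kind '", kind, "'")
  attr(df, "kind") <- kind
  df
}

#' Write a synthetic paired study to disk
#'
#' Writes one time-series TSV per subject and session, a manifest, a
#' ground-truth JSON (planted edges and shifts), and optional motion files,
#' in the layout [readManifest()] and [runPipeline()] consume.
#'
#' @param study a [PairedStudy-class].
#' @param dir output directory (created if needed).
#' @param motion optional named list of [MotionTrace-class] per subject
#'   (the same trace is referenced for both sessions).
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(study, dir, motion = NULL) {
  stopifnot(is(study, "PairedStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in study@subjects) {
    for (sess in c("pre", "post")) {
      ts <- if (sess == "pre") study@pre[[s]] else study@post[[s]]
      fn <- sprintf("%s_%s.tsv", s, sess)
      writeTimeSeriesTsv(ts, file.path(dir, fn))
      mfn <- ""
      if (!is.null(motion) && s %in% names(motion)) {
        mfn <- sprintf("%s_motion.txt", s)
        writeMotionFile(motion[[s]], file.path(dir, mfn))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, session = sess,
        label = if (sess == "pre") -1L else 1L, path = fn, motion = mfn)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(
    seed = study@seed,
    edges = if (nrow(study@truth@edges))
      data.frame(i = study@truth@edges[, 1L],
                 j = study@truth@edges[, 2L],
                 delta_r = study@truth@deltaR)
    else data.frame(i = integer(0), j = integer(0), delta_r = numeric(0)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Write edge-level result tables
#'
#' `writeFeatureTable()` writes the ranked feature table (edge index,
#' region pair, optional names, tau, |tau|, number of folds selecting the
#' edge); `writeConsensusTsv()` the consensus edge list with signs;
#' `writeRegionWeightsTsv()` the per-region consensus degrees.
#'
#' @param cv a [CVResult-class].
#' @param consensus a [ConsensusSet-class].
#' @param nRegions number of regions R.
#' @param path output file.
#' @param regionNames optional data.frame from [readRegionTable()].
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(cv, consensus, nRegions, path,
                              regionNames = NULL) {
  tau <- consensus@fullTau@tau
  pairs <- edgeIndex(seq_along(tau), nRegions)
  nfolds <- tabulate(unlist(consensus@perFold), nbins = length(tau))
  df <- data.frame(edge = seq_along(tau), i = pairs[, 1L], j = pairs[, 2L],
                   tau = tau, abs_tau = abs(tau),
                   selected_in_folds = nfolds)
  if (!is.null(regionNames)) {
    df$name_i <- regionNames$name[match(df$i, regionNames$id)]
    df$name_j <- regionNames$name[match(df$j, regionNames$id)]
  }
  df <- df[order(-df$abs_tau, df$edge), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
writeConsensusTsv <- function(consensus, nRegions, path,
                              regionNames = NULL) {
  e <- consensus@edges
  pairs <- if (length(e)) edgeIndex(e, nRegions)
           else matrix(integer(0), 0, 2)
  df <- data.frame(edge = e, i = pairs[, 1L], j = pairs[, 2L],
                   sign = consensus@signs,
                   tau = consensus@fullTau@tau[e])
  if (!is.null(regionNames)) {
    df$name_i <- regionNames$name[match(df$i, regionNames$id)]
    df$name_j <- regionNames$name[match(df$j, regionNames$id)]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
writeRegionWeightsTsv <- function(consensus, nRegions, path,
                                  regionNames = NULL) {
  w <- regionWeights(consensus, nRegions)
  df <- data.frame(region = as.integer(names(w)), weight = as.numeric(w))
  if (!is.null(regionNames))
    df$name <- regionNames$name[match(df$region, regionNames$id)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full connectome-MVPA pipeline
#'
#' End-to-end driver: reads a study manifest (regional time series or
#' precomputed feature files), optionally preprocesses each series
#' (discard, nuisance regression of motion parameters, band-pass,
#' FD scrubbing), builds Fisher-z connectivity features, runs LOOCV with
#' nested Kendall-tau selection, derives the consensus connections and
#' region weights, and (when `B > 0`) the whole-pipeline permutation test.
#' The returned report carries every parameter and seed needed to
#' reproduce the run; rerunning with the same inputs and seed gives an
#' identical report.
#'
#' @param manifest path to a manifest file (see [readManifest()]) or an
#'   already-validated manifest data.frame.
#' @param config an [SvmConfig-class].
#' @param B permutations for the significance test (0 skips it).
#' @param scheme permutation scheme, `"free"` or `"paired"`.
#' @param seed seed for the permutation test.
#' @param preprocess list of preprocessing options applied to each series
#'   (`discard`, `lowHz`, `highHz`, `fdThresholdMm`, `regressMotion`), or
#'   `NULL` to use the series as given.
#' @param outDir optional directory; when given, the JSON report and the
#'   feature/consensus/region-weight TSVs are written there.
#' @param regionNames optional region-name table (see [readRegionTable()]).
#' @return the report, an invisible list.
#' @export
runPipeline <- function(manifest, config = svmConfig(), B = 0,
                        scheme = "free", seed = 1, preprocess = NULL,
                        outDir = NULL, regionNames = NULL) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  kind <- attr(manifest, "kind")
  if (is.null(kind)) kind <- "timeseries"
  prepLogs <- list()
  if (kind == "timeseries") {
    feats <- vector("list", nrow(manifest))
    nReg <- NULL
    for (r in seq_len(nrow(manifest))) {
      ts <- readTimeSeriesTsv(manifest$path[r])
      if (!is.null(preprocess)) {
        motion <- NULL
        cov <- NULL
        if (isTRUE(preprocess$regressMotion) &&
            "motion" %in% names(manifest) && nzchar(manifest$motion[r])) {
          motion <- readMotionFile(manifest$motion[r])
          keep <- seq_len(nFrames(motion))
          disc <- preprocess$discard %||% 0
          if (disc > 0) keep <- keep[-seq_len(disc)]
          motion <- MotionTrace(motionParams(motion)[keep, , drop = FALSE],
                                unit = rotationUnit(motion))
          cov <- motionParams(motion)
        }
        pp <- preprocessSeries(
          ts, discard = preprocess$discard %||% 0, covariates = cov,
          motion = motion, lowHz = preprocess$lowHz %||% NULL,
          highHz = preprocess$highHz %||% 0.08,
          fdThresholdMm = preprocess$fdThresholdMm %||% 0.5)
        ts <- pp$series
        prepLogs[[r]] <- pp$log
      }
      fv <- vectorizeUpper(correlationMatrix(ts))
      if (is.null(nReg)) nReg <- nRegions(fv)
      else if (nReg != nRegions(fv))
        stop("inconsistent region counts across manifest rows")
      feats[[r]] <- zValues(fv)
    }
    z <- do.call(rbind, feats)
  } else {
    feats <- lapply(manifest$path, function(p) {
      df <- read.table(p, header = TRUE, sep = "\t", comment.char = "#")
      if (!all(c("i", "j", "z") %in% names(df)))
        stop("feature file ", p, " must have columns i, j, z")
      R <- max(df$j)
      df <- df[order(pairIndex(df$i, df$j, R)), ]
      structure(df$z, nRegions = R)
    })
    nReg <- unique(vapply(feats, attr, numeric(1), "nRegions"))
    if (length(nReg) != 1L)
      stop("inconsistent region counts across feature files")
    z <- do.call(rbind, feats)
  }

  study <- LabeledStudy(z, labels = manifest$label,
                        subjects = manifest$subject_id)
  cv <- loocv(study, config)
  fullTau <- kendallTau(zMatrix(study), studyLabels(study))
  cons <- consensusConnections(cv@selections, fullTau)
  weights <- regionWeights(cons, nReg)
  perm <- if (B > 0)
    permutationTest(study, config, B = B, scheme = scheme, seed = seed)
  else NULL

  consPairs <- if (length(cons@edges)) edgeIndex(cons@edges, nReg)
               else matrix(integer(0), 0, 2)
  report <- list(
    n_samples = nrow(z), n_features = ncol(z), n_regions = nReg,
    config = list(sigma = config@sigma, C = config@C, k = config@k),
    seed = as.integer(seed),
    metrics = as.list(cv@metrics),
    folds = cv@folds,
    consensus = data.frame(edge = cons@edges, i = consPairs[, 1L],
                           j = consPairs[, 2L], sign = cons@signs),
    region_weights = as.list(weights),
    permutation = if (!is.null(perm))
      list(gr0 = perm@gr0, p = perm@p, B = perm@B, scheme = perm@scheme,
           null_mean = mean(perm@nullGr),
           null_q95 = as.numeric(quantile(perm@nullGr, 0.95)))
    else NULL,
    preprocessing = prepLogs)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeFeatureTable(cv, cons, nReg, file.path(outDir, "features.tsv"),
                      regionNames)
    writeConsensusTsv(cons, nReg, file.path(outDir, "consensus.tsv"),
                      regionNames)
    writeRegionWeightsTsv(cons, nReg,
                          file.path(outDir, "region_weights.tsv"),
                          regionNames)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
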