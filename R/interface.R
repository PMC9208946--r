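# Formats and the end-to-end runner. Volumes travel as NIfTI-1 (TR in the
# time-axis pixdim), motion traces as 6-column TSV, configuration, reports
# and the run manifest as JSON. The runner ties phantom -> denoise ->
# segment and phantom -> BOLD -> ALFF/zALFF together with one seed.

#' Read a NIfTI-1 volume
#'
#' 2D/3D files are returned as plain arrays; 4D files become a
#' [BoldSeries-class] with the repetition time taken from the time-axis
#' pixdim field and an all-TRUE mask (attach a real mask downstream).
#'
#' @param path a .nii or .nii.gz file.
#' @return array or [BoldSeries-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("could not parse '", path, "' as a NIfTI-1 volume: ",
         conditionMessage(e), call. = FALSE))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop("4D file '", path, "' has no positive TR in pixdim[4]")
    new("BoldSeries", data = arr, tr = tr,
        mask = array(TRUE, dim = dim(arr)[1:3]))
  } else arr
}

#' Write a volume as NIfTI-1
#'
#' Arrays, label maps, [BoldSeries-class] (TR stored in the time-axis
#' pixdim), and ALFF/zALFF maps (values written) are supported.
#'
#' @param obj array, [BoldSeries-class], [ALFFMap-class] or
#'   [ZALFFMap-class].
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(obj, path) {
  if (is(obj, "BoldSeries")) {
    img <- RNifti::asNifti(obj@data)
    RNifti::pixdim(img) <- c(rep(1, length(dim(obj@data)) - 1L), obj@tr)
  } else if (is(obj, "ALFFMap") || is(obj, "ZALFFMap")) {
    img <- RNifti::asNifti(obj@values)
  } else {
    img <- RNifti::asNifti(obj)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 6-column motion trace TSV
#'
#' Columns tx, ty, tz (mm) and rx, ry, rz (degrees), one row per volume,
#' tab-separated with a header line.
#'
#' @param path TSV file path.
#' @return data.frame with the 6 motion columns.
#' @export
readMotion <- function(path) {
  mot <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!all(need %in% names(mot)))
    stop("motion TSV must have columns ", paste(need, collapse = ", "))
  mot[, need]
}

#' @rdname readMotion
#' @param motion data.frame or matrix with the 6 motion columns.
#' @export
writeMotion <- function(motion, path) {
  motion <- as.data.frame(motion)
  names(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sidecarFor <- function(path, params, seed) {
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  payload <- list(parameters = params, seed = seed,
                  software = paste0("neurofuzz ",
                                    utils::packageVersion("neurofuzz")))
  jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  side
}

#' Run the phantom-to-results pipeline
#'
#' Executes the enabled stages in order on one seed: tissue phantom
#' generation, optional corruption, adaptive median denoising, FCM
#' segmentation with Jaccard scoring against the phantom truth, BOLD phantom
#' generation, motion QC, trimming, and ALFF/mALFF/zALFF mapping. Every
#' written volume gets a JSON sidecar recording the stage parameters, the
#' seed and the package version; a manifest of outputs and headline numbers
#' is written to \code{manifest.json} and returned. Reruns with the same
#' configuration and seed reproduce all numeric outputs exactly.
#'
#' @param config nested list; see the package vignette. Recognised blocks:
#'   \code{phantom} (shape, tissueMeans, tissueSd), \code{corrupt} (model,
#'   level), \code{denoise} (sInit, sMax), \code{segment} (C, m, maxIter,
#'   tol, init), \code{bold} (oscillations, tr, nVolumes, motion),
#'   \code{alff} (band, trim). Top-level: \code{seed}, \code{outDir}, and
#'   optional \code{files} — a character vector of paths that must exist
#'   before anything runs.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) stop("config$outDir is required")
            else config$outDir
  # pre-flight: every referenced file must exist before any compute
  for (f in config$files)
    if (!file.exists(f)) stop("pre-flight failure: missing file '", f, "'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("neurofuzz")),
                   stages = list())
  # fn returns list(result = <in-memory object>, manifest = <plain entry>);
  # only the manifest part is recorded, so large arrays never land in JSON.
  runStage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[neurofuzz] stage %-8s done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    manifest$stages[[name]] <<- out$manifest
    out$result
  }

  phantom <- NULL
  if (!is.null(config$phantom)) {
    p <- config$phantom
    phantom <- runStage("phantom", function() {
      ph <- generateTissuePhantom(
        shape = if (is.null(p$shape)) c(64L, 64L) else unlist(p$shape),
        tissueMeans = if (is.null(p$tissueMeans)) c(20, 120, 220)
                      else unlist(p$tissueMeans),
        tissueSd = if (is.null(p$tissueSd)) 5 else p$tissueSd,
        seed = seed)
      img <- file.path(outDir, "phantom.nii.gz")
      lab <- file.path(outDir, "phantom_labels.nii.gz")
      writeVolume(phantomImage(ph), img)
      writeVolume(trueLabels(ph), lab)
      sidecarFor(img, p, seed)
      list(result = ph, manifest = list(image = img, labels = lab))
    })
  }

  workImage <- if (!is.null(phantom)) phantomImage(phantom) else NULL
  if (!is.null(config$corrupt)) {
    cc <- config$corrupt
    img0 <- workImage
    workImage <- runStage("corrupt", function() {
      if (is.null(img0)) stop("no image to corrupt (enable phantom)")
      out <- corruptImage(img0, model = cc$model, level = cc$level,
                          seed = seed)
      f <- file.path(outDir, "corrupted.nii.gz")
      writeVolume(out, f)
      sidecarFor(f, cc, seed)
      list(result = out, manifest = list(image = f, model = cc$model,
                                         level = cc$level))
    })
  }
  if (!is.null(config$denoise)) {
    dn <- config$denoise
    img0 <- workImage
    workImage <- runStage("denoise", function() {
      if (is.null(img0)) stop("no image to denoise")
      out <- adaptiveMedianFilter(
        img0,
        sInit = if (is.null(dn$sInit)) 3L else dn$sInit,
        sMax = if (is.null(dn$sMax)) 7L else dn$sMax)
      f <- file.path(outDir, "denoised.nii.gz")
      writeVolume(out, f)
      sidecarFor(f, dn, seed)
      list(result = out, manifest = list(image = f))
    })
  }
  if (!is.null(config$segment)) {
    sg <- config$segment
    img0 <- workImage
    runStage("segment", function() {
      if (is.null(img0)) stop("no image to segment")
      seg <- fcmSegment(
        img0,
        C = if (is.null(sg$C)) 3L else sg$C,
        m = if (is.null(sg$m)) 2 else sg$m,
        maxIter = if (is.null(sg$maxIter)) 100L else sg$maxIter,
        tol = if (is.null(sg$tol)) 1e-4 else sg$tol,
        init = if (is.null(sg$init)) "pso" else sg$init,
        seed = seed)
      f <- file.path(outDir, "segmentation.nii.gz")
      writeVolume(labelMap(seg), f)
      sidecarFor(f, sg, seed)
      entry <- list(labels = f, centers = clusterCenters(seg),
                    nIter = nIterations(seg), converged = isConverged(seg),
                    finalObjective = utils::tail(objectiveTrace(seg), 1))
      if (!is.null(phantom))
        entry$perClassJaccard <- as.list(
          perClassJaccard(labelMap(seg), trueLabels(phantom)))
      list(result = seg, manifest = entry)
    })
  }

  if (!is.null(config$bold)) {
    bd <- config$bold
    if (is.null(phantom)) stop("bold stage requires the phantom stage")
    boldOut <- runStage("bold", function() {
      osc <- lapply(bd$oscillations, function(o)
        do.call(oscillationSpec, o))
      gb <- generateBoldSeries(
        trueLabels(phantom), oscillations = osc,
        tr = if (is.null(bd$tr)) 2 else bd$tr,
        nVolumes = if (is.null(bd$nVolumes)) 240L else bd$nVolumes,
        seed = seed,
        motion = if (is.null(bd$motion)) "clean" else bd$motion,
        noiseSd = if (is.null(bd$noiseSd)) 0 else bd$noiseSd)
      f <- file.path(outDir, "bold.nii.gz")
      mf <- file.path(outDir, "motion.tsv")
      writeVolume(gb$series, f)
      writeMotion(gb$motion, mf)
      sidecarFor(f, bd, seed)
      list(result = gb, manifest = list(bold = f, motion = mf))
    })
    if (!is.null(config$alff)) {
      al <- config$alff
      runStage("alff", function() {
        qc <- qcMotion(boldOut$motion)
        if (!qc$pass)
          return(list(result = NULL,
                      manifest = list(qc = "fail",
                                      offendingVolumes =
                                        as.integer(qc$offending))))
        ser <- trimInitial(boldOut$series,
                           n = if (is.null(al$trim)) 15L else al$trim)
        band <- if (is.null(al$band)) c(0.01, 0.08) else unlist(al$band)
        am <- computeALFF(ser, band = band)
        mm <- computeMALFF(am)
        zm <- computeZALFF(am)
        fa <- file.path(outDir, "alff.nii.gz")
        fm <- file.path(outDir, "malff.nii.gz")
        fz <- file.path(outDir, "zalff.nii.gz")
        writeVolume(am, fa); writeVolume(mm, fm); writeVolume(zm, fz)
        sidecarFor(fz, list(band = band, mean = zm@sourceMean,
                            sd = zm@sourceSd, qc = "pass"), seed)
        list(result = zm,
             manifest = list(qc = "pass", alff = fa, malff = fm,
                             zalff = fz, sourceMean = zm@sourceMean,
                             sourceSd = zm@sourceSd))
      })
    }
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
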