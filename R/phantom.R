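# Seeded generators of ground-truthed phantoms: multi-tissue intensity
# images, noise corruptions, 4D BOLD series with ROI-confined oscillations,
# and motion traces. Everything downstream is testable against these.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators never perturb user simulations.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Concentric-geometry label array: class 1 is the innermost disc (sphere in
# 3D), the last class fills the exterior including corners. Known, strictly
# positive class sizes for any grid with every axis >= 8.
concentricLabels <- function(shape, nClasses) {
  centre <- (shape + 1) / 2
  half <- min(shape) / 2
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  rho <- sqrt(rowSums(sweep(idx, 2, centre)^2)) / half
  lab <- pmin(floor(rho * nClasses) + 1L, nClasses)
  array(as.integer(lab), dim = shape)
}

#' Generate a ground-truthed multi-tissue phantom
#'
#' Builds a concentric-geometry phantom (innermost disc = first class, e.g.
#' CSF; outermost shell = last class, e.g. WM) and draws pixel intensities as
#' Gaussian deviates around the per-class means. The returned object carries
#' the exact label map, so segmentation accuracy can be scored against truth.
#'
#' @param shape integer vector of grid dimensions (2 or 3 axes), each >= 8.
#' @param tissueMeans numeric vector of distinct per-class mean intensities
#'   (ascending order maps to CSF < GM < WM on a T1-like contrast).
#' @param tissueSd non-negative within-class intensity SD.
#' @param seed integer RNG seed; identical seeds give identical phantoms.
#' @return A [TissuePhantom-class] object.
#' @examples
#' ph <- generateTissuePhantom(c(64, 64), c(20, 120, 220), tissueSd = 5)
#' table(trueLabels(ph))
#' @export
generateTissuePhantom <- function(shape = c(64L, 64L),
                                  tissueMeans = c(20, 120, 220),
                                  tissueSd = 5,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L)
    stop("shape must have 2 or 3 dimensions")
  if (any(shape < 8L))
    stop("every phantom axis must be at least 8 pixels")
  if (length(tissueMeans) < 2L)
    stop("at least 2 tissue classes are required")
  if (anyDuplicated(tissueMeans))
    stop("tissue class means must be distinct")
  if (tissueSd < 0) stop("tissueSd must be non-negative")

  labels <- concentricLabels(shape, length(tissueMeans))
  counts <- tabulate(labels, nbins = length(tissueMeans))
  if (any(counts == 0L))
    stop("degenerate geometry: class(es) ",
         paste(which(counts == 0L), collapse = ", "), " have zero pixels")

  img <- withSeed(seed, {
    array(tissueMeans[labels] + stats::rnorm(length(labels), 0, tissueSd),
          dim = shape)
  })
  new("TissuePhantom", image = img, labels = labels,
      tissueMeans = as.numeric(tissueMeans), tissueSd = as.numeric(tissueSd),
      seed = as.integer(seed))
}

#' Corrupt an intensity image with impulse or Gaussian noise
#'
#' Impulse (salt-and-pepper) noise sets an exact fraction of pixels, sampled
#' without replacement, to the minimum or maximum representable intensity
#' with equal probability; all other pixels are bit-identical to the input.
#' Gaussian noise adds i.i.d. deviates everywhere.
#'
#' @param image numeric array.
#' @param model "impulse" or "gaussian".
#' @param level for impulse, the fraction of pixels corrupted (in [0, 1]);
#'   for gaussian, the noise SD (> 0, or 0 for a no-op).
#' @param seed integer RNG seed.
#' @param range length-2 numeric, the representable intensity range used for
#'   salt/pepper values (default the nominal 0--255 scale).
#' @return The corrupted array, same shape as the input.
#' @export
corruptImage <- function(image, model = c("impulse", "gaussian"),
                         level, seed = 1L, range = c(0, 255)) {
  model <- match.arg(model)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level))
    stop("level must be a single finite number")
  if (level == 0) return(image)
  out <- image
  if (model == "impulse") {
    if (level < 0 || level > 1)
      stop("impulse level must lie in [0, 1] (fraction of pixels)")
    n <- round(level * length(image))
    withSeed(seed, {
      idx <- sample.int(length(image), n)
      out[idx] <- ifelse(stats::runif(n) < 0.5, range[1], range[2])
    })
  } else {
    if (level < 0) stop("gaussian level (SD) must be positive")
    withSeed(seed, {
      out <- image + array(stats::rnorm(length(image), 0, level),
                           dim = dim(image))
    })
  }
  out
}

#' Specify a low-frequency oscillation confined to one ROI
#'
#' @param roiLabel integer label code of the ROI carrying the oscillation.
#' @param frequency oscillation frequency in Hz (>= 0).
#' @param amplitude oscillation amplitude in signal units (>= 0).
#' @param phase phase in radians.
#' @param baseline baseline signal level in the ROI.
#' @param noiseSd SD of i.i.d. Gaussian noise added to the ROI series (>= 0).
#' @return A list of class "OscillationSpec".
#' @export
oscillationSpec <- function(roiLabel, frequency, amplitude, phase = 0,
                            baseline = 100, noiseSd = 0) {
  if (frequency < 0) stop("frequency must be non-negative")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  structure(list(roiLabel = as.integer(roiLabel), frequency = frequency,
                 amplitude = amplitude, phase = phase, baseline = baseline,
                 noiseSd = noiseSd),
            class = "OscillationSpec")
}

#' Generate a 4D BOLD series with ROI-confined oscillations
#'
#' Voxels inside each oscillation's ROI follow
#' \code{baseline + amplitude * sin(2*pi*f*t + phase) + noise}; all other
#' voxels follow \code{baseline + noise}. Sampling times are
#' \code{t = (0, tr, 2*tr, ...)}. A 6-column motion trace (tx, ty, tz in mm;
#' rx, ry, rz in degrees) is returned alongside: all zeros for the "clean"
#' scenario, or with one mid-series volume exceeding the 3 mm / 3 degree
#' thresholds for the "spike" scenario used to exercise motion QC.
#'
#' @param labels integer label array (2D or 3D) defining the ROIs.
#' @param oscillations list of [oscillationSpec()] objects.
#' @param tr repetition time in seconds (> 0).
#' @param nVolumes number of time points (>= 32).
#' @param seed integer RNG seed.
#' @param motion "clean" or "spike".
#' @param baseline baseline level of voxels outside every oscillation ROI.
#' @param noiseSd noise SD of voxels outside every oscillation ROI (>= 0).
#' @return list with elements \code{series} (a [BoldSeries-class]) and
#'   \code{motion} (a data.frame with columns tx, ty, tz, rx, ry, rz).
#' @export
generateBoldSeries <- function(labels, oscillations = list(), tr = 2,
                               nVolumes = 240L, seed = 1L,
                               motion = c("clean", "spike"),
                               baseline = 100, noiseSd = 0) {
  motion <- match.arg(motion)
  if (tr <= 0) stop("tr must be positive")
  nVolumes <- as.integer(nVolumes)
  if (nVolumes < 32L) stop("at least 32 volumes are required")
  if (inherits(oscillations, "OscillationSpec"))
    oscillations <- list(oscillations)
  nyquist <- 1 / (2 * tr)
  for (os in oscillations) {
    if (!inherits(os, "OscillationSpec"))
      stop("oscillations must be a list of OscillationSpec objects")
    if (os$frequency > nyquist)
      stop(sprintf(
        "oscillation frequency %.4g Hz exceeds the Nyquist limit %.4g Hz (tr = %g s)",
        os$frequency, nyquist, tr))
  }
  spatial <- dim(labels)
  nVox <- prod(spatial)
  tt <- (seq_len(nVolumes) - 1) * tr

  data <- withSeed(seed, {
    # voxels x time; background first, then overwrite each oscillation ROI
    m <- matrix(baseline, nrow = nVox, ncol = nVolumes)
    if (noiseSd > 0)
      m <- m + matrix(stats::rnorm(nVox * nVolumes, 0, noiseSd),
                      nrow = nVox)
    for (os in oscillations) {
      vox <- which(as.integer(labels) == os$roiLabel)
      if (!length(vox)) next
      sig <- os$baseline +
        os$amplitude * sin(2 * pi * os$frequency * tt + os$phase)
      blk <- matrix(sig, nrow = length(vox), ncol = nVolumes, byrow = TRUE)
      if (os$noiseSd > 0)
        blk <- blk + matrix(stats::rnorm(length(vox) * nVolumes, 0,
                                         os$noiseSd), nrow = length(vox))
      m[vox, ] <- blk
    }
    array(m, dim = c(spatial, nVolumes))
  })

  mot <- data.frame(tx = numeric(nVolumes), ty = 0, tz = 0,
                    rx = 0, ry = 0, rz = 0)
  if (motion == "spike") {
    k <- ceiling(nVolumes / 2)
    mot$tx[k] <- 5
    mot$rx[k] <- 4
  }
  mask <- array(as.integer(labels) > 0L, dim = spatial)
  list(series = new("BoldSeries", data = data, tr = tr, mask = mask),
       motion = mot)
}
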