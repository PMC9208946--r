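# Resting-state amplitude analysis: motion quality control, removal of the
# unstable initial volumes, linear detrending, band-limited spectral
# amplitude (ALFF) over 0.01-0.08 Hz, and the whole-brain normalisations
# mALFF (divide by mean) and zALFF (z-score against the whole-brain mean and
# SD).

#' Motion quality control
#'
#' A subject fails QC if any volume translates strictly more than
#' \code{maxTransMm} millimetres on any axis or rotates strictly more than
#' \code{maxRotDeg} degrees about any axis (a volume at exactly the threshold
#' passes). Failing subjects are excluded whole; no volume scrubbing.
#'
#' @param motion data.frame or matrix with 6 columns: translations tx, ty, tz
#'   in mm and rotations rx, ry, rz in degrees, one row per volume.
#' @param maxTransMm,maxRotDeg exclusion thresholds; defaults 3 mm and
#'   3 degrees.
#' @param nVolumes optional expected number of volumes; a mismatch with the
#'   trace length is an error.
#' @return list with \code{pass} (logical) and \code{offending} (integer
#'   indices of volumes exceeding a threshold).
#' @export
qcMotion <- function(motion, maxTransMm = 3, maxRotDeg = 3,
                     nVolumes = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion trace must have 6 columns (tx, ty, tz, rx, ry, rz)")
  if (!all(is.finite(motion))) stop("motion trace must be finite")
  if (!is.null(nVolumes) && nrow(motion) != nVolumes)
    stop(sprintf("motion trace has %d rows but the series has %d volumes",
                 nrow(motion), nVolumes))
  transBad <- apply(abs(motion[, 1:3, drop = FALSE]) > maxTransMm, 1L, any)
  rotBad <- apply(abs(motion[, 4:6, drop = FALSE]) > maxRotDeg, 1L, any)
  offending <- which(transBad | rotBad)
  list(pass = length(offending) == 0L, offending = offending)
}

#' Drop the unstable initial volumes of a BOLD series
#'
#' Removes the first \code{n} time points (default 15), which are dominated
#' by the approach to steady-state magnetisation; the repetition time and
#' mask are unchanged.
#'
#' @param series a [BoldSeries-class].
#' @param n number of leading volumes to drop; must be smaller than the
#'   series length.
#' @return the trimmed [BoldSeries-class].
#' @export
trimInitial <- function(series, n = 15L) {
  stopifnot(is(series, "BoldSeries"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  d <- dim(series@data)
  nt <- d[length(d)]
  if (nt <= n)
    stop(sprintf("cannot drop %d volumes from a %d-volume series", n, nt))
  if (n == 0L) return(series)
  keep <- (n + 1L):nt
  idx <- c(lapply(d[-length(d)], seq_len), list(keep))
  new("BoldSeries",
      data = do.call(`[`, c(list(series@data), idx, list(drop = FALSE))),
      tr = series@tr, mask = series@mask)
}

# Remove per-voxel linear trends (least-squares line in time) from a
# time x voxel matrix.
detrendLinear <- function(m) {
  nt <- nrow(m)
  X <- cbind(1, seq_len(nt))
  m - X %*% qr.coef(qr(X), m)
}

#' Compute the amplitude of low-frequency fluctuation (ALFF)
#'
#' Each voxel series is linearly detrended, transformed to the frequency
#' domain by FFT, and converted to a one-sided amplitude spectrum
#' (\code{2 |X_k| / n}, the square root of the periodogram power up to a
#' constant, scaled so a pure sinusoid of amplitude A reads A at its bin).
#' ALFF is the mean amplitude over the frequency bins inside the band
#' (band edges inclusive); \code{method = "summed_power"} sums the
#' periodogram power over the band instead. Voxels outside the mask get 0.
#'
#' @param series a [BoldSeries-class].
#' @param band numeric length 2, (low, high) in Hz; must lie strictly below
#'   the Nyquist frequency 1/(2 tr). Default c(0.01, 0.08).
#' @param method "mean_amplitude" (default) or "summed_power".
#' @return an [ALFFMap-class].
#' @export
computeALFF <- function(series, band = c(0.01, 0.08),
                        method = c("mean_amplitude", "summed_power")) {
  stopifnot(is(series, "BoldSeries"))
  method <- match.arg(method)
  d <- dim(series@data)
  nt <- d[length(d)]
  nyquist <- 1 / (2 * series@tr)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be (low, high) with 0 < low < high")
  if (band[2] > nyquist)
    stop(sprintf("band upper edge %.4g Hz exceeds the Nyquist limit %.4g Hz",
                 band[2], nyquist))

  spatial <- d[-length(d)]
  vox <- which(series@mask)
  m <- matrix(aperm(series@data, c(length(d), seq_len(length(d) - 1L))),
              nrow = nt)[, vox, drop = FALSE]
  m <- detrendLinear(m)

  freqs <- (seq_len(nt) - 1) / (nt * series@tr)
  half <- 2:(floor(nt / 2) + 1L)          # positive-frequency bins
  inBand <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  if (!length(inBand))
    stop("no frequency bins fall inside the requested band")

  amp <- 2 * Mod(stats::mvfft(m)[inBand, , drop = FALSE]) / nt
  alff <- if (method == "mean_amplitude") colMeans(amp)
          else colSums((amp / 2)^2 * nt / 2)

  values <- array(0, dim = spatial)
  values[vox] <- alff
  new("ALFFMap", values = values, band = as.numeric(band),
      mask = series@mask)
}

#' Normalise ALFF by the whole-brain mean (mALFF)
#'
#' Divides every in-mask voxel by the in-mask mean ALFF; the resulting map
#' has in-mask mean 1.
#'
#' @param alff an [ALFFMap-class].
#' @return an [ALFFMap-class] of mALFF values.
#' @export
computeMALFF <- function(alff) {
  stopifnot(is(alff, "ALFFMap"))
  v <- alff@values[alff@mask]
  mu <- mean(v)
  if (mu <= 0) stop("within-mask mean ALFF must be positive")
  values <- array(0, dim = dim(alff@values))
  values[alff@mask] <- v / mu
  new("ALFFMap", values = values, band = alff@band, mask = alff@mask)
}

#' Standardise ALFF to zALFF
#'
#' z-scores each in-mask voxel against the whole-brain (in-mask) mean and
#' standard deviation: \eqn{z = (ALFF - \bar{ALFF}) / SD}. The population SD
#' (divisor n) is used by default so the construction is exact:
#' the output has in-mask mean 0 and SD 1. The mean and SD used are stored
#' for provenance.
#'
#' @param alff an [ALFFMap-class].
#' @param sdType "population" (default) or "sample" (divisor n - 1).
#' @return a [ZALFFMap-class].
#' @export
computeZALFF <- function(alff, sdType = c("population", "sample")) {
  stopifnot(is(alff, "ALFFMap"))
  sdType <- match.arg(sdType)
  v <- alff@values[alff@mask]
  mu <- mean(v)
  sdv <- if (sdType == "population") sqrt(mean((v - mu)^2)) else stats::sd(v)
  if (!is.finite(sdv) || sdv <= 0)
    stop("ALFF map is constant within the mask; SD is zero")
  values <- array(0, dim = dim(alff@values))
  values[alff@mask] <- (v - mu) / sdv
  new("ZALFFMap", values = values, band = alff@band, mask = alff@mask,
      sourceMean = mu, sourceSd = sdv)
}

#' Regress nuisance covariates out of a BOLD series
#'
#' Optional ordinary-least-squares residualisation of every voxel series
#' against supplied regressor columns (e.g. mean signal, motion parameters,
#' CSF and WM signals). An intercept is always included; residuals retain
#' the voxel mean so downstream amplitude measures keep their scale origin.
#'
#' @param series a [BoldSeries-class].
#' @param regressors numeric matrix with one row per volume.
#' @return the residualised [BoldSeries-class].
#' @export
residualizeSeries <- function(series, regressors) {
  stopifnot(is(series, "BoldSeries"))
  regressors <- as.matrix(regressors)
  d <- dim(series@data)
  nt <- d[length(d)]
  if (nrow(regressors) != nt)
    stop("regressors must have one row per volume")
  m <- matrix(aperm(series@data, c(length(d), seq_len(length(d) - 1L))),
              nrow = nt)
  mu <- colMeans(m)
  X <- cbind(1, regressors)
  res <- m - X %*% qr.coef(qr(X), m)
  res <- sweep(res, 2L, mu, `+`)
  data <- aperm(array(res, dim = c(nt, d[-length(d)])),
                c(seq_len(length(d) - 1L) + 1L, 1L))
  new("BoldSeries", data = array(data, dim = d), tr = series@tr,
      mask = series@mask)
}
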