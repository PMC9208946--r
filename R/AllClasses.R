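#' @import methods
NULL

#' Tissue phantom with ground-truth labels
#'
#' Container for a synthetic multi-tissue intensity image together with the
#' exact label map that generated it. Labels are integer codes \code{1..C}
#' ordered by ascending class mean intensity (the CSF < GM < WM convention on
#' a T1-like contrast).
#'
#' @slot image numeric array (2D or 3D) of intensities, arbitrary units on a
#'   nominal 0--255 scale.
#' @slot labels integer array, same dimensions as \code{image}; ground truth.
#' @slot tissueMeans numeric vector of per-class mean intensities.
#' @slot tissueSd numeric scalar, within-class intensity standard deviation.
#' @slot seed integer seed the phantom was generated from.
#'
#' @seealso [generateTissuePhantom()]
#' @export
setClass("TissuePhantom",
  representation(
    image = "array",
    labels = "array",
    tissueMeans = "numeric",
    tissueSd = "numeric",
    seed = "integer"
  )
)

setValidity("TissuePhantom", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@labels)))
    msg <- c(msg, "image and labels must share dimensions")
  if (length(object@tissueMeans) < 2L)
    msg <- c(msg, "at least 2 tissue classes are required")
  if (anyDuplicated(object@tissueMeans))
    msg <- c(msg, "tissue class means must be distinct")
  if (length(msg)) msg else TRUE
})

#' 4D BOLD time series
#'
#' A voxel time series with its repetition time and brain mask. The time axis
#' is last; spatial dimensions match the mask.
#'
#' @slot data numeric array with time as the last axis.
#' @slot tr numeric scalar, repetition time in seconds.
#' @slot mask logical array over the spatial grid.
#'
#' @seealso [generateBoldSeries()], [computeALFF()]
#' @export
setClass("BoldSeries",
  representation(data = "array", tr = "numeric", mask = "array")
)

setValidity("BoldSeries", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) < 2L)
    msg <- c(msg, "data must have at least one spatial axis plus time")
  if (!identical(d[-length(d)], dim(object@mask)))
    msg <- c(msg, "mask dimensions must equal the spatial dimensions of data")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Voxel map of band-limited spectral amplitude (ALFF)
#'
#' Per-voxel amplitude of low-frequency fluctuation over a frequency band,
#' non-negative inside the mask and zero outside.
#'
#' @slot values numeric array of ALFF values.
#' @slot band numeric length-2 vector, (low, high) band edges in Hz.
#' @slot mask logical array, same dimensions as \code{values}.
#'
#' @seealso [computeALFF()]
#' @export
setClass("ALFFMap",
  representation(values = "array", band = "numeric", mask = "array")
)

setValidity("ALFFMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  if (length(object@band) != 2L || object@band[1] <= 0 ||
      object@band[2] <= object@band[1])
    msg <- c(msg, "band must be (low, high) with 0 < low < high")
  v <- object@values[object@mask]
  if (length(v) && any(v < -1e-12, na.rm = TRUE))
    msg <- c(msg, "in-mask ALFF values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Standardised ALFF (zALFF) map
#'
#' Voxel-wise z-scores of ALFF, computed against the whole-brain (in-mask)
#' mean and standard deviation, which are retained as provenance. By
#' construction the in-mask mean is 0 and the in-mask SD is 1.
#'
#' @slot values numeric array of z-scores (zero outside the mask).
#' @slot band numeric length-2 vector, band of the source ALFF map (Hz).
#' @slot mask logical array.
#' @slot sourceMean numeric, in-mask mean ALFF used for centring.
#' @slot sourceSd numeric, in-mask ALFF standard deviation used for scaling.
#'
#' @seealso [computeZALFF()]
#' @export
setClass("ZALFFMap",
  representation(values = "array", band = "numeric", mask = "array",
                 sourceMean = "numeric", sourceSd = "numeric")
)

setValidity("ZALFFMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  v <- object@values[object@mask]
  if (length(v) > 1L) {
    if (abs(mean(v)) > 1e-9)
      msg <- c(msg, "in-mask mean of zALFF must be 0 (within 1e-9)")
    sdPop <- sqrt(mean((v - mean(v))^2))
    sdSmp <- stats::sd(v)
    # unit SD under either the population or the sample convention
    if (abs(sdPop - 1) > 1e-9 && abs(sdSmp - 1) > 1e-9)
      msg <- c(msg, "in-mask SD of zALFF must be 1 (within 1e-9)")
  }
  if (object@sourceSd <= 0)
    msg <- c(msg, "sourceSd must be positive")
  if (length(msg)) msg else TRUE
})

#' Fuzzy C-means segmentation result
#'
#' Hard label map, fuzzy membership matrix, fitted cluster centres and the
#' optimisation trace of one FCM run.
#'
#' @slot labels integer array of hard labels (argmax membership), codes
#'   \code{1..C}.
#' @slot membership C x N numeric matrix of memberships; every column sums
#'   to 1.
#' @slot centers numeric vector of C cluster centre intensities.
#' @slot objectiveTrace numeric vector, objective J after each iteration;
#'   non-increasing.
#' @slot nIter integer, iterations performed.
#' @slot converged logical, whether the tolerance was met before the
#'   iteration cap.
#' @slot init character, the initialisation used ("pso", "random", "given").
#'
#' @seealso [fcmSegment()]
#' @export
setClass("FuzzySegmentation",
  representation(
    labels = "array",
    membership = "matrix",
    centers = "numeric",
    objectiveTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    init = "character"
  )
)

setValidity("FuzzySegmentation", function(object) {
  msg <- character()
  u <- object@membership
  if (nrow(u) != length(object@centers))
    msg <- c(msg, "membership rows must match number of centers")
  if (ncol(u) != length(object@labels))
    msg <- c(msg, "membership columns must match number of pixels")
  cs <- colSums(u)
  if (length(cs) && max(abs(cs - 1)) > 1e-9)
    msg <- c(msg, "membership columns must sum to 1 within 1e-9")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (length(object@labels) &&
      !identical(as.integer(object@labels),
                 as.integer(max.col(t(u), ties.method = "first"))))
    msg <- c(msg, "labels must equal the per-pixel argmax of membership")
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-8 * (1 + abs(tr[-length(tr)]))))
    msg <- c(msg, "objectiveTrace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve
#'
#' Operating points over all observed thresholds, trapezoidal AUC, and the
#' Youden-optimal cut-off with its sensitivity and specificity.
#'
#' @slot points data.frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}, sorted by threshold.
#' @slot auc numeric in [0, 1].
#' @slot youdenCutoff numeric, threshold maximising sensitivity +
#'   specificity - 1 (ties broken toward the lowest threshold).
#' @slot sensAtCutoff,specAtCutoff numeric, operating point at the cut-off.
#' @slot direction character, "cases_high" if cases score above controls,
#'   else "cases_low".
#'
#' @seealso [rocAnalysis()]
#' @export
setClass("ROCCurve",
  representation(
    points = "data.frame",
    auc = "numeric",
    youdenCutoff = "numeric",
    sensAtCutoff = "numeric",
    specAtCutoff = "numeric",
    direction = "character"
  )
)

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (!all(c("threshold", "sensitivity", "specificity") %in%
           names(object@points)))
    msg <- c(msg, "points must have threshold/sensitivity/specificity")
  th <- object@points$threshold
  if (is.unsorted(th[is.finite(th)]))
    msg <- c(msg, "points must be sorted by threshold")
  if (length(msg)) msg else TRUE
})
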