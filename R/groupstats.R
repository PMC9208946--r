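# ROI-level group comparison of zALFF between cases and controls:
# per-ROI mean extraction, two-sample tests, 2x2 chi-square, and empirical
# ROC discrimination with the Youden-optimal cut-off.

#' Mean zALFF per region of interest
#'
#' Averages the in-mask voxels of each ROI code. An ROI with no in-mask
#' voxels is flagged missing (mean NA), never silently zero.
#'
#' @param zalff a [ZALFFMap-class] (or [ALFFMap-class]).
#' @param roiLabels integer label array on the same grid; 0 = background.
#' @param roiNames optional named character vector or data.frame mapping
#'   label codes to region names (e.g. c(`1` = "R-STG")).
#' @return data.frame with columns roi (code), name, nVoxels, mean, missing.
#' @export
roiMeans <- function(zalff, roiLabels, roiNames = NULL) {
  stopifnot(is(zalff, "ALFFMap") || is(zalff, "ZALFFMap"))
  if (!identical(dim(mapValues(zalff)), dim(roiLabels)))
    stop("ROI label grid must match the map grid")
  codes <- sort(unique(as.integer(roiLabels)))
  codes <- codes[codes > 0L]
  if (!length(codes)) stop("no positive ROI codes in the label volume")
  vals <- mapValues(zalff)
  mask <- brainMask(zalff)
  res <- lapply(codes, function(k) {
    sel <- (as.integer(roiLabels) == k) & as.vector(mask)
    n <- sum(sel)
    data.frame(roi = k,
               name = if (!is.null(roiNames) &&
                          as.character(k) %in% names(roiNames))
                        unname(roiNames[[as.character(k)]])
                      else as.character(k),
               nVoxels = n,
               mean = if (n) mean(vals[sel]) else NA_real_,
               missing = n == 0L)
  })
  out <- do.call(rbind, res)
  if (all(out$missing))
    warning("no ROI overlaps the map mask")
  out
}

#' Two-sample t test on ROI summary values
#'
#' Welch (default) or pooled-variance two-sided t test. The degenerate case
#' of zero variance in both groups with equal means returns t = 0, p = 1;
#' zero variance with unequal means is flagged as an error.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param variant "welch" or "pooled".
#' @return list with t, p, df, and the group means.
#' @export
twoSampleT <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  meanA = mean(a), meanB = mean(b)))
    stop("both groups are constant with unequal means; t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), meanA = mean(a), meanB = mean(b))
}

#' Two-sample t test from printed group summaries
#'
#' Computes the t statistic and two-sided p-value directly from group means,
#' SDs and sizes — the form needed to check statistics reported in clinical
#' summary tables.
#'
#' @param mean1,sd1,n1 first group's summary.
#' @param mean2,sd2,n2 second group's summary.
#' @param variant "welch" (Satterthwaite df) or "pooled".
#' @return list with t, p, df.
#' @export
twoSampleTSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                              variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with chisq, p, df = 1.
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive")
  ht <- stats::chisq.test(table, correct = correct)
  list(chisq = unname(ht$statistic), p = ht$p.value, df = 1L)
}

#' Empirical ROC analysis of a diagnostic score
#'
#' Builds the empirical ROC over all distinct observed scores (predicting
#' "case" when the score is at or above the threshold in the cases-high
#' direction), computes the AUC by the trapezoidal rule — which equals the
#' Mann-Whitney proportion of correctly ordered case/control pairs with ties
#' counted half — and locates the Youden-optimal cut-off
#' (max sensitivity + specificity - 1; ties resolved toward the lowest
#' threshold). With \code{direction = "auto"} the direction is flipped when
#' controls score higher, so the reported AUC is always >= 0.5.
#'
#' @param cases,controls numeric score vectors (both non-empty).
#' @param direction "auto", "cases_high" or "cases_low".
#' @return a [ROCCurve-class].
#' @examples
#' roc <- rocAnalysis(c(2.5, 3.5, 4.5), c(1, 2, 3))
#' rocAUC(roc)    # 8/9
#' @export
rocAnalysis <- function(cases, controls,
                        direction = c("auto", "cases_high", "cases_low")) {
  direction <- match.arg(direction)
  if (!length(cases) || !length(controls))
    stop("both groups must be non-empty")
  if (!all(is.finite(c(cases, controls))))
    stop("scores must be finite")

  build <- function(cs, ct) {
    # cases-high convention: positive when score >= threshold
    th <- sort(unique(c(cs, ct)))
    sens <- vapply(th, function(t) mean(cs >= t), numeric(1))
    spec <- vapply(th, function(t) mean(ct < t), numeric(1))
    # closing points: threshold below all scores (sens 1, spec 0) and above
    th <- c(-Inf, th, Inf)
    sens <- c(1, sens, 0)
    spec <- c(0, spec, 1)
    fpr <- 1 - spec
    ord <- order(fpr, sens)  # integrate along the FPR axis
    auc <- sum(diff(fpr[ord]) * (utils::head(sens[ord], -1) +
                                 utils::tail(sens[ord], -1)) / 2)
    auc <- abs(auc)
    youden <- sens + spec - 1
    best <- which(youden == max(youden))[1L]  # lowest threshold on ties
    list(points = data.frame(threshold = th, sensitivity = sens,
                             specificity = spec),
         auc = auc, cut = th[best], sens = sens[best], spec = spec[best])
  }

  r <- build(cases, controls)
  dir <- "cases_high"
  if (direction == "cases_low" || (direction == "auto" && r$auc < 0.5)) {
    # flip the score axis: cases are called at or below the threshold
    rf <- build(-cases, -controls)
    r <- list(points = data.frame(threshold = rev(-rf$points$threshold),
                                  sensitivity = rev(rf$points$sensitivity),
                                  specificity = rev(rf$points$specificity)),
              auc = rf$auc, cut = -rf$cut, sens = rf$sens, spec = rf$spec)
    dir <- "cases_low"
  }
  new("ROCCurve", points = r$points, auc = r$auc, youdenCutoff = r$cut,
      sensAtCutoff = r$sens, specAtCutoff = r$spec, direction = dir)
}
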