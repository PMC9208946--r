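# Adaptive median filtering: the classical two-stage scheme in which the
# window grows per pixel until its median is not a local extreme, and the
# pixel is replaced only if it is itself a local extreme. Removes impulse
# (salt-and-pepper) noise while leaving uncorrupted pixels untouched.

padIndex <- function(n, p, border) {
  if (border == "reflect") c(p:1, seq_len(n), n:(n - p + 1))
  else c(rep(1L, p), seq_len(n), rep(n, p))
}

padArray <- function(img, p, border) {
  d <- dim(img)
  idx <- lapply(d, padIndex, p = p, border = border)
  do.call(`[`, c(list(img), idx, list(drop = FALSE)))
}

# Core n-dimensional adaptive median pass (used for 2D images and, with
# slicewise = FALSE, full 3D windows).
amfCore <- function(img, sInit, sMax, border) {
  d <- dim(img)
  nd <- length(d)
  p <- (sMax - 1L) %/% 2L
  P <- padArray(img, p, border)
  strides <- cumprod(c(1, dim(P)[-nd]))

  grid <- as.matrix(expand.grid(lapply(d, function(n) seq_len(n) + p)))
  lin0 <- as.vector(1 + (grid - 1) %*% strides)

  out <- as.vector(img)
  undecided <- rep(TRUE, length(out))

  for (s in seq(sInit, sMax, by = 2L)) {
    idx <- which(undecided)
    if (!length(idx)) break
    h <- (s - 1L) %/% 2L
    offs <- as.matrix(expand.grid(rep(list(-h:h), nd)))
    offLin <- as.vector(offs %*% strides)
    M <- matrix(P[outer(lin0[idx], offLin, `+`)],
                nrow = length(idx), ncol = length(offLin))
    md <- apply(M, 1L, stats::median)
    mn <- do.call(pmin, as.data.frame(M))
    mx <- do.call(pmax, as.data.frame(M))
    x <- out[idx]
    ok <- mn < md & md < mx            # stage A: median is not an extreme
    rep_px <- ok & !(mn < x & x < mx)  # stage B: replace only extreme pixels
    out[idx[rep_px]] <- md[rep_px]
    undecided[idx[ok]] <- FALSE
    if (s == sMax) out[idx[!ok]] <- md[!ok]
  }
  array(out, dim = d)
}

#' Adaptive median filter
#'
#' Two-stage adaptive median filtering. For every pixel the window grows from
#' \code{sInit} in steps of 2 until the window median is strictly between the
#' window minimum and maximum (stage A); the pixel is then replaced by that
#' median only if the pixel itself is a window extreme (stage B), otherwise
#' left unchanged. If the window reaches \code{sMax} while the median is
#' still an extreme, the median is output. Impulse pixels are thereby
#' removed while fine structure away from impulses is preserved, and the
#' output intensities are always observed input values (no new values are
#' invented).
#'
#' @param image numeric array, 2D or 3D.
#' @param sInit initial window edge length in pixels; odd, >= 3.
#' @param sMax maximum window edge length; odd, >= \code{sInit}. Every
#'   filtered axis must be at least \code{sMax} long.
#' @param border boundary handling: "reflect" (mirror, edge included) or
#'   "nearest" (edge replication).
#' @param slicewise for 3D input, filter each 2D slice along the third axis
#'   independently (the default, matching how displayed MR slices are
#'   processed); \code{FALSE} uses full cubic 3D windows.
#' @return Filtered array, same shape as the input.
#' @examples
#' img <- matrix(100, 9, 9); img[5, 5] <- 255
#' filt <- adaptiveMedianFilter(img, sInit = 3, sMax = 7)
#' filt[5, 5]  # impulse removed
#' @export
adaptiveMedianFilter <- function(image, sInit = 3L, sMax = 7L,
                                 border = c("reflect", "nearest"),
                                 slicewise = TRUE) {
  border <- match.arg(border)
  sInit <- as.integer(sInit); sMax <- as.integer(sMax)
  if (sInit %% 2L == 0L || sMax %% 2L == 0L)
    stop("window sizes must be odd")
  if (sInit < 3L || sMax < sInit)
    stop("window sizes must satisfy 3 <= sInit <= sMax")
  d <- dim(image)
  if (is.null(d) || length(d) < 2L || length(d) > 3L)
    stop("image must be a 2D or 3D array")

  if (length(d) == 3L && slicewise) {
    if (any(d[1:2] < sMax))
      stop("image in-plane dimensions must be at least sMax")
    out <- image
    for (z in seq_len(d[3]))
      out[, , z] <- amfCore(image[, , z, drop = TRUE], sInit, sMax, border)
    return(out)
  }
  if (any(d < sMax))
    stop("image dimensions must be at least sMax along every filtered axis")
  amfCore(image, sInit, sMax, border)
}
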