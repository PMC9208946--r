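# Independent oracles used across the suite. Deliberately brute-force and
# written without reference to the package internals they check.

# Direct DFT amplitude spectrum of one series: loops over explicit
# sum_t x_t exp(-2 pi i k t / n); returns one-sided amplitudes (2|X_k|/n)
# and their frequencies in Hz.
dftAmplitudeOracle <- function(x, tr) {
  n <- length(x)
  ks <- seq_len(floor(n / 2))
  amp <- vapply(ks, function(k) {
    t <- 0:(n - 1)
    re <- sum(x * cos(-2 * pi * k * t / n))
    im <- sum(x * sin(-2 * pi * k * t / n))
    2 * sqrt(re^2 + im^2) / n
  }, numeric(1))
  data.frame(freq = ks / (n * tr), amp = amp)
}

# Mann-Whitney AUC: exhaustive comparison of every case/control pair,
# ties counted half.
mwAUCOracle <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Brute-force Youden cut-off: scan every candidate threshold (all observed
# scores), cases called at or above threshold; lowest threshold wins ties.
youdenOracle <- function(cases, controls) {
  th <- sort(unique(c(cases, controls, -Inf, Inf)))
  j <- vapply(th, function(t)
    mean(cases >= t) + mean(controls < t) - 1, numeric(1))
  th[which(j == max(j))[1]]
}

# FCM objective at the optimal memberships for m = 2, in closed form:
# J(c) = sum_k (sum_i d_ik^-2)^-1 (points hitting a centre contribute 0).
fcmOptimalJOracle <- function(x, centers) {
  d2 <- outer(x, centers, `-`)^2
  sum(apply(d2, 1, function(r) {
    if (any(r == 0)) 0 else 1 / sum(1 / r)
  }))
}

# Exhaustive grid search for the best pair of centres of a 1D 2-cluster
# problem under the m = 2 FCM objective.
gridBestPairOracle <- function(x, step = 0.5) {
  g <- seq(min(x), max(x), by = step)
  best <- c(NA, NA); bestJ <- Inf
  for (i in seq_along(g)) for (j in seq_len(i - 1)) {
    J <- fcmOptimalJOracle(x, c(g[i], g[j]))
    if (J < bestJ) { bestJ <- J; best <- sort(c(g[i], g[j])) }
  }
  best
}

# Literal per-pixel adaptive median filter (reflect borders), nested loops.
amfReferenceOracle <- function(img, sInit = 3, sMax = 7) {
  d <- dim(img)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- img
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    s <- sInit
    repeat {
      h <- (s - 1) / 2
      w <- img[cbind(
        rep(reflect((r - h):(r + h), d[1]), times = s),
        rep(reflect((c - h):(c + h), d[2]), each = s))]
      md <- stats::median(w); mn <- min(w); mx <- max(w)
      if (mn < md && md < mx) {
        x <- img[r, c]
        out[r, c] <- if (mn < x && x < mx) x else md
        break
      }
      if (s >= sMax) { out[r, c] <- md; break }
      s <- s + 2
    }
  }
  out
}

# Midpoint-threshold labelling of a 2-class image: the segmentation oracle
# for noiseless or lightly corrupted 2-class phantoms.
thresholdOracle <- function(img, means) {
  array(ifelse(img < mean(means), 1L, 2L), dim = dim(img))
}

# Small 2-class phantom shared by denoising tests.
twoClassPhantom <- function(shape = c(64, 64), means = c(50, 200), sd = 0,
                            seed = 11) {
  generateTissuePhantom(shape, means, sd, seed = seed)
}
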