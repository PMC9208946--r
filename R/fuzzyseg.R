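# Fuzzy C-means (FCM) segmentation on image intensity, with cluster centres
# initialised by particle swarm optimisation (PSO), hard labels by argmax
# defuzzification, and Jaccard evaluation against ground truth.
#
# Clustering operates on the 1D intensity feature: the membership update is
# u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)), the centre update the u^m-weighted
# mean, and the objective J_m = sum_ik u_ik^m (x_k - c_i)^2 (Bezdek updates
# with fuzzifier m). Defaults m = 2, T = 100 iterations, tolerance 1e-4.

#' Fuzzy C-means objective
#'
#' The fuzzified within-cluster sum of squared distances
#' \eqn{J_m = \sum_i \sum_k u_{ik}^m (x_k - c_i)^2}.
#'
#' @param x numeric vector of data values (e.g. pixel intensities).
#' @param centers numeric vector of C cluster centres.
#' @param membership C x N membership matrix.
#' @param m fuzzifier exponent, > 1.
#' @return non-negative scalar J.
#' @export
fcmObjective <- function(x, centers, membership, m = 2) {
  if (!is.matrix(membership) || nrow(membership) != length(centers) ||
      ncol(membership) != length(x))
    stop("membership must be a length(centers) x length(x) matrix")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  D2 <- outer(centers, x, `-`)^2
  sum(membership^m * D2)
}

#' Update fuzzy memberships for fixed centres
#'
#' Standard fuzzifier-m update: \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}}
#' with \eqn{d_{ik} = |x_k - c_i|}. A point within \code{zeroDistanceEps} of
#' one or more centres receives membership 1 split equally among those centres
#' and 0 elsewhere (the formula otherwise divides by zero).
#'
#' @inheritParams fcmObjective
#' @param zeroDistanceEps snap radius for coincident point/centre pairs.
#' @return C x N membership matrix; every column sums to 1.
#' @export
updateMembership <- function(x, centers, m = 2, zeroDistanceEps = 1e-12) {
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (length(centers) > 1 && diff(range(centers)) <= zeroDistanceEps)
    stop("all cluster centers are identical; memberships are undefined")
  d <- abs(outer(centers, x, `-`))
  snap <- d <= zeroDistanceEps
  pw <- d^(-2 / (m - 1))
  u <- sweep(pw, 2L, colSums(pw), `/`)
  zc <- which(colSums(snap) > 0L)
  if (length(zc)) {
    z <- snap[, zc, drop = FALSE]
    u[, zc] <- sweep(z * 1, 2L, colSums(z), `/`)
  }
  u
}

#' Update cluster centres for fixed memberships
#'
#' Each centre is the \eqn{u^m}-weighted mean of the data:
#' \eqn{c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}.
#'
#' @inheritParams fcmObjective
#' @return numeric vector of C updated centres.
#' @export
updateCenters <- function(x, membership, m = 2) {
  if (m <= 1) stop("fuzzifier m must exceed 1")
  w <- membership^m
  mass <- rowSums(w)
  if (any(mass == 0))
    stop("cluster(s) ", paste(which(mass == 0), collapse = ", "),
         " have zero total membership mass")
  as.vector((w %*% x) / mass)
}

# Fitness of a candidate centre vector: the FCM objective at the memberships
# those centres imply. Degenerate particles (all centres coincident) score Inf.
fcmFitness <- function(x, centers, m, zeroDistanceEps = 1e-12) {
  if (length(centers) > 1 && diff(range(centers)) <= zeroDistanceEps)
    return(Inf)
  u <- updateMembership(x, centers, m, zeroDistanceEps)
  fcmObjective(x, centers, u, m)
}

#' Choose FCM initial centres by particle swarm optimisation
#'
#' Each particle is a candidate vector of C centres; its fitness is the FCM
#' objective at the memberships those centres imply. Velocities and positions
#' follow the standard update
#' \eqn{v \leftarrow w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)};
#' positions are clamped to the data range. The global best is returned after
#' \code{nIter} iterations; its fitness trace (non-increasing by construction)
#' is attached as attribute \code{"fitnessTrace"}.
#'
#' @param x numeric data vector with at least C distinct values.
#' @param C number of clusters.
#' @param m fuzzifier used in the fitness.
#' @param nParticles swarm size (>= 1; >= 2 for a meaningful swarm).
#' @param nIter PSO iterations.
#' @param inertia,cognitive,social PSO hyperparameters w, c1, c2 (all > 0);
#'   defaults are the canonical constriction-equivalent values 0.72, 1.49,
#'   1.49.
#' @param seed integer RNG seed.
#' @param initialPositions optional nParticles x C matrix of starting centre
#'   vectors (default: uniform draws over the data range).
#' @return numeric vector of C centres, sorted ascending, with attribute
#'   \code{"fitnessTrace"}.
#' @export
psoInitCenters <- function(x, C, m = 2, nParticles = 20L, nIter = 50L,
                           inertia = 0.72, cognitive = 1.49, social = 1.49,
                           seed = 1L, initialPositions = NULL) {
  C <- as.integer(C)
  if (length(unique(x)) < C)
    stop("number of clusters C exceeds the number of distinct data values")
  if (inertia <= 0 || cognitive <= 0 || social <= 0)
    stop("inertia, cognitive and social weights must be positive")
  rng <- range(x)
  withSeed(seed, {
    pos <- if (is.null(initialPositions)) {
      matrix(stats::runif(nParticles * C, rng[1], rng[2]),
             nrow = nParticles, ncol = C)
    } else {
      stopifnot(ncol(initialPositions) == C,
                nrow(initialPositions) == nParticles)
      as.matrix(initialPositions)
    }
    vel <- matrix(0, nrow = nParticles, ncol = C)
    fit <- apply(pos, 1L, fcmFitness, x = x, m = m)
    pbest <- pos
    pbestFit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]
    gbestFit <- fit[g]
    trace <- numeric(nIter)

    for (it in seq_len(nIter)) {
      r1 <- matrix(stats::runif(nParticles * C), nParticles)
      r2 <- matrix(stats::runif(nParticles * C), nParticles)
      vel <- inertia * vel +
        cognitive * r1 * (pbest - pos) +
        social * r2 * (sweep(pos, 2L, gbest, `-`) * -1)
      pos <- pos + vel
      pos[pos < rng[1]] <- rng[1]
      pos[pos > rng[2]] <- rng[2]
      fit <- apply(pos, 1L, fcmFitness, x = x, m = m)
      improved <- fit < pbestFit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbestFit[improved] <- fit[improved]
      if (min(pbestFit) < gbestFit) {
        g <- which.min(pbestFit)
        gbest <- pbest[g, ]
        gbestFit <- pbestFit[g]
      }
      trace[it] <- gbestFit
    }
    structure(sort(gbest), fitnessTrace = trace)
  })
}

#' Convert a membership matrix to hard labels
#'
#' Per-element argmax over clusters; ties are broken toward the lowest
#' cluster index.
#'
#' @param membership C x N membership matrix.
#' @param dim optional dimensions to reshape the label vector into an array.
#' @return integer labels in 1..C (vector, or array if \code{dim} is given).
#' @export
defuzzify <- function(membership, dim = NULL) {
  lab <- as.integer(max.col(t(membership), ties.method = "first"))
  if (!is.null(dim)) lab <- array(lab, dim = dim)
  lab
}

#' Segment an image by fuzzy C-means
#'
#' Alternates the membership and centre updates from a chosen initialisation
#' until the monitored quantity falls below \code{tol} or \code{maxIter}
#' sweeps have run. By default convergence is declared on the maximum
#' absolute centre displacement; \code{monitor = "objective"} uses the change
#' in J instead. With \code{relabel = TRUE} clusters are sorted by ascending
#' centre intensity, so on T1-like contrast label 1 is CSF-like, the last
#' label WM-like.
#'
#' @param image numeric array (or vector) of intensities.
#' @param C number of clusters (>= 2).
#' @param m fuzzifier (> 1); default 2.
#' @param maxIter iteration cap T; default 100.
#' @param tol termination tolerance epsilon; default 1e-4.
#' @param init "pso" (default), "random" (C distinct data values), or
#'   "given" (supply \code{centers}).
#' @param centers initial centres when \code{init = "given"}.
#' @param seed RNG seed for PSO or random initialisation.
#' @param monitor "centers" or "objective" — the quantity compared to
#'   \code{tol}.
#' @param zeroDistanceEps snap radius passed to [updateMembership()].
#' @param relabel sort clusters by ascending centre intensity (default TRUE;
#'   set FALSE to keep the initialisation's cluster order).
#' @param psoControl named list of overrides passed to [psoInitCenters()]
#'   (nParticles, nIter, inertia, cognitive, social).
#' @return A [FuzzySegmentation-class] object.
#' @examples
#' ph <- generateTissuePhantom(c(32, 32), c(40, 200), tissueSd = 4)
#' seg <- fcmSegment(phantomImage(ph), C = 2, init = "pso", seed = 7)
#' mean(labelMap(seg) == trueLabels(ph))
#' @export
fcmSegment <- function(image, C = 3L, m = 2, maxIter = 100L, tol = 1e-4,
                       init = c("pso", "random", "given"), centers = NULL,
                       seed = 1L, monitor = c("centers", "objective"),
                       zeroDistanceEps = 1e-12, relabel = TRUE,
                       psoControl = list()) {
  init <- match.arg(init)
  monitor <- match.arg(monitor)
  C <- as.integer(C)
  if (C < 2L) stop("C must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (maxIter < 1L) stop("maxIter must be at least 1")
  if (tol <= 0) stop("tol must be positive")
  x <- as.numeric(image)
  if (!all(is.finite(x))) stop("image must be finite-valued")
  dims <- if (is.null(dim(image))) length(x) else dim(image)

  cen <- switch(init,
    pso = as.numeric(do.call(psoInitCenters,
      c(list(x = x, C = C, m = m, seed = seed), psoControl))),
    random = withSeed(seed, sample(unique(x), C)),
    given = {
      if (is.null(centers) || length(centers) != C)
        stop("init = \"given\" requires a length-C centers vector")
      as.numeric(centers)
    })

  trace <- numeric(0)
  converged <- FALSE
  jPrev <- Inf
  nIter <- 0L
  for (it in seq_len(maxIter)) {
    u <- updateMembership(x, cen, m, zeroDistanceEps)
    newCen <- updateCenters(x, u, m)
    j <- fcmObjective(x, newCen, u, m)
    trace <- c(trace, j)
    nIter <- it
    delta <- if (monitor == "centers") max(abs(newCen - cen))
             else abs(jPrev - j)
    cen <- newCen
    jPrev <- j
    if (delta < tol) { converged <- TRUE; break }
  }
  u <- updateMembership(x, cen, m, zeroDistanceEps)

  if (relabel) {
    ord <- order(cen)
    cen <- cen[ord]
    u <- u[ord, , drop = FALSE]
  }
  labels <- array(defuzzify(u), dim = dims)

  new("FuzzySegmentation", labels = labels, membership = u,
      centers = cen, objectiveTrace = trace, nIter = nIter,
      converged = converged, init = init)
}

#' Jaccard similarity between two region masks
#'
#' \eqn{JS = |S_1 \cap S_2| / |S_1 \cup S_2|}, where \eqn{S_1} is the
#' segmented region and \eqn{S_2} the ground truth. Returns 1 when both masks
#' are empty (the union is empty, so the regions agree vacuously).
#'
#' @param s1,s2 logical arrays of identical shape.
#' @return scalar in [0, 1].
#' @export
jaccardSimilarity <- function(s1, s2) {
  if (!identical(dim(s1), dim(s2)) || length(s1) != length(s2))
    stop("region masks must have identical shape")
  s1 <- as.logical(s1); s2 <- as.logical(s2)
  uni <- sum(s1 | s2)
  if (uni == 0L) return(1)
  sum(s1 & s2) / uni
}

# All permutations of a vector (for label matching; C is small).
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(allPerms(v[-i]), function(p) c(v[i], p)))
  out
}

#' Per-class Jaccard similarity of a segmentation against truth
#'
#' @param labels integer label array from a segmentation.
#' @param truth integer ground-truth label array, same shape.
#' @param matchLabels if TRUE, search all label permutations and score the
#'   one maximising the mean Jaccard (useful when cluster order is not
#'   canonical); otherwise labels are compared code-for-code.
#' @return named numeric vector, one Jaccard value per truth class.
#' @export
perClassJaccard <- function(labels, truth, matchLabels = FALSE) {
  if (!identical(dim(labels), dim(truth)))
    stop("label arrays must have identical shape")
  truthInt <- as.integer(truth)
  classes <- sort(unique(truthInt))
  score <- function(lab) {
    vapply(classes, function(k)
      jaccardSimilarity(lab == k, truthInt == k), numeric(1))
  }
  if (!matchLabels) {
    js <- score(as.integer(labels))
  } else {
    best <- -Inf
    js <- NULL
    for (p in allPerms(classes)) {
      relab <- p[match(as.integer(labels), classes)]
      s <- score(relab)
      if (mean(s) > best) { best <- mean(s); js <- s }
    }
  }
  names(js) <- classes
  js
}
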