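test_that("FCM objective matches hand-computed sums", {
  # crisp assignment with every point at a centre
  u <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(fcmObjective(c(0, 10), c(0, 10), u, m = 2), 0)
  # single centre at 5, full membership: 25 + 25
  expect_equal(fcmObjective(c(0, 10), 5, matrix(1, 1, 2), m = 2), 50)
  expect_error(fcmObjective(c(0, 10), 5, matrix(1, 2, 2)), "matrix")
  expect_error(fcmObjective(c(0, 10), 5, matrix(1, 1, 2), m = 1), "m")
})

test_that("membership update follows the fuzzifier formula exactly", {
  # point 2 between centres {0, 10}, m = 2: u_near = 1/(1 + (2/8)^2) = 16/17
  u <- updateMembership(2, c(0, 10), m = 2)
  expect_equal(u[1, 1], 16 / 17, tolerance = 1e-12)
  expect_equal(u[2, 1], 1 / 17, tolerance = 1e-12)
  # point at a centre: crisp membership there
  u0 <- updateMembership(c(0, 5), c(0, 10), m = 2)
  expect_equal(u0[, 1], c(1, 0))
  expect_equal(u0[, 2], c(0.5, 0.5))  # equidistant: symmetric split
  # columns always sum to one
  set.seed(5)
  x <- runif(100, 0, 255)
  uu <- updateMembership(x, c(10, 90, 200), m = 2)
  expect_true(max(abs(colSums(uu) - 1)) < 1e-9)
  expect_true(all(uu >= 0 & uu <= 1))
  expect_error(updateMembership(x, c(5, 5, 5)), "identical")
})

test_that("centre update is the u^m-weighted mean", {
  x <- c(0, 2, 10, 12)
  crisp <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(updateCenters(x, crisp, m = 2), c(1, 11))
  half <- matrix(0.5, 2, 4)
  expect_equal(updateCenters(x, half, m = 2), c(6, 6))  # global mean twice
  expect_equal(updateCenters(5, matrix(1, 1, 1), m = 2), 5)
  expect_error(updateCenters(x, rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))),
               "zero total membership")
})

test_that("PSO initialisation honours its fixed points and monotone gbest", {
  # a lone particle resting at the optimum of a 1-cluster problem stays put
  x <- c(4, 4, 4, 6, 6, 6)
  cen <- psoInitCenters(x, C = 1, nParticles = 1, nIter = 20, seed = 1,
                        initialPositions = matrix(5, 1, 1))
  expect_equal(as.numeric(cen), 5)
  # gbest fitness trace is non-increasing by definition
  set.seed(13)
  y <- c(rnorm(100, 0), rnorm(100, 100))
  cen2 <- psoInitCenters(y, C = 2, seed = 2)
  tr <- attr(cen2, "fitnessTrace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_error(psoInitCenters(c(1, 1, 1), C = 2), "distinct")
})

test_that("PSO finds the blob centres of well-separated 1D data", {
  set.seed(99)
  x <- c(rnorm(200, 0, 1), rnorm(200, 100, 1))
  cen <- as.numeric(psoInitCenters(x, C = 2, seed = 31))
  oracle <- gridBestPairOracle(x, step = 0.5)
  expect_lt(abs(cen[1] - 0), 1.0)
  expect_lt(abs(cen[2] - 100), 1.0)
  expect_lt(abs(cen[1] - oracle[1]), 1.0)
  expect_lt(abs(cen[2] - oracle[2]), 1.0)
})

test_that("defuzzification is argmax with lowest-index tie breaking", {
  expect_identical(defuzzify(rbind(c(1, 0), c(0, 1))), c(1L, 2L))
  expect_identical(defuzzify(matrix(c(0.5, 0.5), 2, 1)), 1L)
  expect_identical(defuzzify(matrix(c(0.2, 0.3, 0.5), 3, 1)), 3L)
  expect_identical(dim(defuzzify(matrix(0.5, 2, 4), dim = c(2, 2))),
                   c(2L, 2L))
})

test_that("segmentation reproduces the threshold oracle on a clean phantom", {
  ph <- generateTissuePhantom(c(64, 64), c(40, 200), 0, seed = 2)
  seg <- fcmSegment(phantomImage(ph), C = 2, m = 2, maxIter = 100,
                    tol = 1e-4, init = "pso", seed = 5)
  oracle <- thresholdOracle(phantomImage(ph), c(40, 200))
  expect_identical(labelMap(seg), oracle)
  expect_equal(unname(perClassJaccard(labelMap(seg), trueLabels(ph))),
               c(1, 1))
  expect_true(isConverged(seg))
})

test_that("iteration cap and convergence flags behave as contracted", {
  ph <- generateTissuePhantom(c(32, 32), c(20, 120, 220), 10, seed = 3)
  seg1 <- fcmSegment(phantomImage(ph), C = 3, maxIter = 1, init = "random",
                     seed = 1)
  expect_identical(nIterations(seg1), 1L)
  expect_false(isConverged(seg1))
  expect_length(objectiveTrace(seg1), 1L)
})

test_that("membership columns sum to 1 and J is non-increasing every run", {
  for (s in 1:5) {
    set.seed(s)
    x <- runif(150, 0, 255)
    seg <- fcmSegment(x, C = 3, init = "random", seed = s)
    expect_true(max(abs(colSums(membershipMatrix(seg)) - 1)) < 1e-9)
    tr <- objectiveTrace(seg)
    expect_true(all(diff(tr) <= 1e-8 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("permuting given initial centres only permutes the labels", {
  ph <- generateTissuePhantom(c(32, 32), c(20, 120, 220), 5, seed = 8)
  a <- fcmSegment(phantomImage(ph), C = 3, init = "given",
                  centers = c(10, 100, 240), relabel = FALSE)
  b <- fcmSegment(phantomImage(ph), C = 3, init = "given",
                  centers = c(240, 10, 100), relabel = FALSE)
  expect_equal(sort(clusterCenters(a)), sort(clusterCenters(b)))
  # the permutation mapping a's clusters onto b's
  perm <- match(round(clusterCenters(a), 6), round(clusterCenters(b), 6))
  expect_identical(array(perm[labelMap(a)], dim = dim(labelMap(a))),
                   labelMap(b))
})

test_that("defuzzified labels agree with a matched k-means oracle", {
  ph <- generateTissuePhantom(c(64, 64), c(20, 120, 220), 5, seed = 6)
  seg <- fcmSegment(phantomImage(ph), C = 3, init = "pso", seed = 6)
  km <- stats::kmeans(as.vector(phantomImage(ph)),
                      centers = sort(clusterCenters(seg)))
  agree <- mean(as.vector(labelMap(seg)) == km$cluster)
  expect_gte(agree, 0.99)
})

test_that("FCM centres agree with the e1071 reference implementation", {
  set.seed(10)
  x <- c(rnorm(150, 30, 5), rnorm(150, 150, 5))
  seg <- fcmSegment(x, C = 2, init = "given", centers = c(0, 255))
  ref <- e1071::cmeans(matrix(x), centers = matrix(c(0, 255)), m = 2)
  expect_equal(sort(clusterCenters(seg)), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})

test_that("Jaccard similarity follows the set definition", {
  a <- matrix(FALSE, 3, 3); b <- matrix(FALSE, 3, 3)
  a[1:2, ] <- TRUE          # 6 pixels
  b[2:3, ] <- TRUE          # 6 pixels; intersection row 2 = 3; union = 9
  expect_equal(jaccardSimilarity(a, b), 1 / 3)
  expect_equal(jaccardSimilarity(a, a), 1)
  expect_equal(jaccardSimilarity(a, !a), 0)
  expect_equal(jaccardSimilarity(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               1)
  expect_error(jaccardSimilarity(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape")
})
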