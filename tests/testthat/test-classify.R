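# well-separated Gaussian blobs in 3D feature space
makeBlobs <- function(n_per = c(120, 100, 40), centers = NULL, sd = 0.1,
                      seed = 71) {
  if (is.null(centers))
    centers <- rbind(c(-5, 0, 0), c(0, 5, 0), c(5, 0, 5))
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(n_per), function(j)
    cbind(rnorm(n_per[j], centers[j, 1], sd),
          rnorm(n_per[j], centers[j, 2], sd),
          rnorm(n_per[j], centers[j, 3], sd))))
  colnames(X) <- c("d1n", "d2n", "d3n")
  list(X = X, truth = rep(seq_along(n_per), n_per), centers = centers)
}

test_that("k-medoids recovers well-separated blobs and matches cluster::pam", {
  b <- makeBlobs()
  fit <- fitKmedoids(b$X, k = 3, seed = 1, n_restarts = 10)
  # partition identical to a nearest-true-center oracle
  d2c <- sapply(1:3, function(j) rowSums(sweep(b$X, 2, b$centers[j, ])^2))
  oracle <- max.col(-d2c)
  expect_equal(length(unique(paste(fit@assignment, oracle))), 3L)
  # same seed twice: identical medoids; distinct points requirement enforced
  fit2 <- fitKmedoids(b$X, k = 3, seed = 1, n_restarts = 10)
  expect_identical(fit@medoids, fit2@medoids)
  expect_error(fitKmedoids(b$X[c(1, 1, 1), ], k = 3), "distinct")
  # independent build+swap implementation agrees on the objective
  pam_fit <- cluster::pam(b$X, 3)
  expect_equal(totalDistance(fit),
               sum(pam_fit$clusinfo[, "av_diss"] * pam_fit$clusinfo[, "size"]),
               tolerance = 1e-6)
  # all points identical at k = 1: zero total distance
  same <- matrix(1, 20, 3, dimnames = list(NULL, colnames(b$X)))
  f1 <- fitKmedoids(same, k = 1, seed = 1)
  expect_equal(totalDistance(f1), 0)
})

test_that("semantic labels follow the d3-then-d1 ordering rule", {
  b <- makeBlobs(centers = rbind(c(-1, 0.5, 0.3),   # AC: low d1
                                 c(0.7, -0.7, -0.5),  # CCP
                                 c(1, 1.5, 3)))       # OT: high d3
  fit <- labelClusters(fitKmedoids(b$X, k = 3, seed = 2, n_restarts = 10), b$X)
  lm <- labelMap(fit)
  maj <- function(cl) names(which.max(table(b$truth[fit@assignment == cl])))
  expect_equal(lm[fit@assignment[1]], "AC")      # blob 1 points labeled AC
  expect_equal(unname(lm[as.integer(maj(which(lm == "OT")))] != "x"), TRUE)
  # majority composition agrees with the semantic rule
  expect_equal(maj(which(lm == "AC")), "1")
  expect_equal(maj(which(lm == "CCP")), "2")
  expect_equal(maj(which(lm == "OT")), "3")
  # flipping the d1 sign swaps AC and CCP labels consistently
  Xf <- b$X; Xf[, 1] <- -Xf[, 1]
  fitf <- labelClusters(fitKmedoids(Xf, k = 3, seed = 2, n_restarts = 10), Xf)
  lmf <- labelMap(fitf)
  expect_equal(maj2 <- names(which.max(table(b$truth[assignTraces(fitf, Xf) == "AC"]))), "2")
  # exact ties in the ordering statistic demand manual labels
  Xt <- rbind(matrix(c(0, 0, 1), 5, 3, byrow = TRUE),
              matrix(c(3, 0, 1), 5, 3, byrow = TRUE),
              matrix(c(6, 0, 1), 5, 3, byrow = TRUE))
  colnames(Xt) <- colnames(b$X)
  ft <- fitKmedoids(Xt, k = 3, seed = 1)
  expect_error(labelClusters(ft, Xt), "tie")
  expect_error(labelClusters(fitKmedoids(b$X, k = 2, seed = 1), b$X), "k = 3")
})

test_that("assignment is idempotent, deterministic, and tie-broken low", {
  b <- makeBlobs()
  fit <- fitKmedoids(b$X, k = 3, seed = 1, n_restarts = 10)
  a1 <- assignTraces(fit, b$X)
  expect_identical(a1, fit@assignment)         # self-assignment = fit partition
  expect_identical(a1, assignTraces(fit, b$X))
  # a point equidistant from two medoids goes to the lower cluster index
  mid <- (fit@medoids[1, ] + fit@medoids[2, ]) / 2
  # place the midpoint exactly between medoids 1 and 2
  expect_equal(assignTraces(fit, rbind(mid)), 1L)
})

test_that("elbow analysis finds k = 3 for three blobs with monotone distance", {
  b <- makeBlobs(n_per = c(150, 130, 120), sd = 0.15)
  eb <- elbowAnalysis(b$X, k_range = 1:7, seed = 3, n_restarts = 5)
  expect_equal(eb$optimal_k, 3L)
  expect_true(all(diff(eb$total_distance) <= 1e-9))
  expect_gt(eb$elbow_strength, 0.2)
  # a single blob yields a weak elbow signal
  one <- makeBlobs(n_per = c(400, 0, 0), sd = 1)
  eb1 <- elbowAnalysis(one$X, k_range = 1:7, seed = 3, n_restarts = 5)
  expect_lt(eb1$elbow_strength, eb$elbow_strength)
  expect_error(elbowAnalysis(b$X, k_range = 1:2), "at least 3")
})

test_that("edge traces sit near the AC/CCP midplane and preserve shifts", {
  b <- makeBlobs(centers = rbind(c(-1, 0.5, 0), c(0.8, -0.8, 0), c(1, 1, 4)),
                 n_per = c(400, 400, 80), sd = 0.5, seed = 72)
  fit <- labelClusters(fitKmedoids(b$X, k = 3, seed = 1, n_restarts = 10), b$X)
  ed <- findEdgeTraces(fit, b$X, fraction = 0.10)
  pool <- ed$categories %in% c("AC", "CCP")
  expect_equal(sum(ed$edge), round(0.10 * sum(pool)))
  expect_true(all(!ed$edge[!pool]))            # OTs never flagged
  # flagged traces have the smallest distance asymmetry in the pool
  d <- sqrt(dascr:::.dist_to(b$X, fit@medoids))
  iac <- which(labelMap(fit) == "AC"); iccp <- which(labelMap(fit) == "CCP")
  asym <- abs(d[, iac] - d[, iccp])
  expect_lt(max(asym[ed$edge]), min(asym[pool & !ed$edge]) + 1e-9)
  expect_error(findEdgeTraces(fit, b$X, fraction = 1.2), "fraction")
})

test_that("models serialize to JSON and restore", {
  b <- makeBlobs()
  fit <- labelClusters(fitKmedoids(b$X, k = 3, seed = 1, n_restarts = 5), b$X)
  path <- tempfile(fileext = ".json")
  writeDasModel(fit, path)
  back <- readDasModel(path)
  expect_equal(back@medoids, fit@medoids, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(labelMap(back), labelMap(fit))
  expect_identical(assignTraces(back, b$X), assignTraces(fit, b$X))
})
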