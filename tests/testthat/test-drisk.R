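test_that("quantization rounds half-up, clamps at 1, tracks imax", {
  ts <- makeTraceSet(list(c(2.4, 7.5, 7.49), c(0.3, 0.01, 1.2),
                          c(12.6, 3.3, 1.9)))
  q <- quantizeTraces(ts)
  expect_equal(as.integer(states(q)[[1]]), c(2L, 8L, 7L))
  expect_equal(as.integer(states(q)[[2]]), c(1L, 1L, 1L))
  expect_equal(imax(q), 13L)
  # non-finite intensities are rejected at container construction
  expect_error(makeTraceSet(list(c(1, NaN, 2))), "non-finite")
})

test_that("transition masses match hand-counted fractions on tiny fixtures", {
  # four hand-built chains of <= 5 frames
  chains <- list(c(2L, 3L, 2L, 2L), c(2L, 1L, 2L), c(3L, 3L, 2L, 4L, 1L),
                 c(2L, 2L, 2L, 2L))
  ts <- makeTraceSet(lapply(chains, as.numeric))
  map <- suppressWarnings(estimateTransitions(quantizeTraces(ts)))
  # t=1: states 2,2,3,2; transitions 2->3 (up), 2->1 (down), 3->3, 2->2
  expect_equal(map@downMass[2, 1], 1 / 3)       # one of three traces at (2,1) drops
  expect_equal(map@downMass[3, 1], 0)
  expect_equal(map@upMass[3, 1], 1 / 3)         # 2->3 out of N(2,1)=3
  # t=2: states 3,1,3,2; transitions 3->2, 1->2, 3->2, 2->2
  expect_equal(map@downMass[3, 2], 1)           # both traces at (3,2) drop
  expect_equal(map@upMass[2, 2], 1)             # 1->2 out of N(1,2)=1
  expect_error(estimateTransitions(
    quantizeTraces(makeTraceSet(list(c(1, 2)))[integer(0)])), "empty")
})

test_that("vectorized W/D equals the brute-force enumeration oracle exactly", {
  set.seed(41)
  n <- 80
  chains <- replicate(n, {
    len <- sample(3:20, 1)
    pmax(1L, as.integer(round(cumsum(c(sample(1:6, 1),
                                       rnorm(len - 1, 0.3, 1.2))))))
  }, simplify = FALSE)
  ts <- makeTraceSet(lapply(chains, as.numeric))
  q <- quantizeTraces(ts)
  map <- suppressWarnings(estimateTransitions(q))
  orc <- oracleRiskMap(lapply(states(q), as.integer), imax(q), map@tmax)
  expect_equal(unname(map@N), orc$N)
  expect_equal(unname(map@downMass), orc$down)
  expect_equal(unname(map@upMass), orc$up, tolerance = 1e-12)
  # D with epsilon = 0 must equal the oracle log-ratio wherever finite
  mapD <- computeD(map, epsilon = 0, min_count = 1L)
  orcD <- log(orc$down) - log(orc$up)
  orcD[!is.finite(orcD)] <- NA_real_
  orcD[1, ] <- 0
  expect_equal(unname(mapD@D), orcD, tolerance = 1e-12)
})

test_that("pure growth gives negative D; detailed balance gives D near 0", {
  # all transitions upward, at two different rates so that arrivals land in
  # occupied cells: net risk must be non-positive everywhere and strictly
  # negative where gain flux is observed
  chains <- c(replicate(30, as.numeric(1:8), simplify = FALSE),
              replicate(30, as.numeric(ceiling((1:8) / 2)), simplify = FALSE))
  mapg <- computeD(suppressWarnings(
    estimateTransitions(quantizeTraces(makeTraceSet(chains)))),
    min_count = 5L)
  Dg <- mapg@D[-1, ]
  expect_true(all(Dg[!is.na(Dg)] <= 0))
  expect_true(any(Dg[!is.na(Dg)] < 0))
  # symmetric +/-1 random walk between reflecting states 1..5 (stationary):
  # mean |D| over defined interior cells shrinks with sample size
  sim_walk <- function(n_traces, len, seed) {
    set.seed(seed)
    chains <- replicate(n_traces, {
      s <- integer(len); s[1] <- sample(1:5, 1)
      for (t in 2:len) {
        prop <- s[t - 1] + sample(c(-1L, 1L), 1)
        s[t] <- if (prop >= 1 && prop <= 5) prop else s[t - 1]
      }
      as.numeric(s)
    }, simplify = FALSE)
    map <- computeD(suppressWarnings(
      estimateTransitions(quantizeTraces(makeTraceSet(chains)))),
      min_count = 10L)
    D <- map@D[2:5, ]
    mean(abs(D[!is.na(D)]))
  }
  m_small <- sim_walk(250, 20, 7)    # ~5e3 transitions
  m_large <- sim_walk(5000, 20, 7)   # ~1e5 transitions
  expect_lt(m_large, 0.05)
  expect_lt(m_large, m_small)
})

test_that("D conventions: bottom row zero, sparse cells undefined", {
  chains <- replicate(30, as.numeric(c(1, 2, 3, 2, 1)), simplify = FALSE)
  map <- computeD(suppressWarnings(
    estimateTransitions(quantizeTraces(makeTraceSet(chains)))))
  expect_equal(unname(map@D[1, ]), rep(0, map@tmax))
  expect_true(all(is.na(map@D[2:3, ][map@N[2:3, ] < 5])))
})

test_that("projection starts at zero and falls back to nearest defined state", {
  chains <- c(replicate(30, as.numeric(c(2, 3, 4, 3, 2)), simplify = FALSE),
              list(as.numeric(c(2, 9, 4, 3, 2))))  # state 9 visited once
  ts <- makeTraceSet(chains)
  q <- quantizeTraces(ts)
  map <- computeD(suppressWarnings(estimateTransitions(q)), min_count = 5L)
  pr <- projectTraces(map, q)
  expect_true(all(vapply(pr$series, function(v) v[1] == 0, logical(1))))
  # the (9, t=2) cell is undefined (N = 1): falls back to nearest defined
  # state at t = 2, ties to the lower state
  def_rows <- which(!is.na(map@D[, 2]))
  nearest <- def_rows[order(abs(def_rows - 9), def_rows)][1]
  expect_equal(pr$series[[31]][2], map@D[nearest, 2])
  expect_equal(pr$n_fallback, 1L)
  expect_error(projectTraces(map, q, fallback = FALSE), "undefined")
  # a trace longer than the map grid is rejected
  long_ts <- makeTraceSet(list(as.numeric(rep(2, map@tmax + 1))))
  expect_error(projectTraces(map, quantizeTraces(long_ts)), "longer")
})

test_that("risk maps serialize and restore exactly", {
  chains <- replicate(25, as.numeric(c(2, 3, 2, 4, 3)), simplify = FALSE)
  map <- computeD(suppressWarnings(
    estimateTransitions(quantizeTraces(makeTraceSet(chains)))))
  path <- tempfile(fileext = ".json")
  writeDRiskMap(map, path)
  map2 <- readDRiskMap(path)
  expect_equal(map2@D, map@D)
  expect_equal(map2@N, map@N)
  expect_equal(map2@minCount, map@minCount)
})
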