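test_that("day adjustment recovers a known linear transform", {
  set.seed(31)
  ref <- rgamma(5000, 3, 0.5)
  day <- (ref[sample(5000)] - 5) / 2          # reference = 2 * day + 5
  adj <- fitDayAdjustment(day, ref)
  expect_equal(adj$alpha, 2, tolerance = 0.05)
  expect_equal(adj$beta, 5, tolerance = 0.15)
  # identical pools: identity transform
  adj0 <- fitDayAdjustment(ref, ref)
  expect_equal(adj0$alpha, 1, tolerance = 1e-6)
  expect_equal(adj0$beta, 0, tolerance = 1e-6)
  # quantile matching is monotone-vs-monotone, so the gain stays positive
  # even for a sign-flipped pool; degenerate pools are rejected
  expect_gt(fitDayAdjustment(-ref, ref)$alpha, 0)
  expect_error(fitDayAdjustment(rep(1, 100), ref), "degenerate")
  # applying the adjustment transforms every trace linearly
  ts <- makeTraceSet(list(c(1, 2, 3), c(4, 5, 6)))
  ts2 <- applyDayAdjustment(ts, adj)
  expect_equal(as.numeric(intensityList(ts2)[[1]]),
               adj$alpha * c(1, 2, 3) + adj$beta)
})

test_that("bootstrapped control and mock samples are disjoint and seeded", {
  ids <- sprintf("m%03d", 1:45)
  b1 <- bootstrapControl(ids, n = 20, seed = 4)
  b2 <- bootstrapControl(ids, n = 20, seed = 4)
  expect_identical(b1, b2)
  expect_length(intersect(b1$control, b1$mock), 0)
  expect_length(unique(c(b1$control, b1$mock)), 40)
  # a 40-movie pool is exactly partitioned
  b3 <- bootstrapControl(ids[1:40], n = 20, seed = 1)
  expect_setequal(c(b3$control, b3$mock), ids[1:40])
  expect_error(bootstrapControl(ids[1:30], n = 20), "too small")
  # disjointness across repeated draws
  for (s in 1:20) {
    b <- bootstrapControl(ids, n = 20, seed = s)
    expect_length(intersect(b$control, b$mock), 0)
  }
})

test_that("condition comparison gives zero effect and p = 1 against itself", {
  set.seed(32)
  mm <- data.frame(movie_id = sprintf("m%d", 1:8),
                   cs_init_rate = rgamma(8, 20, 2), ccp_pct = runif(8, 30, 50),
                   ac_pct = runif(8, 40, 60), ccp_rate = rgamma(8, 5, 2),
                   median_ccp_lifetime = runif(8, 20, 35))
  res <- compareConditions(mm, mm)
  expect_true(all(res$delta_r == 0))
  expect_true(all(res$p == 1))
  expect_error(compareConditions(mm[1, ], mm), ">= 2 movies")
  expect_error(compareConditions(mm, mm, variables = "bogus"), "missing")
  # a known multiplicative shift in one variable
  mm2 <- mm; mm2$ccp_pct <- mm$ccp_pct * 0.7
  res2 <- compareConditions(mm2, mm, variables = "ccp_pct")
  expect_equal(res2$delta_r, -30, tolerance = 1e-9)
  expect_lt(res2$p, 0.01)
})

test_that("exact rank-sum null matches brute-force enumeration and sums to 1", {
  for (nn in list(c(2L, 2L), c(3L, 3L), c(3L, 4L))) {
    null_df <- exactRanksumNull(nn[1], nn[2])
    expect_equal(sum(null_df$prob), 1, tolerance = 1e-12)
    # enumerate every assignment of ranks to group 1
    combs <- combn(nn[1] + nn[2], nn[1])
    ps <- apply(combs, 2, function(ix) {
      x <- seq_len(nn[1] + nn[2])
      suppressWarnings(stats::wilcox.test(x[ix], x[-ix])$p.value)
    })
    tab <- table(round(ps, 12)) / ncol(combs)
    expect_equal(null_df$p, as.numeric(names(tab)), tolerance = 1e-9)
    expect_equal(null_df$prob, as.numeric(tab), tolerance = 1e-12)
  }
  # symmetric in the group labels
  expect_equal(exactRanksumNull(4, 7), exactRanksumNull(7, 4))
  expect_error(exactRanksumNull(16, 16), "n <= 15")
})

test_that("permutation p-value histogram matches the exact discrete null", {
  set.seed(33)
  vals <- rnorm(24, 40, 5)           # one same-condition pool of 24 movies
  pp <- permutationPvalues(vals, n_perm = 1000, seed = 6)
  expect_length(pp$p_values, 1000)
  expect_equal(sum(pp$empirical$prob), 1, tolerance = 1e-12)
  # comparison at 10 equal-null-mass bins: the resolution at which 1000
  # draws estimate the histogram with useful precision
  tv <- tvDistance(pp$empirical, pp$exact_null, n_bins = 10)
  expect_lt(tv, 0.05)
  # the shifted-normal reference moves mass toward small p
  small <- pp$exact_null$p < 0.05
  expect_gt(sum(pp$reference$prob[small]), sum(pp$exact_null$prob[small]) * 2)
  expect_error(permutationPvalues(vals[1:23]), "even")
  # n_perm = 1 concentrates the histogram on a single attainable value
  p1 <- permutationPvalues(vals, n_perm = 1, seed = 1)
  expect_equal(sum(p1$empirical$prob > 0), 1)
})

test_that("phenotype summary PCA splits variance as constructed", {
  set.seed(34)
  a <- rnorm(11); b <- rnorm(11)
  tab <- cbind(v1 = a, v2 = 2 * a + rnorm(11, 0, 1e-8), v3 = b)
  ps <- phenotypeSummary(tab)
  expect_equal(sum(ps$explained_pct), 100, tolerance = 1e-9)
  # v1/v2 collapse onto one component; v3 is orthogonal: 2/3 vs 1/3
  expect_equal(sort(ps$explained_pct[1:2], decreasing = TRUE),
               c(200 / 3, 100 / 3), tolerance = 1)
  expect_equal(abs(ps$correlation["v1", "v2"]), 1, tolerance = 1e-6)
  expect_lt(abs(ps$correlation["v1", "v3"]), 0.7)
  expect_error(phenotypeSummary(cbind(tab, v4 = 1)), "constant")
  # duplicated observations project identically
  ps2 <- phenotypeSummary(tab[c(1:11, 1), ])
  expect_equal(unname(ps2$scores[12, ]), unname(ps2$scores[1, ]))
})

test_that("phenotype bootstrap recovers a known shift and a null mock", {
  set.seed(35)
  mkmm <- function(n, ccp_mu) data.frame(
    movie_id = sprintf("x%03d", seq_len(n) + floor(runif(1, 0, 1e6))),
    cs_init_rate = rgamma(n, 40, 4), ccp_pct = rnorm(n, ccp_mu, 2.5),
    ac_pct = rnorm(n, 95 - ccp_mu, 2.5), ccp_rate = rgamma(n, 20, 5),
    median_ccp_lifetime = rnorm(n, 26, 2))
  pool <- mkmm(45, 40)
  kd <- mkmm(20, 28)                 # 30% lower CCP percentage
  pb <- phenotypeBootstrap(pool, list(siKD = kd), n_boot = 60, seed = 12)
  s <- pb$summary
  kd_row <- s[s$condition == "siKD" & s$variable == "ccp_pct", ]
  mock_row <- s[s$condition == "siMock" & s$variable == "ccp_pct", ]
  expect_equal(kd_row$delta_r_mean, -30, tolerance = 3)
  expect_lt(kd_row$p_mean, 0.001)
  expect_gt(mean(mock_row$p_mean), 0.05)
  expect_lt(abs(mock_row$delta_r_mean), 5)
  # reproducible bit-for-bit under a fixed seed
  pb2 <- phenotypeBootstrap(pool, list(siKD = kd), n_boot = 60, seed = 12)
  expect_identical(pb$draws, pb2$draws)
})
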