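test_that("trace/movie tables round-trip losslessly through CSV", {
  ts <- makeTraceSet(list(c(1.25, 2.5, 3.75), c(4.125, 5, 6.5, 7.25)),
                     movie_id = c("m01", "m02"), n_invalid = 3L)
  tp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeTraces(ts, tp, mp)
  back <- readTraces(tp, mp)
  expect_length(back, 1L)
  ts2 <- back[[1]]
  expect_equal(nTraces(ts2), 2L)
  expect_equal(as.list(intensityList(ts2)), as.list(intensityList(ts)))
  expect_equal(lifetimes(ts2), lifetimes(ts))
  expect_equal(movieData(ts2)$n_invalid, movieData(ts)$n_invalid)
  expect_equal(nTotal(ts2), nTotal(ts))
})

test_that("a valid-flagged trace with a frame gap is demoted to invalid", {
  tr <- data.frame(condition = "c", day = "d", movie_id = "m1",
                   trace_id = c("a", "a", "a", "a", "b", "b", "b"),
                   frame = c(3, 4, 6, 7, 1, 2, 3),
                   intensity_au = c(1, 2, 3, 4, 5, 6, 7),
                   valid = 1L)
  mv <- data.frame(movie_id = "m1", condition = "c", day = "d",
                   cell_area_um2 = 100, duration_s = 451,
                   frame_interval_s = 1, n_invalid = 0L)
  tp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write.csv(tr, tp, row.names = FALSE); write.csv(mv, mp, row.names = FALSE)
  expect_warning(sets <- readTraces(tp, mp), "demoted")
  ts <- sets[[1]]
  expect_equal(nTraces(ts), 1L)              # only trace b survives
  expect_equal(traceData(ts)$trace_id, "b")
  expect_equal(movieData(ts)$n_invalid, 1L)  # a demoted
  expect_equal(nTotal(ts), 2L)               # Ntot = valid + invalid
})

test_that("schema and integrity errors are reported by name", {
  tr <- data.frame(condition = "c", day = "d", movie_id = "m1",
                   trace_id = "a", frame = 1, intensity_au = 1)
  mv <- data.frame(movie_id = "m1", condition = "c", day = "d",
                   cell_area_um2 = 100, duration_s = 451,
                   frame_interval_s = 1, n_invalid = 0L)
  tp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write.csv(tr, tp, row.names = FALSE); write.csv(mv, mp, row.names = FALSE)
  expect_error(readTraces(tp, mp), "valid")
  tr$valid <- 1L
  tr2 <- rbind(tr, tr)      # same trace id, repeated frame 1: non-monotone
  write.csv(tr2, tp, row.names = FALSE)
  expect_error(readTraces(tp, mp), "non-monotone")
  mv2 <- mv[, setdiff(colnames(mv), "cell_area_um2")]
  write.csv(tr, tp, row.names = FALSE); write.csv(mv2, mp, row.names = FALSE)
  expect_error(readTraces(tp, mp), "cell_area_um2")
})

test_that("empty trace table yields movies with Ntot = Niv", {
  mv <- data.frame(movie_id = c("m1", "m2"), condition = "c", day = "d",
                   cell_area_um2 = 100, duration_s = 451,
                   frame_interval_s = 1, n_invalid = c(0L, 4L))
  tp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write.csv(mv[0, c(1, 2)], tp, row.names = FALSE)  # headerless-ish empty
  write.csv(data.frame(condition = character(), day = character(),
                       movie_id = character(), trace_id = character(),
                       frame = integer(), intensity_au = numeric(),
                       valid = integer()), tp, row.names = FALSE)
  write.csv(mv, mp, row.names = FALSE)
  sets <- readTraces(tp, mp)
  expect_equal(nTraces(sets[[1]]), 0L)
  expect_equal(nTotal(sets[[1]]), c(0L, 4L))
})

test_that("classification output refuses unassigned traces unless forced", {
  ts <- makeTraceSet(list(c(1, 2, 3), c(4, 5, 6)))
  out <- tempfile(fileext = ".csv")
  expect_error(writeClassification(ts, NULL, out), "unassigned")
  writeClassification(ts, NULL, out, force = TRUE)
  expect_true(file.exists(out))
  categories(ts) <- c("AC", "CCP")
  feats <- data.frame(movie_id = traceData(ts)$movie_id,
                      trace_id = traceData(ts)$trace_id,
                      d1 = c(-0.5, 0.1), d2 = c(-2, -3), d3 = c(0, 0.2))
  writeClassification(ts, feats, out)
  back <- readClassification(out)
  expect_equal(back$category, c("AC", "CCP"))
  expect_equal(back$d1, feats$d1)
  # empty set writes a header-only file
  writeClassification(ts[integer(0)], NULL, out)
  expect_equal(nrow(readClassification(out)), 0L)
})

test_that("TraceSet validity catches inconsistent structures", {
  expect_error(makeTraceSet(list(numeric(0))), "zero frames")
  ts <- makeTraceSet(list(c(1, 2, 3)))
  expect_error(categories(ts) <- "bogus", "category")
  td <- traceData(ts); td$lifetime_s <- 99
  expect_error(new("TraceSet", traceData = td, movieData = movieData(ts)),
               "lifetime")
})
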