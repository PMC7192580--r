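# Small deterministic fixtures shared across test files.

# a TraceSet built from explicit intensity vectors
makeTraceSet <- function(int_list, movie_id = NULL, n_movies = 1,
                         condition = "ctrl", day = "d1", area = 100,
                         duration = 451, n_invalid = 0L) {
  n <- length(int_list)
  if (is.null(movie_id))
    movie_id <- rep(sprintf("m%02d", seq_len(n_movies)), length.out = n)
  movies <- unique(movie_id)
  md <- S4Vectors::DataFrame(movie_id = movies, condition = condition,
                             day = day, cell_area_um2 = area,
                             duration_s = duration, frame_interval_s = 1,
                             n_invalid = rep(as.integer(n_invalid),
                                             length(movies)))
  td <- S4Vectors::DataFrame(trace_id = sprintf("t%03d", seq_len(n)),
                             movie_id = movie_id,
                             intensity = IRanges::NumericList(int_list))
  TraceSet(td, md)
}

# brute-force transition-counting oracle for the risk map: literal loops
# over every trace, frame, and state pair (independent of the vectorized
# implementation)
oracleRiskMap <- function(state_list, imax, tmax) {
  N <- matrix(0, imax, tmax)
  down_cnt <- matrix(0, imax, tmax)
  up_cnt <- array(0, c(imax, imax, tmax))  # [from, to, t]
  for (s in state_list) {
    for (t in seq_along(s)) {
      if (t > tmax) break
      N[s[t], t] <- N[s[t], t] + 1
    }
    if (length(s) >= 2) {
      for (t in seq_len(length(s) - 1)) {
        if (t >= tmax) break
        if (s[t + 1] < s[t]) down_cnt[s[t], t] <- down_cnt[s[t], t] + 1
        if (s[t + 1] > s[t]) up_cnt[s[t], s[t + 1], t] <-
            up_cnt[s[t], s[t + 1], t] + 1
      }
    }
  }
  down <- matrix(NA_real_, imax, tmax)
  up <- matrix(NA_real_, imax, tmax)
  for (i in seq_len(imax)) for (t in seq_len(tmax)) {
    if (N[i, t] == 0) next
    down[i, t] <- down_cnt[i, t] / N[i, t]
    u <- 0
    if (i > 1) for (j in seq_len(i - 1))
      if (N[j, t] > 0) u <- u + up_cnt[j, i, t] / N[j, t]
    up[i, t] <- u
  }
  list(N = N, down = down, up = up)
}

# categorized two-movie set with known counts for metric tests:
# per movie 2 ACs (3 frames), 2 CCPs (5 frames), 1 OT, plus 2 invalid
makeCategorizedSet <- function() {
  ints <- c(replicate(4, c(2, 3, 4), simplify = FALSE),
            replicate(4, c(5, 9, 12, 12, 9), simplify = FALSE),
            replicate(2, c(30, 10, 3), simplify = FALSE))
  ts <- makeTraceSet(ints,
                     movie_id = c("m01", "m01", "m02", "m02",
                                  "m01", "m01", "m02", "m02",
                                  "m01", "m02"),
                     n_invalid = 2L)
  categories(ts) <- rep(c("AC", "CCP", "OT"), c(4, 4, 2))
  ts
}
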