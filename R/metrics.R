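#' Clathrin-structure initiation rate
#'
#' Total trackable structures (valid + invalid) detected per minute per
#' square micron of cell footprint: Ntot / (A * T) with T in minutes.
#'
#' @param n_total Total trace count (valid + invalid).
#' @param area Cell area (um^2).
#' @param duration_s Movie duration (s).
#' @return Rate in 1/(min um^2).
#' @examples
#' initiationRate(4510, 100, 451)  # 6
#' @export
initiationRate <- function(n_total, area, duration_s) {
  if (any(area <= 0) || any(duration_s <= 0))
    stop("area and duration must be > 0")
  n_total / (area * duration_s / 60)
}

#' Per-movie stage-resolved CME metrics
#'
#' For every movie: the initiation rate over all traces, the AC/CCP/OT
#' percentages over valid categorized traces, the CCP rate
#' (nCCP / (A * T)), and the median CCP lifetime.
#'
#' @param ts A categorized \linkS4class{TraceSet}.
#' @return data.frame, one row per movie: counts, \code{cs_init_rate},
#'   \code{ccp_pct}, \code{ac_pct}, \code{ot_pct}, \code{ccp_rate},
#'   \code{median_ccp_lifetime}.
#' @export
movieMetrics <- function(ts) {
  stopifnot(is(ts, "TraceSet"))
  td <- ts@traceData
  if (nrow(td) && any(td$category == "unassigned"))
    stop("uncategorized traces present; run the classifier first")
  md <- ts@movieData
  f <- factor(td$movie_id, levels = md$movie_id)
  cnt <- function(cat) as.integer(table(f[td$category == cat]))
  n_ccp <- cnt("CCP"); n_ac <- cnt("AC"); n_ot <- cnt("OT")
  n_valid <- as.integer(table(f))
  n_tot <- n_valid + md$n_invalid
  t_min <- md$duration_s / 60
  med_life <- rep(NA_real_, nrow(md))
  has <- n_ccp > 0
  if (any(has)) {
    ml <- tapply(td$lifetime_s[td$category == "CCP"],
                 factor(td$movie_id[td$category == "CCP"],
                        levels = md$movie_id), stats::median)
    med_life <- as.numeric(ml)
  }
  data.frame(movie_id = md$movie_id, condition = md$condition, day = md$day,
             n_valid = n_valid, n_invalid = md$n_invalid, n_total = n_tot,
             n_ccp = n_ccp, n_ac = n_ac, n_ot = n_ot,
             cs_init_rate = n_tot / (md$cell_area_um2 * t_min),
             ccp_pct = ifelse(n_valid > 0, 100 * n_ccp / n_valid, NA_real_),
             ac_pct = ifelse(n_valid > 0, 100 * n_ac / n_valid, NA_real_),
             ot_pct = ifelse(n_valid > 0, 100 * n_ot / n_valid, NA_real_),
             ccp_rate = n_ccp / (md$cell_area_um2 * t_min),
             median_ccp_lifetime = med_life,
             stringsAsFactors = FALSE)
}

#' Pooled condition-level summary of movie metrics
#'
#' Means of the per-movie rates and percentages plus the pooled median CCP
#' lifetime (medians of per-movie medians are reported alongside).
#'
#' @param ts A categorized \linkS4class{TraceSet}.
#' @return One-row data.frame.
#' @export
conditionMetrics <- function(ts) {
  mm <- movieMetrics(ts)
  td <- ts@traceData
  pooled_med <- if (any(td$category == "CCP"))
    stats::median(td$lifetime_s[td$category == "CCP"]) else NA_real_
  data.frame(condition = mm$condition[1], n_movies = nrow(mm),
             cs_init_rate = mean(mm$cs_init_rate),
             ccp_pct = mean(mm$ccp_pct, na.rm = TRUE),
             ac_pct = mean(mm$ac_pct, na.rm = TRUE),
             ot_pct = mean(mm$ot_pct, na.rm = TRUE),
             ccp_rate = mean(mm$ccp_rate),
             median_ccp_lifetime_pooled = pooled_med,
             median_ccp_lifetime_by_movie =
               stats::median(mm$median_ccp_lifetime, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

# per-trace value of a distribution variable
.trace_variable <- function(ts, variable = c("lifetime", "imax")) {
  variable <- match.arg(variable)
  if (variable == "lifetime") lifetimes(ts)
  else as.numeric(max(intensityList(ts)))  # max of raw intensities per trace
}

#' Empirical distribution and kernel density of a trace variable
#'
#' Lifetime or maximum (raw, unquantized) intensity for one category, with
#' a Gaussian-kernel density at the normal-reference bandwidth.
#'
#' @param ts A categorized \linkS4class{TraceSet}.
#' @param variable \code{"lifetime"} or \code{"imax"}.
#' @param category One of AC/CCP/OT, or \code{"all"}.
#' @param n_grid Density grid size.
#' @return List with \code{values}, \code{x}, \code{y}.
#' @export
traceDistribution <- function(ts, variable = c("lifetime", "imax"),
                              category = "all", n_grid = 512L) {
  v <- .trace_variable(ts, variable)
  if (category != "all") v <- v[categories(ts) == category]
  if (length(v) < 2L) stop("fewer than 2 traces in category ", category)
  if (length(unique(v)) < 2L) stop("degenerate (single-valued) input")
  d <- stats::density(v, bw = "nrd", n = n_grid)
  list(values = v, x = d$x, y = d$y)
}

#' Bootstrap confidence band for a probability density
#'
#' Movie-to-movie variation is treated as the dominant source of
#' uncertainty. Each movie's values are resampled to the common size nx
#' (the median per-movie count of the category) before pooling, the pooled
#' sample is smoothed with a Gaussian kernel at the normal-reference
#' bandwidth, and movies are then resampled with replacement \code{n_boot}
#' times; the band is the pointwise 2.5th/97.5th percentile of the
#' bootstrap curves, evaluated on a fixed grid with the central bandwidth.
#'
#' @param ts A categorized \linkS4class{TraceSet} with >= 2 movies.
#' @param variable \code{"lifetime"} or \code{"imax"}.
#' @param category AC/CCP/OT or "all".
#' @param n_boot Bootstrap repetitions.
#' @param seed RNG seed.
#' @param n_grid Grid size.
#' @return List: \code{x}, \code{p} (central), \code{lower}, \code{upper},
#'   \code{n_boot}, \code{nx}.
#' @export
bootstrapPdfBand <- function(ts, variable = c("lifetime", "imax"),
                             category = "all", n_boot = 400L, seed = 1L,
                             n_grid = 256L) {
  v <- .trace_variable(ts, variable)
  keep <- if (category == "all") rep(TRUE, nTraces(ts))
          else categories(ts) == category
  by_movie <- split(v[keep], traceData(ts)$movie_id[keep])
  empty <- names(by_movie)[lengths(by_movie) == 0L]
  present <- setdiff(movieData(ts)$movie_id, names(by_movie))
  if (length(c(empty, present)))
    warning("excluding ", length(c(empty, present)),
            " movie(s) with zero members of category ", category)
  by_movie <- by_movie[lengths(by_movie) > 0L]
  if (length(by_movie) < 2L) stop("need >= 2 movies with members")
  nx <- as.integer(stats::median(lengths(by_movie)))
  withSeed(seed, {
    pool0 <- unlist(lapply(by_movie, function(x)
      x[sample.int(length(x), nx, replace = TRUE)]), use.names = FALSE)
    bw <- stats::bw.nrd(pool0)
    x0 <- stats::density(pool0, bw = bw, n = n_grid)
    grid <- x0$x
    curves <- matrix(NA_real_, n_boot, n_grid)
    for (b in seq_len(n_boot)) {
      mv <- sample.int(length(by_movie), length(by_movie), replace = TRUE)
      pool <- unlist(lapply(by_movie[mv], function(x)
        x[sample.int(length(x), nx, replace = TRUE)]), use.names = FALSE)
      curves[b, ] <- stats::density(pool, bw = bw, n = n_grid,
                                    from = grid[1], to = grid[n_grid])$y
    }
    qs <- apply(curves, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    list(x = grid, p = x0$y, lower = qs[1, ], upper = qs[2, ],
         n_boot = n_boot, nx = nx)
  })
}

#' Lifetime-cohort average of aligned traces
#'
#' Averages the traces whose lifetime falls within \code{tau_target +/-
#' half_width} seconds, aligned at their first frame, giving the per-frame
#' mean and standard deviation (n-1 denominator) up to the cohort lifetime.
#' Supports the optional second channel for master/slave-style cohorts.
#'
#' @param ts A \linkS4class{TraceSet} (optionally subset by category first).
#' @param tau_target Cohort lifetime (s).
#' @param half_width Lifetime tolerance (s), default 5.
#' @param channel 1 or 2.
#' @param category Optional category filter.
#' @return List: \code{t}, \code{mean}, \code{sd}, \code{n_members},
#'   \code{tau_target}.
#' @export
cohortAverage <- function(ts, tau_target, half_width = 5, channel = 1L,
                          category = NULL) {
  sel <- abs(lifetimes(ts) - tau_target) <= half_width
  if (!is.null(category)) sel <- sel & categories(ts) == category
  if (!any(sel))
    stop("empty cohort at tau = ", tau_target, " s")
  il <- intensityList(ts, channel = channel)[sel]
  nf_out <- max(1L, as.integer(floor(tau_target / frameInterval(ts))))
  M <- matrix(NA_real_, sum(sel), nf_out)
  nf <- pmin(lengths(il), nf_out)
  for (i in seq_along(il)) M[i, seq_len(nf[i])] <- il[[i]][seq_len(nf[i])]
  list(t = seq_len(nf_out) * frameInterval(ts),
       mean = colMeans(M, na.rm = TRUE),
       sd = apply(M, 2, stats::sd, na.rm = TRUE),
       n_members = sum(sel), tau_target = tau_target)
}
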