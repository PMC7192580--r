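#' Cross-day intensity adjustment by quantile matching
#'
#' Fits the linear transform alpha * I + beta that brings one day's control
#' intensity pool onto the reference day's pool by least squares over
#' matched quantiles (evenly spaced grid). The fit is then applied to every
#' trace of that day, including the experimental conditions.
#'
#' @param day_intensities Numeric pool of control intensities on day d.
#' @param reference_intensities Control pool of the reference (standard) day.
#' @param n_quantiles Size of the quantile grid.
#' @return List of class \code{dayAdjustment}: \code{alpha}, \code{beta},
#'   \code{rms_residual}.
#' @export
fitDayAdjustment <- function(day_intensities, reference_intensities,
                             n_quantiles = 999L) {
  if (stats::sd(day_intensities) == 0 || stats::sd(reference_intensities) == 0)
    stop("degenerate intensity pool (zero variance)")
  p <- seq_len(n_quantiles) / (n_quantiles + 1)
  qd <- stats::quantile(day_intensities, p, names = FALSE)
  qr <- stats::quantile(reference_intensities, p, names = FALSE)
  fit <- stats::lsfit(qd, qr)
  alpha <- fit$coefficients[2]; beta <- fit$coefficients[1]
  if (alpha <= 0) stop("day adjustment produced non-positive gain ",
                       "(distribution reversal)")
  structure(list(alpha = unname(alpha), beta = unname(beta),
                 rms_residual = sqrt(mean(fit$residuals^2))),
            class = "dayAdjustment")
}

#' @rdname fitDayAdjustment
#' @param ts A \linkS4class{TraceSet} whose intensities are transformed.
#' @param adjustment A \code{dayAdjustment}.
#' @export
applyDayAdjustment <- function(ts, adjustment) {
  stopifnot(is(ts, "TraceSet"), inherits(adjustment, "dayAdjustment"))
  ts@traceData$intensity <- adjustment$alpha * ts@traceData$intensity +
    adjustment$beta
  validObject(ts)
  ts
}

#' Draw disjoint bootstrapped control and mock movie samples
#'
#' Selects \code{n} movies without replacement as the bootstrapped control
#' and a further disjoint \code{n} as the mock "perturbation", which
#' gauges day-to-day variability under the null.
#'
#' @param movie_ids Character pool of control movie ids (>= 2n).
#' @param n Movies per sample.
#' @param seed RNG seed.
#' @return List with \code{control} and \code{mock} id vectors.
#' @export
bootstrapControl <- function(movie_ids, n = 20L, seed = 1L) {
  if (length(movie_ids) < 2L * n)
    stop("pool of ", length(movie_ids), " movies too small for two disjoint ",
         "samples of ", n)
  withSeed(seed, {
    pick <- sample(movie_ids, 2L * n, replace = FALSE)
    list(control = pick[seq_len(n)], mock = pick[n + seq_len(n)])
  })
}

.pheno_vars <- c("cs_init_rate", "ccp_pct", "ac_pct", "ccp_rate",
                 "median_ccp_lifetime")

#' Compare two conditions on per-movie metric values
#'
#' For each variable, the percentage difference of condition means
#' (Delta r = 100 * (mean_exp - mean_ctrl) / mean_ctrl) and a two-sided
#' Wilcoxon rank sum p-value over the per-movie values. Median CCP lifetime
#' uses per-movie medians as its samples.
#'
#' @param experiment_metrics,control_metrics Per-movie metric data.frames
#'   from \code{\link{movieMetrics}} (>= 2 movies each).
#' @param variables Metric columns to compare.
#' @return data.frame: variable, delta_r, p.
#' @export
compareConditions <- function(experiment_metrics, control_metrics,
                              variables = .pheno_vars) {
  if (nrow(experiment_metrics) < 2L || nrow(control_metrics) < 2L)
    stop("need >= 2 movies per side")
  miss <- setdiff(variables, colnames(experiment_metrics))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  res <- lapply(variables, function(v) {
    xe <- experiment_metrics[[v]]; xc <- control_metrics[[v]]
    xe <- xe[is.finite(xe)]; xc <- xc[is.finite(xc)]
    dr <- 100 * (mean(xe) - mean(xc)) / mean(xc)
    p <- suppressWarnings(stats::wilcox.test(xe, xc)$p.value)
    data.frame(variable = v, delta_r = dr, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bootstrap phenotype comparison against a pooled control
#'
#' Each bootstrap draws disjoint control and mock movie samples from the
#' pooled control movies and compares every experimental condition (plus the
#' mock) to the bootstrapped control, collecting the percentage difference
#' and rank-sum p per variable. Summaries are the bootstrap means, standard
#' deviations and percentile 95% intervals.
#'
#' @param pool_metrics Per-movie metrics of the pooled control movies.
#' @param condition_metrics Named list of per-movie metric data.frames, one
#'   per experimental condition.
#' @param variables Metric columns to compare.
#' @param n_boot Bootstrap repetitions.
#' @param n Movies per bootstrapped sample.
#' @param seed RNG seed.
#' @return List of class \code{phenotypeResult}: \code{draws} (long
#'   data.frame: condition, variable, bootstrap, delta_r, p) and
#'   \code{summary} (condition, variable, delta_r_mean, delta_r_sd, ci
#'   bounds, p_mean, p_sd).
#' @export
phenotypeBootstrap <- function(pool_metrics, condition_metrics,
                               variables = .pheno_vars, n_boot = 300L,
                               n = 20L, seed = 1L) {
  stopifnot(is.list(condition_metrics), length(condition_metrics) >= 1L)
  ids <- pool_metrics$movie_id
  draws <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    picks <- bootstrapControl(ids, n = n, seed = seed + b)
    ctrl <- pool_metrics[ids %in% picks$control, , drop = FALSE]
    mock <- pool_metrics[ids %in% picks$mock, , drop = FALSE]
    sets <- c(condition_metrics, list(siMock = mock))
    res <- lapply(names(sets), function(cc) {
      out <- compareConditions(sets[[cc]], ctrl, variables)
      out$condition <- cc
      out$bootstrap <- b
      out
    })
    draws[[b]] <- do.call(rbind, res)
  }
  draws <- do.call(rbind, draws)
  agg <- do.call(rbind, lapply(split(draws, draws[c("condition", "variable")]),
    function(d) data.frame(
      condition = d$condition[1], variable = d$variable[1],
      delta_r_mean = mean(d$delta_r), delta_r_sd = stats::sd(d$delta_r),
      delta_r_lo = stats::quantile(d$delta_r, 0.025, names = FALSE),
      delta_r_hi = stats::quantile(d$delta_r, 0.975, names = FALSE),
      p_mean = mean(d$p), p_sd = stats::sd(d$p),
      frac_p_below_05 = mean(d$p < 0.05),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(draws = draws, summary = agg, n_boot = n_boot),
            class = "phenotypeResult")
}

#' Exact null distribution of the small-sample two-sided rank-sum p-value
#'
#' The two-sided Wilcoxon rank sum p-value for group sizes (n1, n2) takes
#' finitely many values under exchangeability; this returns each attainable
#' p with its exact probability (via the rank-sum count recursion).
#'
#' @param n1,n2 Group sizes (enumeration practical up to ~15 per group).
#' @return data.frame: \code{p} (attainable two-sided p-values, increasing)
#'   and \code{prob} (their null probabilities, summing to 1).
#' @export
exactRanksumNull <- function(n1 = 12L, n2 = 12L) {
  if (n1 > 15L || n2 > 15L) stop("exact enumeration limited to n <= 15 per group")
  m <- n1 * n2
  u <- 0:m
  pv <- vapply(u, function(x)
    min(1, 2 * min(stats::pwilcox(x, n1, n2),
                   1 - stats::pwilcox(x - 1L, n1, n2))), numeric(1))
  d <- stats::dwilcox(u, n1, n2)
  atoms <- tapply(d, round(pv, 12), sum)
  data.frame(p = as.numeric(names(atoms)), prob = as.numeric(atoms),
             row.names = NULL)
}

#' Permutation distribution of rank-sum p-values for same-condition movies
#'
#' Randomly splits 2n same-condition per-movie values into two groups of n,
#' computes the exact two-sided rank-sum p per split, and histograms the
#' p-values over the finite attainable set. Also returns the exact discrete
#' null and a reference simulation of n N(0,1) vs n N(0.5,1) samples, whose
#' mass shifts toward small p.
#'
#' @param values Per-movie metric values (even count 2n, e.g. 24 CCP
#'   percentages).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param reference_shift Mean shift of the reference normal simulation.
#' @param n_reference Number of reference simulations.
#' @return List: \code{p_values} (length n_perm), \code{empirical}
#'   (data.frame p/prob on the attainable set), \code{exact_null},
#'   \code{reference} (shifted-normal histogram on the same set).
#' @export
permutationPvalues <- function(values, n_perm = 1000L, seed = 1L,
                               reference_shift = 0.5, n_reference = 1000L) {
  n2 <- length(values)
  if (n2 %% 2L != 0L) stop("need an even number of movies")
  n <- n2 %/% 2L
  null_df <- exactRanksumNull(n, n)
  snap <- function(p) null_df$p[max.col(-abs(outer(p, null_df$p, "-")),
                                        ties.method = "first")]
  withSeed(seed, {
    pv <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n2, n)
      suppressWarnings(stats::wilcox.test(values[idx], values[-idx])$p.value)
    }, numeric(1))
    pref <- vapply(seq_len(n_reference), function(i) {
      suppressWarnings(stats::wilcox.test(stats::rnorm(n),
                                          stats::rnorm(n, reference_shift))$p.value)
    }, numeric(1))
    emp <- table(factor(snap(pv), levels = null_df$p)) / n_perm
    ref <- table(factor(snap(pref), levels = null_df$p)) / n_reference
    list(p_values = pv,
         empirical = data.frame(p = null_df$p, prob = as.numeric(emp)),
         exact_null = null_df,
         reference = data.frame(p = null_df$p, prob = as.numeric(ref)))
  })
}

#' Total variation distance between two discrete p-value distributions
#'
#' Optionally coarsens the attainable-p atoms into \code{n_bins} bins of
#' (near) equal null mass before comparing, which is the resolution at which
#' a histogram of ~1000 draws estimates probabilities with useful precision.
#'
#' @param empirical,null_df data.frames with columns p/prob on a common set.
#' @param n_bins Number of equal-null-mass bins; \code{NULL} compares atoms
#'   directly.
#' @return Total variation distance in [0, 1].
#' @export
tvDistance <- function(empirical, null_df, n_bins = NULL) {
  stopifnot(isTRUE(all.equal(empirical$p, null_df$p)))
  pe <- empirical$prob; pn <- null_df$prob
  if (!is.null(n_bins)) {
    cum <- cumsum(pn)
    bin <- pmin(floor(cum * n_bins / (cum[length(cum)] + 1e-12)) + 1L, n_bins)
    pe <- tapply(pe, bin, sum); pn <- tapply(pn, bin, sum)
  }
  0.5 * sum(abs(pe - pn))
}

#' Phenotype summary: PCA and correlation of condition-by-variable effects
#'
#' Centers and scales the percentage-difference table (conditions as rows),
#' runs standard PCA and reports scores, variable loadings, explained
#' variance and the pairwise correlation matrix.
#'
#' @param effect_table Numeric matrix/data.frame, conditions x variables.
#' @return List: \code{scores}, \code{loadings}, \code{explained_pct},
#'   \code{correlation}.
#' @export
phenotypeSummary <- function(effect_table) {
  X <- as.matrix(effect_table)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant column(s): ",
         paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       explained_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
       correlation = stats::cor(X))
}
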