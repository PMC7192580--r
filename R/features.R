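#' Per-trace disassembly asymmetry features
#'
#' Summarizes each disassembly-risk series by three statistics:
#' \itemize{
#'   \item \code{d1}: time average of the series, (1/tau) * sum(D). Abortive
#'     coats, trapped in the suppressed-risk growth regime, sit at d1 < 0;
#'     maturing pits spend most of their life near D = 0.
#'   \item \code{d2}: log range rate, log((max(D) - min(D)) / tau), the
#'     lifetime-normalized spread of the series. Flat series (max = min) are
#'     floored at log(range_floor / tau).
#'   \item \code{d3}: modified skewness, (1/tau) * sum((D - d1)^3) / sigma^3
#'     with sigma = sqrt((1/tau) * sum((D - d1)^2)); 0 when sigma = 0. Picks
#'     out outlier traces whose few initial values are far above the rest.
#' }
#' Here tau is the dimensionless lifetime (seconds at 1 frame/s).
#'
#' @param series \code{NumericList} of risk series (from
#'   \code{\link{projectTraces}}) or a plain list of numeric vectors.
#' @param lifetimes Numeric lifetimes in seconds; defaults to the series
#'   lengths times \code{frame_interval}.
#' @param trace_id,movie_id Optional id vectors carried into the output.
#' @param frame_interval Seconds between frames.
#' @param range_floor Degenerate-range floor for d2 (a.u. of D).
#' @return data.frame with columns movie_id, trace_id, lifetime_s, d1, d2, d3.
#' @examples
#' computeDasFeatures(list(c(0, -0.3, -0.6)))$d1  # -0.3
#' @export
computeDasFeatures <- function(series, lifetimes = NULL, trace_id = NULL,
                               movie_id = NULL, frame_interval = 1,
                               range_floor = 1e-3) {
  if (is.list(series) && !is(series, "NumericList"))
    series <- IRanges::NumericList(series)
  nf <- lengths(series)
  if (any(nf == 0L)) stop("empty risk series")
  if (is.null(lifetimes)) lifetimes <- nf * frame_interval
  tau <- lifetimes / 1  # dimensionless lifetime (1 s frames)
  v <- unlist(series, use.names = FALSE)
  g <- rep.int(seq_along(nf), nf)
  sums <- rowsum(v, g)[, 1L]
  d1 <- sums / tau
  mx <- vapply(split(v, g), max, numeric(1))
  mn <- vapply(split(v, g), min, numeric(1))
  rng <- pmax(mx - mn, range_floor)
  d2 <- log(rng / tau)
  dev <- v - d1[g]
  m2 <- rowsum(dev^2, g)[, 1L] / tau
  m3 <- rowsum(dev^3, g)[, 1L] / tau
  sigma <- sqrt(m2)
  # flat series carry no asymmetry (guard against sigma at rounding-error
  # scale for constant input)
  d3 <- ifelse(sigma > 0 & (mx - mn) > 0, m3 / sigma^3, 0)
  data.frame(movie_id = if (is.null(movie_id)) NA_character_ else movie_id,
             trace_id = if (is.null(trace_id)) as.character(seq_along(nf)) else trace_id,
             lifetime_s = lifetimes, d1 = d1, d2 = d2, d3 = d3,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' d2: log range rate of a single risk series
#'
#' Convenience scalar form of the second DAS feature,
#' d2 = log((max(D) - min(D)) / tau).
#'
#' @param dmax,dmin Maximum and minimum of the risk series (or a series via
#'   \code{series}).
#' @param tau Lifetime in seconds (dimensionless at 1 frame/s).
#' @param series Optional numeric risk series; overrides dmax/dmin.
#' @param range_floor Degenerate-range floor.
#' @examples
#' computeD2(0.2, -0.8, 30)  # ~ -3.4
#' computeD2(0, -1, 10)      # ~ -2.3
#' @export
computeD2 <- function(dmax = NULL, dmin = NULL, tau, series = NULL,
                      range_floor = 1e-3) {
  if (!is.null(series)) { dmax <- max(series); dmin <- min(series) }
  log(max(dmax - dmin, range_floor) / tau)
}

#' Control-based feature normalization
#'
#' Fits per-feature means and standard deviations on the control condition;
#' every condition from the same day is then normalized with the control
#' statistics unchanged: d_norm = (d - mu_ctrl) / sigma_ctrl.
#'
#' @param control_features Feature data.frame from
#'   \code{\link{computeDasFeatures}} for the control condition.
#' @return List of class \code{dasNormalizer} with \code{mu}, \code{sigma}
#'   (each length 3, named d1/d2/d3).
#' @export
fitNormalizer <- function(control_features) {
  X <- as.matrix(control_features[, c("d1", "d2", "d3")])
  if (nrow(X) < 2L) stop("need at least 2 control traces")
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  if (any(sigma == 0)) stop("zero control variance in feature(s): ",
                            paste(names(sigma)[sigma == 0], collapse = ", "))
  structure(list(mu = mu, sigma = sigma), class = "dasNormalizer")
}

#' @rdname fitNormalizer
#' @param features Feature data.frame to normalize.
#' @param normalizer A \code{dasNormalizer}.
#' @return \code{applyNormalizer}: the data.frame with added columns
#'   \code{d1n}, \code{d2n}, \code{d3n}.
#' @export
applyNormalizer <- function(features, normalizer) {
  stopifnot(inherits(normalizer, "dasNormalizer"))
  for (a in 1:3) {
    f <- paste0("d", a)
    features[[paste0(f, "n")]] <-
      (features[[f]] - normalizer$mu[[f]]) / normalizer$sigma[[f]]
  }
  features
}
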