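#' Fit the initial growth of paired epi/TIRF cohort intensities
#'
#' Linear fits to the early frames of both channels determine the initial
#' growth rates used to gain-match the epi channel. Frame 2 is excluded
#' (systematically unsmooth in both channels); the candidate point sets are
#' {1,3,4} plus frames 5..k one by one up to 10, and the set minimizing the
#' summed per-point mean squared residual of the two fits is retained
#' (ties to the smallest set).
#'
#' @param IE,IT Epi and TIRF cohort mean intensities per frame (1 s frames).
#' @return List: \code{kE}, \code{kT} (slopes at t = 1), \code{PE1},
#'   \code{PT1} (fitted values at t = 1), \code{points} (chosen frame set),
#'   \code{coefE}, \code{coefT}.
#' @export
fitInitialGrowth <- function(IE, IT) {
  n <- min(length(IE), length(IT))
  if (n < 4L) stop("need at least 4 usable frames")
  kmax <- min(10L, n)
  sets <- lapply(4:kmax, function(k) c(1L, 3L, 4L, if (k >= 5L) 5:k))
  best <- NULL
  for (S in sets) {
    fe <- stats::lsfit(S, IE[S]); ft <- stats::lsfit(S, IT[S])
    res <- mean(fe$residuals^2) + mean(ft$residuals^2)
    if (is.null(best) || res < best$res - 1e-12)
      best <- list(res = res, S = S, fe = fe, ft = ft)
  }
  kE <- unname(best$fe$coefficients[2]); kT <- unname(best$ft$coefficients[2])
  if (kT <= 1e-12)
    warning("flat TIRF channel (kT ~ 0); depth estimates will be unreliable")
  list(kE = kE, kT = kT,
       PE1 = unname(best$fe$coefficients[1] + kE),
       PT1 = unname(best$ft$coefficients[1] + kT),
       points = best$S,
       coefE = unname(best$fe$coefficients),
       coefT = unname(best$ft$coefficients),
       residual = best$res)
}

#' Gain-match the epi channel to the TIRF channel
#'
#' IEp(t) = (kT/kE) IE(t) + I0 with the additive correction
#' I0 = -(kT/kE) PE(1) + PT(1), chosen so the adjusted epi trace meets the
#' TIRF fit at t = 1 (zero invagination at first detection).
#'
#' @param IE Epi intensity course.
#' @param fit Result of \code{\link{fitInitialGrowth}}.
#' @return List: \code{IEp} (adjusted course), \code{gain} (kT/kE),
#'   \code{I0}.
#' @export
adjustEpi <- function(IE, fit) {
  if (fit$kE <= 0) stop("non-positive epi growth rate kE")
  a <- fit$kT / fit$kE
  I0 <- -a * fit$PE1 + fit$PT1
  list(IEp = a * IE + I0, gain = a, I0 = I0)
}

#' Invagination depth course from gain-matched epi and TIRF intensities
#'
#' The TIRF excitation field decays with distance from the coverslip with
#' characteristic depth h, so the centroid displacement of a structure obeys
#' IT = IEp * exp(-dz/h), i.e. dz(t)/h = log(IEp(t)/IT(t)). Uncertainty is
#' first-order propagation of the two channel errors, with the gain and I0
#' treated as constants. Frames with non-positive intensity in either
#' channel are masked with a warning (weak foreground over high background).
#'
#' @param IEp Adjusted epi course from \code{\link{adjustEpi}}.
#' @param IT TIRF course.
#' @param dIE,dIT Per-frame channel errors (sd); propagated when supplied.
#' @param h TIRF characteristic depth (nm), default 115.
#' @param gain kT/kE used in the adjustment (for error propagation).
#' @return data.frame: t, dz_over_h, dz_nm, err (on dz/h scale).
#' @export
invaginationDepth <- function(IEp, IT, dIE = NULL, dIT = NULL, h = 115,
                              gain = 1) {
  n <- min(length(IEp), length(IT))
  IEp <- IEp[seq_len(n)]; IT <- IT[seq_len(n)]
  bad <- !(IEp > 0 & IT > 0)
  if (any(bad))
    warning(sum(bad), " frame(s) with non-positive intensity masked")
  dz <- rep(NA_real_, n)
  dz[!bad] <- log(IEp[!bad] / IT[!bad])
  err <- rep(NA_real_, n)
  if (!is.null(dIE) && !is.null(dIT)) {
    err[!bad] <- sqrt((gain * dIE[seq_len(n)][!bad] / IEp[!bad])^2 +
                      (dIT[seq_len(n)][!bad] / IT[!bad])^2)
  }
  data.frame(t = seq_len(n), dz_over_h = dz, dz_nm = h * dz, err = err)
}

#' Full epi/TIRF depth pipeline for a two-channel cohort table
#'
#' @param cohort data.frame with columns \code{t, IE, dIE, IT, dIT}
#'   (errors optional).
#' @param h TIRF characteristic depth (nm).
#' @return List: \code{fit}, \code{adjust}, \code{depth} (data.frame as in
#'   \code{\link{invaginationDepth}}).
#' @export
epiTirfDepth <- function(cohort, h = 115) {
  need <- c("t", "IE", "IT")
  if (!all(need %in% colnames(cohort)))
    stop("cohort table needs columns ", paste(need, collapse = ", "))
  fit <- fitInitialGrowth(cohort$IE, cohort$IT)
  adj <- adjustEpi(cohort$IE, fit)
  depth <- invaginationDepth(adj$IEp, cohort$IT, cohort$dIE, cohort$dIT,
                             h = h, gain = adj$gain)
  depth$t <- cohort$t[seq_len(nrow(depth))]
  list(fit = fit, adjust = adj, depth = depth)
}

#' Forward-simulate a two-channel epi/TIRF cohort with known depth course
#'
#' Builds a clathrin recruitment course (linear growth to a plateau), maps
#' it through channel gains, and attenuates the TIRF channel by
#' exp(-dz/h). Useful as the ground truth for testing the inversion.
#'
#' @param dz_over_h Known depth course (per frame, starting near 0).
#' @param gain_epi,gain_tirf Channel gains.
#' @param growth_rate Recruitment rate (a.u./frame) of the underlying course.
#' @param t_plateau Frame at which recruitment plateaus.
#' @param noise_sd Additive noise applied to both channels.
#' @param seed RNG seed (NULL for noiseless).
#' @return data.frame: t, IE, dIE, IT, dIT, true_dz_over_h.
#' @export
simulateEpiTirfCohort <- function(dz_over_h, gain_epi = 1.8, gain_tirf = 0.9,
                                  growth_rate = 5, t_plateau = 12,
                                  noise_sd = 0, seed = NULL) {
  nf <- length(dz_over_h)
  tt <- seq_len(nf)
  C <- growth_rate * pmin(tt, t_plateau)
  IE <- gain_epi * C
  IT <- gain_tirf * C * exp(-dz_over_h)
  if (noise_sd > 0) {
    withSeed(seed, {
      IE <- IE + stats::rnorm(nf, 0, noise_sd)
      IT <- IT + stats::rnorm(nf, 0, noise_sd)
    })
  }
  data.frame(t = tt, IE = IE, dIE = rep(noise_sd, nf), IT = IT,
             dIT = rep(noise_sd, nf), true_dz_over_h = dz_over_h)
}
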