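#' Simulation configuration for synthetic clathrin-structure traces
#'
#' Defaults encode the population structure the classifier assumes:
#' clathrin-coated pits (CCPs) with Rayleigh-distributed lifetimes whose mode
#' sits near 26 s, growing to a bright plateau before a falling limb;
#' abortive coats (ACs) with exponential lifetimes of a few seconds that
#' grow slowly and dimly until abrupt disassembly terminates the track; and
#' rare outlier traces (OTs) that appear abnormally bright and decay within
#' a couple of frames to a dim residual. Intensity units are arbitrary
#' camera units; see the methods vignette for the rationale behind each
#' default.
#'
#' @param n_traces Total traces per condition.
#' @param fractions Named or ordered probabilities (AC, CCP, OT), summing
#'   to 1.
#' @param ccp_lifetime_scale Rayleigh scale sigma (s); the Rayleigh mode
#'   equals sigma.
#' @param ac_lifetime_mean Mean of the exponential AC lifetime law (s),
#'   governing the trackable excess beyond the 3-frame detection floor
#'   (memoryless disassembly hazard).
#' @param ccp_plateau_range Plateau intensity range (a.u.), drawn uniformly.
#' @param ccp_growth_rate Assembly-phase ramp rate (a.u./s).
#' @param ac_level Mean AC intensity (a.u.).
#' @param ot_peak Initial OT intensity (a.u.).
#' @param ot_lifetime_mean Exponential mean OT lifetime (s).
#' @param noise_sd Additive Gaussian measurement noise per frame (a.u.).
#' @param seed RNG seed.
#' @param movies Number of movies the traces are spread over.
#' @param cell_area Cell footprint per movie (um^2).
#' @param duration Movie duration (s).
#' @return List of class \code{dascSimConfig}.
#' @export
dascSimConfig <- function(n_traces = 10000L,
                          fractions = c(AC = 0.5, CCP = 0.4, OT = 0.1),
                          ccp_lifetime_scale = 26,
                          ac_lifetime_mean = 8,
                          ccp_plateau_range = c(16, 40),
                          ccp_growth_rate = 3,
                          ac_level = 5,
                          ot_peak = 100,
                          ot_lifetime_mean = 5,
                          noise_sd = 0.6,
                          seed = 1L,
                          movies = 20L,
                          cell_area = 300,
                          duration = 451) {
  fractions <- unname(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("config error: fractions must be 3 non-negative values summing to 1")
  scales <- c(ccp_lifetime_scale, ac_lifetime_mean, ccp_plateau_range,
              ccp_growth_rate, ac_level, ot_peak, ot_lifetime_mean, noise_sd,
              cell_area, duration)
  if (any(scales <= 0)) stop("config error: all scales must be > 0")
  structure(list(n_traces = as.integer(n_traces), fractions = fractions,
                 ccp_lifetime_scale = ccp_lifetime_scale,
                 ac_lifetime_mean = ac_lifetime_mean,
                 ccp_plateau_range = ccp_plateau_range,
                 ccp_growth_rate = ccp_growth_rate, ac_level = ac_level,
                 ot_peak = ot_peak, ot_lifetime_mean = ot_lifetime_mean,
                 noise_sd = noise_sd, seed = seed, movies = as.integer(movies),
                 cell_area = cell_area, duration = duration),
            class = "dascSimConfig")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.rrayleigh <- function(n, sigma) sigma * sqrt(-2 * log(stats::runif(n)))

# one AC trace: slow assembly interrupted by recurrent partial collapses
# (continuous subunit exchange without significant net assembly), so the
# coat stays dim and growth-dominated at every age until final disassembly
# terminates the track within the last frame interval
.sim_ac <- function(nf, cfg) {
  lev <- cfg$ac_level * exp(stats::rnorm(1, 0, 0.2))
  base <- numeric(nf)
  b <- 0.35 * lev
  for (t in seq_len(nf)) {
    base[t] <- b
    b <- b + 0.15 * lev
    if (stats::runif(1) < 0.12) b <- b * stats::runif(1, 0.5, 0.7)
  }
  phi <- 0.6; psd <- 0.08 * lev
  x <- as.numeric(stats::filter(stats::rnorm(nf, 0, psd), phi,
                                method = "recursive"))
  base + x
}

# one CCP trace: fluctuating linear ramp to a plateau (reached within ~half
# the lifetime), OU fluctuation on the plateau, and a falling limb over a
# random 10-25% tail of the lifetime down to ~45% of the plateau
# (internalization removes the coat from the evanescent field before it
# decays to the detection floor)
.sim_ccp <- function(nf, cfg) {
  p <- stats::runif(1, cfg$ccp_plateau_range[1], cfg$ccp_plateau_range[2])
  t_rise <- max(2, min(p / cfg$ccp_growth_rate, 0.3 * nf))
  f_dec <- stats::runif(1, 0.10, 0.25)
  t_fall <- max(ceiling((1 - f_dec) * nf), 2L)
  tt <- seq_len(nf)
  base <- pmin(1 + (p - 1) * tt / t_rise, p)
  fall <- tt > t_fall
  if (any(fall))
    base[fall] <- base[t_fall] * (1 - 0.55 * (tt[fall] - t_fall) / max(1, nf - t_fall))
  jit <- exp(stats::rnorm(nf, 0, 0.05))
  phi <- 0.8; psd <- 0.04 * p
  ou <- as.numeric(stats::filter(stats::rnorm(nf, 0, psd), phi,
                                 method = "recursive"))
  # subunit exchange makes the assembly phase as fluctuating as the plateau
  ramp_n <- ifelse(tt <= t_rise + 1, stats::rnorm(nf, 0, 1.0), 0)
  base * jit + ou + ramp_n
}

# one OT trace: abnormally bright first detections decaying within a couple
# of frames to a dim residual that lingers (high-background region), giving
# the risk series its few large initial values
.sim_ot <- function(nf, cfg) {
  peak <- cfg$ot_peak * exp(stats::rnorm(1, 0, 0.10))
  tail_lev <- 0.5 * cfg$ac_level
  front <- peak * exp(-(seq_len(nf) - 1) / 1.5)
  x <- as.numeric(stats::filter(stats::rnorm(nf, 0, 0.10 * cfg$ac_level), 0.6,
                                method = "recursive"))
  pmax(front, tail_lev + x)
}

#' Simulate one condition of labeled synthetic traces
#'
#' Draws per-trace classes from the configured fractions, simulates each
#' class's trajectory shape, spreads traces uniformly over movies and start
#' frames, and truncates traces that would outlive the movie (flagged in the
#' truth table). Ground-truth labels, including the continuous lifetime
#' draws, are returned separately and never stored in the trace categories.
#'
#' @param config A \code{\link{dascSimConfig}}.
#' @param condition,day Labels stamped into the movie metadata.
#' @param movie_prefix Prefix for generated movie ids.
#' @return List with elements \code{traces} (a \linkS4class{TraceSet}) and
#'   \code{truth} (data.frame: movie_id, trace_id, true_label,
#'   true_lifetime_s, truncated).
#' @examples
#' sim <- simulateCondition(dascSimConfig(n_traces = 200, seed = 7))
#' table(sim$truth$true_label)
#' @export
simulateCondition <- function(config = dascSimConfig(), condition = "control",
                              day = "day1", movie_prefix = condition) {
  stopifnot(inherits(config, "dascSimConfig"))
  withSeed(config$seed, {
    n <- config$n_traces
    lab <- sample(c("AC", "CCP", "OT"), n, replace = TRUE,
                  prob = config$fractions)
    life <- numeric(n)
    # exponential-hazard disassembly is memoryless: a coat that survives the
    # tracker's 3-frame detection floor has a trackable lifetime of floor +
    # Exp(mean) exactly, so the emitted AC population carries the configured
    # exponential law in its excess lifetime
    life[lab == "AC"] <- 2.5 +
      stats::rexp(sum(lab == "AC"), 1 / config$ac_lifetime_mean)
    life[lab == "CCP"] <- .rrayleigh(sum(lab == "CCP"), config$ccp_lifetime_scale)
    # OTs are transient but must exceed the tracker's 3-frame floor to be
    # seen at all: minimum trackable length plus a short exponential tail
    ot_tail <- max(config$ot_lifetime_mean - 3, 0.5)
    life[lab == "OT"] <- 3 + stats::rexp(sum(lab == "OT"), 1 / ot_tail)
    fi <- 1
    Tn <- config$duration
    nf_drawn <- pmax(1L, pmin(as.integer(round(life / fi)), as.integer(Tn)))
    start <- sample.int(as.integer(Tn), n, replace = TRUE)
    nf <- pmin(nf_drawn, as.integer(Tn) - start + 1L)
    truncated <- nf < nf_drawn
    # the upstream tracker emits a valid trace only for >= 3 significant
    # consecutive detections; shorter structures are counted as invalid
    # (and the three risk-series features are degenerate below 3 frames)
    valid <- nf >= 3L
    movie <- sprintf("%s_m%02d", movie_prefix,
                     sample.int(config$movies, n, replace = TRUE))
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      if (!valid[i]) next
      y <- switch(lab[i],
                  AC = .sim_ac(nf[i], config),
                  CCP = .sim_ccp(nf[i], config),
                  OT = .sim_ot(nf[i], config))
      y <- y + stats::rnorm(nf[i], 0, config$noise_sd)
      traces[[i]] <- pmax(y, 0.01)
    }
    ids <- sprintf("t%06d", seq_len(n))
    movie_ids <- sprintf("%s_m%02d", movie_prefix, seq_len(config$movies))
    n_inv <- as.integer(table(factor(movie[!valid], levels = movie_ids)))
    md <- DataFrame(movie_id = movie_ids,
                    condition = condition, day = day,
                    cell_area_um2 = config$cell_area, duration_s = Tn,
                    frame_interval_s = fi, n_invalid = n_inv)
    td <- DataFrame(trace_id = ids[valid], movie_id = movie[valid],
                    start_frame = as.integer(start[valid]),
                    lifetime_s = nf[valid] * fi,
                    category = "unassigned", edge = FALSE,
                    intensity = IRanges::NumericList(traces[valid]))
    list(traces = TraceSet(td, md),
         truth = data.frame(movie_id = movie, trace_id = ids,
                            true_label = lab, true_lifetime_s = life,
                            valid = valid, truncated = truncated,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a control/perturbed pair of conditions
#'
#' The second condition uses the identical generator except that the CCP
#' fraction is reduced by \code{ccp_fraction_shift}, with the AC fraction
#' increased accordingly (emulating a stabilization defect).
#'
#' @param config A \code{\link{dascSimConfig}} for the control condition.
#' @param ccp_fraction_shift Probability mass moved from CCP to AC.
#' @param conditions Labels for the two conditions.
#' @return List with elements named after \code{conditions}, each as
#'   returned by \code{\link{simulateCondition}}.
#' @export
simulateTwoConditions <- function(config = dascSimConfig(),
                                  ccp_fraction_shift = 0,
                                  conditions = c("control", "perturbed")) {
  f <- config$fractions
  f2 <- c(f[1] + ccp_fraction_shift, f[2] - ccp_fraction_shift, f[3])
  if (any(f2 < 0) || any(f2 > 1))
    stop("config error: ccp_fraction_shift produces fractions outside [0, 1]")
  cfg2 <- config
  cfg2$fractions <- f2
  cfg2$seed <- config$seed + 1L
  out <- list(simulateCondition(config, condition = conditions[1]),
              simulateCondition(cfg2, condition = conditions[2]))
  names(out) <- conditions
  out
}
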