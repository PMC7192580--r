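#' Run the full classification pipeline on one day's conditions
#'
#' Executes the per-day analysis chain: quantize the control traces,
#' estimate the disassembly risk map from the control population, project
#' every condition's traces through that single map, compute and normalize
#' the DAS features with the control statistics, fit the k-medoids model on
#' the control, label its clusters, assign every condition's traces with the
#' control boundaries, flag edge traces, and compute per-movie metrics.
#'
#' @param control A \linkS4class{TraceSet} for the control condition.
#' @param conditions Named list of \linkS4class{TraceSet}s for experimental
#'   conditions measured on the same day (may be empty).
#' @param epsilon,min_count Risk-map pseudo-count and occupancy cutoff
#'   (see \code{\link{computeD}}).
#' @param k Cluster count (3 for AC/CCP/OT).
#' @param n_restarts k-medoids restarts.
#' @param edge_fraction Fraction of the AC+CCP pool flagged as edge traces.
#' @param min_lifetime Optional extra minimum lifetime (s) for traces
#'   entering the analysis; shorter traces are demoted to the invalid count
#'   (default 0: no cutoff beyond the upstream tracker's own).
#' @param seed RNG seed for the stochastic stages.
#' @return List of class \code{dascResult}:
#'   \code{map} (\linkS4class{DRiskMap}), \code{normalizer},
#'   \code{model} (\linkS4class{DasModel}), and per-condition (control
#'   first) \code{features}, \code{traces} (categorized TraceSets),
#'   \code{movie_metrics}, \code{edge}, \code{n_fallback}.
#' @examples
#' \donttest{
#' sim <- simulateTwoConditions(dascSimConfig(n_traces = 1500, seed = 3),
#'                              ccp_fraction_shift = 0.15)
#' res <- runDasc(sim$control$traces,
#'                list(perturbed = sim$perturbed$traces))
#' res$movie_metrics$perturbed$ccp_pct
#' }
#' @export
runDasc <- function(control, conditions = list(), epsilon = NULL,
                    min_count = 5L, k = 3L, n_restarts = 10L,
                    edge_fraction = 0.10, min_lifetime = 0, seed = 1L) {
  stopifnot(is(control, "TraceSet"))
  if (length(conditions) && is.null(names(conditions)))
    stop("conditions must be a named list")
  if (min_lifetime > 0) {
    control <- demoteShortTraces(control, min_lifetime)
    conditions <- lapply(conditions, demoteShortTraces, min_lifetime)
  }
  qc <- quantizeTraces(control)
  # the time grid must cover every condition's longest trace; cells beyond
  # the control's own support stay undefined and are served by fallback
  tmax <- max(vapply(c(list(control), conditions),
                     function(s) max(lifetimes(s) / frameInterval(s)),
                     numeric(1)))
  map <- suppressWarnings(
    dRiskMap(qc, epsilon = epsilon, min_count = min_count,
             tmax = ceiling(tmax),
             provenance = unique(movieData(control)$condition)[1]))
  all_sets <- c(list(control = control), conditions)
  feats <- vector("list", length(all_sets)); names(feats) <- names(all_sets)
  nfb <- integer(length(all_sets)); names(nfb) <- names(all_sets)
  for (nm in names(all_sets)) {
    q <- if (nm == "control") qc else quantizeTraces(all_sets[[nm]])
    pr <- projectTraces(map, q)
    nfb[[nm]] <- pr$n_fallback + pr$n_unresolved
    feats[[nm]] <- computeDasFeatures(pr$series, lifetimes = q@lifetime_s,
                                      trace_id = q@trace_id,
                                      movie_id = q@movie_id)
  }
  normalizer <- fitNormalizer(feats$control)
  feats <- lapply(feats, applyNormalizer, normalizer = normalizer)
  model <- fitKmedoids(feats$control, k = k, seed = seed,
                       n_restarts = n_restarts,
                       provenance = unique(movieData(control)$condition)[1])
  model <- labelClusters(model, feats$control)
  out_sets <- list(); metrics <- list(); edges <- list()
  for (nm in names(all_sets)) {
    ed <- findEdgeTraces(model, feats[[nm]], fraction = edge_fraction)
    ts <- all_sets[[nm]]
    categories(ts) <- ed$categories
    ts@traceData$edge <- ed$edge
    out_sets[[nm]] <- ts
    edges[[nm]] <- ed[c("ccp_pct_all", "ccp_pct_noedge")]
    metrics[[nm]] <- movieMetrics(ts)
  }
  structure(list(map = map, normalizer = normalizer, model = model,
                 features = feats, traces = out_sets,
                 movie_metrics = metrics, edge = edges, n_fallback = nfb,
                 seed = seed),
            class = "dascResult")
}

#' Demote traces below a minimum lifetime to the invalid count
#'
#' @param ts A \linkS4class{TraceSet}.
#' @param min_lifetime Minimum lifetime (s) a trace must reach to stay valid.
#' @return The filtered \code{TraceSet}; removed traces increment their
#'   movie's invalid count so total-trace accounting is preserved.
#' @export
demoteShortTraces <- function(ts, min_lifetime) {
  short <- lifetimes(ts) < min_lifetime
  if (!any(short)) return(ts)
  md <- ts@movieData
  extra <- table(factor(ts@traceData$movie_id[short], levels = md$movie_id))
  md$n_invalid <- md$n_invalid + as.integer(extra)
  new("TraceSet", traceData = ts@traceData[!short, , drop = FALSE],
      movieData = md)
}

#' @export
print.dascResult <- function(x, ...) {
  cat("DASC result (seed ", x$seed, ")\n", sep = "")
  show(x$map)
  show(x$model)
  for (nm in names(x$movie_metrics)) {
    mm <- x$movie_metrics[[nm]]
    cat(sprintf("  %-12s %2d movies | CCP%% %.1f | init %.2f /min/um^2\n",
                nm, nrow(mm), mean(mm$ccp_pct, na.rm = TRUE),
                mean(mm$cs_init_rate)))
  }
  invisible(x)
}
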