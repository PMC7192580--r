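#' Quantize traces into integer intensity-state chains
#'
#' Every intensity value is rounded half-up to its nearest integer state and
#' clamped below at state 1; traces are aligned to their first detection
#' (chain position 1). \code{imax} is the largest state over the whole
#' collection, which by the pooling convention should be one condition-day.
#'
#' @param ts A \linkS4class{TraceSet}.
#' @return A \linkS4class{QuantizedTraces}.
#' @examples
#' md <- data.frame(movie_id = "m", condition = "c", day = "d",
#'                  cell_area_um2 = 1, duration_s = 10,
#'                  frame_interval_s = 1, n_invalid = 0L)
#' td <- data.frame(trace_id = "t", movie_id = "m")
#' td$intensity <- list(c(2.4, 7.5, 7.49))
#' states(quantizeTraces(TraceSet(td, md)))[[1]]  # 2 8 7
#' @export
quantizeTraces <- function(ts) {
  stopifnot(is(ts, "TraceSet"))
  v <- unlist(ts@traceData$intensity, use.names = FALSE)
  if (length(v) && !all(is.finite(v))) {
    nf <- lengths(ts@traceData$intensity)
    bad <- unique(rep(ts@traceData$trace_id, nf)[!is.finite(v)])
    stop("data error: non-finite intensity in trace(s) ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  q <- pmax(1L, as.integer(floor(v + 0.5)))  # half-up rounding, floor at 1
  states <- IRanges::relist(q, ts@traceData$intensity)
  new("QuantizedTraces", states = IRanges::IntegerList(states),
      trace_id = ts@traceData$trace_id, movie_id = ts@traceData$movie_id,
      lifetime_s = ts@traceData$lifetime_s,
      imax = if (length(q)) max(q) else 0L,
      frame_interval = frameInterval(ts))
}

#' @rdname QuantizedTraces-accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname QuantizedTraces-accessors
#' @export
setGeneric("imax", function(x) standardGeneric("imax"))

#' Accessors for QuantizedTraces
#' @param x A \linkS4class{QuantizedTraces}.
#' @name QuantizedTraces-accessors
NULL
#' @rdname QuantizedTraces-accessors
setMethod("states", "QuantizedTraces", function(x) x@states)
#' @rdname QuantizedTraces-accessors
setMethod("imax", "QuantizedTraces", function(x) x@imax)
#' @rdname QuantizedTraces-accessors
setMethod("imax", "DRiskMap", function(x) x@imax)

setMethod("show", "QuantizedTraces", function(object) {
  cat("QuantizedTraces:", length(object@states), "trace(s), imax =",
      object@imax, "\n")
})

#' Estimate time-resolved transition probabilities from a control population
#'
#' For every intensity-time state (i, t), counts the occupancy N(i, t) over
#' all first-frame-aligned traces, the aggregate conditional probability of
#' a drop to any lower state between t and t+1 (\code{downMass}), and the
#' aggregate probability of arrival at i from any lower state
#' (\code{upMass}, each arrival weighted by the occupancy of its source
#' state). These are the two terms whose log-ratio defines the disassembly
#' risk. A warning is emitted when fewer than 200,000 traces are supplied,
#' the population size needed for stable estimates in practice.
#'
#' @param qts \linkS4class{QuantizedTraces} from the control condition.
#' @param tmax Time grid length; defaults to the longest trace.
#' @param provenance Label stored in the map (control condition/day).
#' @return A \linkS4class{DRiskMap} with occupancy and transition-mass
#'   fields populated and \code{D} empty (see \code{\link{computeD}}).
#' @export
estimateTransitions <- function(qts, tmax = NULL, provenance = "control") {
  stopifnot(is(qts, "QuantizedTraces"))
  n <- length(qts@states)
  if (n == 0L) stop("empty trace collection")
  if (n < 200000L)
    warning("only ", n, " traces; >200,000 control traces are typically ",
            "needed for stable transition probabilities", call. = FALSE)
  nf <- lengths(qts@states)
  if (is.null(tmax)) tmax <- max(nf)
  tmax <- as.integer(tmax)
  im <- qts@imax
  s <- unlist(qts@states, use.names = FALSE)
  tt <- sequence(nf)                       # within-trace frame position
  keep <- tt <= tmax
  cell <- (tt[keep] - 1L) * im + s[keep]   # linear (i, t) index
  N <- matrix(tabulate(cell, nbins = im * tmax), nrow = im)
  # transition pairs: all frames except each trace's last
  last <- cumsum(nf)
  is_last <- logical(length(s)); is_last[last] <- TRUE
  cur <- s[!is_last]; nxt <- s[which(!is_last) + 1L]; t0 <- tt[!is_last]
  ok <- t0 < tmax
  cur <- cur[ok]; nxt <- nxt[ok]; t0 <- t0[ok]
  dn <- nxt < cur
  down_cnt <- matrix(tabulate((t0[dn] - 1L) * im + cur[dn],
                              nbins = im * tmax), nrow = im)
  downMass <- down_cnt / ifelse(N > 0, N, NA_real_)
  up <- nxt > cur
  wt <- 1 / N[cbind(cur[up], t0[up])]      # 1 / N(source state, t)
  upv <- numeric(im * tmax)
  if (any(up)) {
    agg <- rowsum(wt, group = (t0[up] - 1L) * im + nxt[up])
    upv[as.integer(rownames(agg))] <- agg[, 1L]
  }
  upMass <- matrix(upv, nrow = im)
  downMass[N == 0] <- NA_real_
  upMass[N == 0] <- NA_real_
  new("DRiskMap", D = matrix(numeric(0), 0, 0), N = N,
      downMass = downMass, upMass = upMass, imax = im, tmax = tmax,
      epsilon = NA_real_, minCount = 5L, nTraces = n,
      provenance = provenance)
}

#' Compute the disassembly risk function D(i, t)
#'
#' D(i, t) = log(downMass + eps) - log(upMass + eps): positive where
#' clathrin loss outweighs gain, negative where structures are still
#' assembling, near zero for plateau fluctuation. Cells with occupancy
#' below \code{min_count} are left undefined (NA); the bottom row D(1, t)
#' is identically 0 since state 1 has no lower states.
#'
#' @param map \linkS4class{DRiskMap} with transition fields populated.
#' @param epsilon Pseudo-count guarding log(0). \code{NULL} (default) uses
#'   the adaptive per-cell value 1/N(i, t); 0 reproduces the raw log-ratio
#'   (undefined cells become +/-Inf-free NA only via min_count).
#' @param min_count Minimum occupancy N(i, t) for a defined cell.
#' @return The map with \code{D} populated.
#' @export
computeD <- function(map, epsilon = NULL, min_count = 5L) {
  stopifnot(is(map, "DRiskMap"))
  eps <- if (is.null(epsilon)) 1 / map@N else epsilon
  D <- log(map@downMass + eps) - log(map@upMass + eps)
  D[map@N < min_count] <- NA_real_
  if (map@imax >= 1L) D[1L, ] <- 0
  D[!is.finite(D) & !is.na(D)] <- NA_real_
  map@D <- D
  map@epsilon <- if (is.null(epsilon)) NA_real_ else as.numeric(epsilon)
  map@minCount <- as.integer(min_count)
  validObject(map)
  map
}

#' One-shot disassembly risk map from control traces
#'
#' @inheritParams estimateTransitions
#' @inheritParams computeD
#' @return A \linkS4class{DRiskMap} with \code{D} populated.
#' @export
dRiskMap <- function(qts, epsilon = NULL, min_count = 5L, tmax = NULL,
                     provenance = "control") {
  computeD(estimateTransitions(qts, tmax = tmax, provenance = provenance),
           epsilon = epsilon, min_count = min_count)
}

setMethod("show", "DRiskMap", function(object) {
  cat("DRiskMap:", object@imax, "states x", object@tmax, "frames",
      "(", object@nTraces, "traces, provenance:", object@provenance, ")\n")
  if (length(object@D)) {
    def <- mean(!is.na(object@D)) * 100
    cat(sprintf("  D defined on %.1f%% of cells; min_count = %d\n",
                def, object@minCount))
  } else cat("  D not yet computed\n")
})

#' Project quantized traces into disassembly-risk series
#'
#' Substitutes each trace's state at each frame into the D map. The first
#' frame is 0 by convention (first detection carries no disassembly risk).
#' Frames that hit an undefined map cell fall back to the nearest defined
#' intensity state at the same time (ties to the lower state), then to the
#' nearest defined time at the same state; fallback events are counted.
#'
#' @param map A computed \linkS4class{DRiskMap}.
#' @param qts \linkS4class{QuantizedTraces} (same quantization convention).
#' @param fallback If FALSE, any undefined lookup beyond frame 1 is an
#'   error listing the offending frames.
#' @return List with \code{series} (\link[IRanges]{NumericList}, one risk
#'   series per trace), \code{n_fallback} (frames resolved by fallback) and
#'   \code{n_unresolved} (frames left at 0 because no defined cell shares
#'   the state or the time).
#' @export
projectTraces <- function(map, qts, fallback = TRUE) {
  stopifnot(is(map, "DRiskMap"), is(qts, "QuantizedTraces"))
  if (!length(map@D)) stop("map has no D computed; call computeD() first")
  nf <- lengths(qts@states)
  if (length(nf) && max(nf) > map@tmax)
    stop("trace longer than the map's time grid (", map@tmax, " frames)")
  s <- unlist(qts@states, use.names = FALSE)
  tt <- sequence(nf)
  v <- rep(NA_real_, length(s))
  inmap <- s <= map@imax
  v[inmap] <- map@D[cbind(s[inmap], tt[inmap])]
  first <- c(1L, utils::head(cumsum(nf), -1L) + 1L)[seq_along(nf)]
  v[first[nf > 0]] <- 0
  nafr <- which(is.na(v))
  n_fb <- 0L; n_un <- 0L
  if (length(nafr)) {
    if (!fallback) {
      tr <- rep(qts@trace_id, nf)[nafr]
      stop("undefined disassembly risk at ", length(nafr), " frame(s) with ",
           "fallback disabled; first offenders: ",
           paste(utils::head(paste0(tr, "@t", tt[nafr]), 5), collapse = ", "))
    }
    def <- !is.na(map@D)
    for (ix in nafr) {
      i <- min(s[ix], map@imax); t <- tt[ix]
      rows <- which(def[, t])
      if (length(rows)) {
        d <- abs(rows - i)
        v[ix] <- map@D[rows[order(d, rows)][1L], t]  # tie -> lower state
        n_fb <- n_fb + 1L
      } else {
        cols <- which(def[i, ])
        if (length(cols)) {
          dd <- abs(cols - t)
          v[ix] <- map@D[i, cols[order(dd, cols)][1L]]
          n_fb <- n_fb + 1L
        } else {
          v[ix] <- 0
          n_un <- n_un + 1L
        }
      }
    }
  }
  list(series = IRanges::NumericList(IRanges::relist(v, qts@states)),
       n_fallback = n_fb, n_unresolved = n_un)
}

#' Serialize / restore a disassembly risk map
#'
#' Writes the map (matrices plus metadata) as JSON, mirroring the grayscale
#' intensity-state-by-time rendering used for visual inspection.
#'
#' @param map A \linkS4class{DRiskMap}.
#' @param path JSON file path.
#' @export
writeDRiskMap <- function(map, path) {
  stopifnot(is(map, "DRiskMap"))
  obj <- list(imax = map@imax, tmax = map@tmax, epsilon = map@epsilon,
              min_count = map@minCount, n_traces = map@nTraces,
              provenance = map@provenance, D = map@D, N = map@N,
              down_mass = map@downMass, up_mass = map@upMass)
  jsonlite::write_json(obj, path, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDRiskMap
#' @export
readDRiskMap <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    matrix(m, nrow = o$imax)
  }
  new("DRiskMap", D = as_mat(o$D), N = as_mat(o$N),
      downMass = as_mat(o$down_mass), upMass = as_mat(o$up_mass),
      imax = as.integer(o$imax), tmax = as.integer(o$tmax),
      epsilon = as.numeric(o$epsilon), minCount = as.integer(o$min_count),
      nTraces = as.integer(o$n_traces), provenance = o$provenance)
}
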