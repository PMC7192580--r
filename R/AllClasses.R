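#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges NumericList IntegerList
NULL

.CATEGORIES <- c("unassigned", "AC", "CCP", "OT")

#' TraceSet: valid clathrin-structure traces and their movie metadata
#'
#' A \code{TraceSet} holds the valid fluorescence intensity traces of one or
#' more movies, together with per-movie metadata. Intensities are stored as a
#' ragged \link[IRanges]{NumericList}, one element per trace, sampled at the
#' movie frame interval (1 s by default). Invalid traces (not always
#' diffraction-limited, or containing consecutive detection gaps) are kept
#' only as per-movie counts: they enter the initiation rate through the total
#' trace count but are excluded from all downstream risk analysis.
#'
#' @slot traceData \code{DataFrame} with one row per valid trace: columns
#'   \code{trace_id}, \code{movie_id}, \code{start_frame}, \code{lifetime_s},
#'   \code{category} (one of \code{unassigned}, \code{AC}, \code{CCP},
#'   \code{OT}), \code{edge} (logical), \code{intensity}
#'   (\code{NumericList}) and optionally \code{intensity2} for a second
#'   channel of equal length.
#' @slot movieData \code{DataFrame} with one row per movie: columns
#'   \code{movie_id}, \code{condition}, \code{day}, \code{cell_area_um2},
#'   \code{duration_s}, \code{frame_interval_s}, \code{n_invalid}.
#'
#' @seealso \code{\link{readTraces}}, \code{\link{simulateCondition}}
#' @export
setClass("TraceSet", slots = c(traceData = "DataFrame", movieData = "DataFrame"))

setValidity("TraceSet", function(object) {
  td <- object@traceData
  md <- object@movieData
  msgs <- character()
  need_td <- c("trace_id", "movie_id", "start_frame", "lifetime_s",
               "category", "edge", "intensity")
  need_md <- c("movie_id", "condition", "day", "cell_area_um2",
               "duration_s", "frame_interval_s", "n_invalid")
  if (!all(need_td %in% colnames(td)))
    msgs <- c(msgs, paste0("traceData lacks column(s): ",
                           paste(setdiff(need_td, colnames(td)), collapse = ", ")))
  if (!all(need_md %in% colnames(md)))
    msgs <- c(msgs, paste0("movieData lacks column(s): ",
                           paste(setdiff(need_md, colnames(md)), collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(md$movie_id))
    msgs <- c(msgs, "duplicated movie_id in movieData")
  if (nrow(td)) {
    if (!all(td$movie_id %in% md$movie_id))
      msgs <- c(msgs, "traceData references movie_id absent from movieData")
    if (anyDuplicated(paste(td$movie_id, td$trace_id, sep = "\r")))
      msgs <- c(msgs, "duplicated (movie_id, trace_id)")
    if (!all(td$category %in% .CATEGORIES))
      msgs <- c(msgs, "category outside {unassigned, AC, CCP, OT}")
    nf <- lengths(td$intensity)
    if (any(nf < 1L))
      msgs <- c(msgs, "trace with zero frames")
    fi <- md$frame_interval_s[match(td$movie_id, md$movie_id)]
    if (any(abs(td$lifetime_s - nf * fi) > 1e-8))
      msgs <- c(msgs, "lifetime_s inconsistent with frame count * frame interval")
    if (!all(is.finite(unlist(td$intensity, use.names = FALSE))))
      msgs <- c(msgs, "non-finite intensity values")
    if (!is.null(td$intensity2) && any(lengths(td$intensity2) != nf))
      msgs <- c(msgs, "secondary channel length differs from primary")
  }
  if (any(md$cell_area_um2 <= 0)) msgs <- c(msgs, "cell_area_um2 must be > 0")
  if (any(md$duration_s <= 0)) msgs <- c(msgs, "duration_s must be > 0")
  if (any(md$frame_interval_s <= 0)) msgs <- c(msgs, "frame_interval_s must be > 0")
  if (any(md$n_invalid < 0)) msgs <- c(msgs, "n_invalid must be >= 0")
  if (length(unique(md$frame_interval_s)) > 1L)
    msgs <- c(msgs, "all movies in a TraceSet must share frame_interval_s")
  if (length(msgs)) msgs else TRUE
})

#' QuantizedTraces: integer-state chains derived from a TraceSet
#'
#' Each trace is aligned to its first statistically significant detection
#' (frame 1) and every intensity is rounded half-up to the nearest integer
#' state, clamped below at state 1. \code{imax} is the largest state observed
#' across the whole collection.
#'
#' @slot states \code{IntegerList}, one integer chain per trace.
#' @slot trace_id,movie_id character vectors parallel to \code{states}.
#' @slot lifetime_s numeric, trace lifetimes in seconds.
#' @slot imax integer, largest quantized state in the collection.
#' @slot frame_interval numeric, seconds between frames.
#' @export
setClass("QuantizedTraces",
         slots = c(states = "IntegerList", trace_id = "character",
                   movie_id = "character", lifetime_s = "numeric",
                   imax = "integer", frame_interval = "numeric"))

setValidity("QuantizedTraces", function(object) {
  n <- length(object@states)
  if (length(object@trace_id) != n || length(object@movie_id) != n ||
      length(object@lifetime_s) != n)
    return("parallel slots of unequal length")
  s <- unlist(object@states, use.names = FALSE)
  if (length(s) && min(s) < 1L) return("states below 1")
  if (length(s) && max(s) > object@imax) return("state exceeds imax")
  TRUE
})

#' DRiskMap: disassembly risk function over intensity states and time
#'
#' Discretizes the net risk of disassembly D(i,t) on the grid of integer
#' intensity states i = 1..imax and frame-aligned times t = 1..tmax.
#' \code{downMass(i,t)} aggregates the conditional probability of dropping
#' from state i to any lower state between t and t+1; \code{upMass(i,t)}
#' aggregates the probability of arriving at state i from any lower state.
#' D = log(downMass) - log(upMass), stabilized by a pseudo-count and left
#' undefined (NA) where the occupancy N(i,t) is below \code{minCount}.
#' Row i = 1 is identically 0: state 1 has no lower states, consistent with
#' a first detection carrying zero disassembly risk.
#'
#' @slot D,N,downMass,upMass matrices of dimension imax x tmax.
#' @slot imax,tmax integer grid dimensions.
#' @slot epsilon numeric pseudo-count; \code{NA} means the adaptive default
#'   1/N(i,t) per cell.
#' @slot minCount integer, minimum occupancy for a defined cell.
#' @slot nTraces integer, number of traces the map was estimated from.
#' @slot provenance character label (control condition / day).
#' @export
setClass("DRiskMap",
         slots = c(D = "matrix", N = "matrix", downMass = "matrix",
                   upMass = "matrix", imax = "integer", tmax = "integer",
                   epsilon = "numeric", minCount = "integer",
                   nTraces = "integer", provenance = "character"))

setValidity("DRiskMap", function(object) {
  dm <- c(object@imax, object@tmax)
  for (nm in c("N", "downMass", "upMass")) {
    if (!identical(dim(slot(object, nm)), as.integer(dm)))
      return(paste(nm, "has wrong dimensions"))
  }
  if (length(object@D) && !identical(dim(object@D), as.integer(dm)))
    return("D has wrong dimensions")
  dmv <- object@downMass[object@N > 0]
  if (length(dmv) && (min(dmv, na.rm = TRUE) < 0 || max(dmv, na.rm = TRUE) > 1 + 1e-9))
    return("downMass outside [0, 1]")
  TRUE
})

#' DasModel: fitted k-medoids classifier in normalized feature space
#'
#' @slot k integer number of clusters.
#' @slot medoids k x 3 matrix of medoid coordinates in (d1n, d2n, d3n).
#' @slot medoidIndex integer row indices of the medoids in the fitting data.
#' @slot assignment integer cluster index of every fitted point.
#' @slot totalDistance numeric, sum of Euclidean distances of fitted points
#'   to their host medoids.
#' @slot labelMap character of length k mapping cluster index to
#'   \code{AC}/\code{CCP}/\code{OT} (NA before semantic labeling).
#' @slot seed numeric RNG seed used for the fit.
#' @slot provenance character label (control condition / day).
#' @export
setClass("DasModel",
         slots = c(k = "integer", medoids = "matrix", medoidIndex = "integer",
                   assignment = "integer", totalDistance = "numeric",
                   labelMap = "character", seed = "numeric",
                   provenance = "character"))

setValidity("DasModel", function(object) {
  if (nrow(object@medoids) != object@k) return("medoids rows != k")
  if (anyDuplicated(object@medoids)) return("medoids not distinct")
  if (length(object@labelMap) != object@k) return("labelMap length != k")
  lm_ok <- is.na(object@labelMap) | object@labelMap %in% c("AC", "CCP", "OT")
  if (!all(lm_ok)) return("labelMap values outside {AC, CCP, OT, NA}")
  if (object@k == 3L && !anyNA(object@labelMap) &&
      !setequal(object@labelMap, c("AC", "CCP", "OT")))
    return("labelMap must be a bijection onto {AC, CCP, OT} for k = 3")
  TRUE
})
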