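#' Construct a TraceSet
#'
#' @param traceData \code{DataFrame} (or data.frame with an
#'   \code{intensity} list column) of valid traces; see
#'   \linkS4class{TraceSet} for required columns. \code{start_frame},
#'   \code{category} and \code{edge} are filled with defaults when absent.
#' @param movieData \code{DataFrame}/data.frame of per-movie metadata.
#' @return A \linkS4class{TraceSet}.
#' @examples
#' md <- data.frame(movie_id = "m1", condition = "ctrl", day = "d1",
#'                  cell_area_um2 = 300, duration_s = 451,
#'                  frame_interval_s = 1, n_invalid = 0L)
#' td <- data.frame(trace_id = "t1", movie_id = "m1")
#' td$intensity <- list(c(1, 2, 3))
#' ts <- TraceSet(td, md)
#' nTraces(ts)
#' @export
TraceSet <- function(traceData, movieData) {
  td <- DataFrame(traceData)
  md <- DataFrame(movieData)
  if (!is(td$intensity, "NumericList"))
    td$intensity <- IRanges::NumericList(lapply(td$intensity, as.numeric))
  if (!is.null(td$intensity2) && !is(td$intensity2, "NumericList"))
    td$intensity2 <- IRanges::NumericList(lapply(td$intensity2, as.numeric))
  if (is.null(td$start_frame)) td$start_frame <- 1L
  fi <- md$frame_interval_s[match(td$movie_id, md$movie_id)]
  if (is.null(td$lifetime_s)) td$lifetime_s <- lengths(td$intensity) * fi
  if (is.null(td$category)) td$category <- "unassigned"
  if (is.null(td$edge)) td$edge <- FALSE
  td$trace_id <- as.character(td$trace_id)
  td$movie_id <- as.character(td$movie_id)
  md$movie_id <- as.character(md$movie_id)
  md$n_invalid <- as.integer(md$n_invalid)
  new("TraceSet", traceData = td[, union(c("trace_id", "movie_id", "start_frame",
        "lifetime_s", "category", "edge", "intensity"), colnames(td))],
      movieData = md)
}

#' @rdname TraceSet-accessors
#' @export
setGeneric("nTraces", function(x) standardGeneric("nTraces"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("intensityList", function(x, channel = 1L) standardGeneric("intensityList"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("categories<-", function(x, value) standardGeneric("categories<-"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname TraceSet-accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' Accessors for TraceSet objects
#'
#' \code{nTraces} counts valid traces; \code{nTotal} returns the per-movie
#' total trace count (valid + invalid) used for the initiation rate;
#' \code{intensityList} returns the ragged intensity series
#' (\code{channel = 2} for the optional second channel); \code{categories}
#' gets/sets per-trace classification labels.
#'
#' @param x A \linkS4class{TraceSet}.
#' @param channel Intensity channel, 1 (default) or 2.
#' @param value Character vector of categories, one per trace.
#' @name TraceSet-accessors
NULL

#' @rdname TraceSet-accessors
setMethod("nTraces", "TraceSet", function(x) nrow(x@traceData))
#' @rdname TraceSet-accessors
setMethod("traceData", "TraceSet", function(x) x@traceData)
#' @rdname TraceSet-accessors
setMethod("movieData", "TraceSet", function(x) x@movieData)
#' @rdname TraceSet-accessors
setMethod("intensityList", "TraceSet", function(x, channel = 1L) {
  if (channel == 1L) return(x@traceData$intensity)
  if (is.null(x@traceData$intensity2))
    stop("TraceSet has no secondary channel")
  x@traceData$intensity2
})
#' @rdname TraceSet-accessors
setMethod("lifetimes", "TraceSet", function(x) x@traceData$lifetime_s)
#' @rdname TraceSet-accessors
setMethod("categories", "TraceSet", function(x) x@traceData$category)
#' @rdname TraceSet-accessors
setMethod("categories<-", "TraceSet", function(x, value) {
  stopifnot(length(value) == nTraces(x))
  x@traceData$category <- as.character(value)
  validObject(x)
  x
})
#' @rdname TraceSet-accessors
setMethod("frameInterval", "TraceSet", function(x) {
  if (nrow(x@movieData)) x@movieData$frame_interval_s[1L] else 1
})
#' @rdname TraceSet-accessors
setMethod("nTotal", "TraceSet", function(x) {
  nv <- table(factor(x@traceData$movie_id, levels = x@movieData$movie_id))
  as.integer(nv) + x@movieData$n_invalid
})

#' @describeIn TraceSet-accessors subset a TraceSet by trace index (movie
#'   metadata is retained in full so per-movie counts stay interpretable).
#' @param i Trace indices (integer or logical).
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "TraceSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, traceData = x@traceData[i, , drop = FALSE])
})

setMethod("show", "TraceSet", function(object) {
  md <- object@movieData
  cat("TraceSet with", nTraces(object), "valid trace(s) in", nrow(md),
      "movie(s)\n")
  cat("  condition(s):", paste(unique(md$condition), collapse = ", "), "\n")
  cat("  day(s):      ", paste(unique(md$day), collapse = ", "), "\n")
  cat("  invalid traces:", sum(md$n_invalid),
      " | frame interval:", frameInterval(object), "s\n")
  tb <- table(factor(categories(object), levels = .CATEGORIES))
  cat("  categories:  ", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

#' Split a multi-condition TraceSet by condition label
#'
#' @param x A \linkS4class{TraceSet}.
#' @return Named list of single-condition \code{TraceSet}s.
#' @export
splitByCondition <- function(x) {
  stopifnot(is(x, "TraceSet"))
  conds <- unique(x@movieData$condition)
  out <- lapply(conds, function(cc) {
    md <- x@movieData[x@movieData$condition == cc, , drop = FALSE]
    td <- x@traceData[x@traceData$movie_id %in% md$movie_id, , drop = FALSE]
    new("TraceSet", traceData = td, movieData = md)
  })
  names(out) <- conds
  out
}

.required_trace_cols <- c("condition", "day", "movie_id", "trace_id",
                          "frame", "intensity_au", "valid")
.required_movie_cols <- c("movie_id", "condition", "day", "cell_area_um2",
                          "duration_s", "frame_interval_s", "n_invalid")

#' Read trace and movie tables into TraceSets
#'
#' Reads the delimited long-format trace table (one row per trace per frame)
#' and the per-movie metadata table, assembles valid traces, and returns one
#' \linkS4class{TraceSet} per condition. Traces flagged valid but containing
#' a gap in their frame sequence are demoted to the invalid count with a
#' warning; truly invalid rows (\code{valid = 0}) only increment the invalid
#' count. An optional \code{channel} column (default 1) carries a second
#' intensity channel.
#'
#' @param trace_table_path CSV with columns \code{condition, day, movie_id,
#'   trace_id, frame, intensity_au, valid} and optional \code{channel}.
#' @param movie_table_path CSV with columns \code{movie_id, condition, day,
#'   cell_area_um2, duration_s, frame_interval_s, n_invalid}.
#' @return Named list of \linkS4class{TraceSet}, one per condition.
#' @export
readTraces <- function(trace_table_path, movie_table_path) {
  tr <- utils::read.csv(trace_table_path, stringsAsFactors = FALSE)
  mv <- utils::read.csv(movie_table_path, stringsAsFactors = FALSE)
  miss <- setdiff(.required_trace_cols, colnames(tr))
  if (nrow(tr) && length(miss))
    stop("trace table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  miss <- setdiff(.required_movie_cols, colnames(mv))
  if (length(miss))
    stop("movie table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  mv$movie_id <- as.character(mv$movie_id)
  if (nrow(tr) == 0L) {
    out <- lapply(split(mv, mv$condition), function(md) {
      TraceSet(DataFrame(trace_id = character(), movie_id = character(),
                         start_frame = integer(), lifetime_s = numeric(),
                         category = character(), edge = logical(),
                         intensity = IRanges::NumericList()),
               md)
    })
    return(out)
  }
  if (is.null(tr$channel)) tr$channel <- 1L
  tr$movie_id <- as.character(tr$movie_id)
  tr$trace_id <- as.character(tr$trace_id)
  key <- paste(tr$movie_id, tr$trace_id, tr$channel, sep = "\r")
  # frames must arrive in strictly increasing order within a trace/channel
  ord_ok <- unlist(lapply(split(tr$frame, key), function(f) all(diff(f) > 0)),
                   use.names = TRUE)
  if (!all(ord_ok))
    stop("integrity error: non-monotone frame indices for trace(s) ",
         paste(gsub("\r", "/", names(ord_ok)[!ord_ok])[1:min(3, sum(!ord_ok))],
               collapse = ", "))
  ch1 <- tr[tr$channel == 1L, , drop = FALSE]
  ch2 <- tr[tr$channel == 2L, , drop = FALSE]
  k1 <- paste(ch1$movie_id, ch1$trace_id, sep = "\r")
  idx <- split(seq_len(nrow(ch1)), k1)
  first <- vapply(idx, `[`, integer(1), 1L)
  info <- data.frame(key = names(idx),
                     movie_id = ch1$movie_id[first],
                     trace_id = ch1$trace_id[first],
                     start_frame = vapply(idx, function(ii) as.integer(ch1$frame[ii][1L]), integer(1)),
                     valid = vapply(idx, function(ii) all(ch1$valid[ii] != 0), logical(1)),
                     gap = vapply(idx, function(ii) any(diff(ch1$frame[ii]) > 1), logical(1)),
                     stringsAsFactors = FALSE)
  demoted <- info$valid & info$gap
  if (any(demoted))
    warning("integrity warning: ", sum(demoted),
            " trace(s) flagged valid but containing consecutive-frame gaps; ",
            "demoted to the invalid count")
  keep <- info$valid & !info$gap
  extra_invalid <- tapply(!keep, info$movie_id, sum)
  mv$n_invalid <- mv$n_invalid +
    ifelse(is.na(extra_invalid[mv$movie_id]), 0L, extra_invalid[mv$movie_id])
  ints <- IRanges::NumericList(unname(lapply(idx[keep],
                                             function(ii) ch1$intensity_au[ii])))
  td <- DataFrame(trace_id = info$trace_id[keep],
                  movie_id = info$movie_id[keep],
                  start_frame = info$start_frame[keep],
                  category = "unassigned", edge = FALSE,
                  intensity = ints)
  if (nrow(ch2)) {
    k2 <- paste(ch2$movie_id, ch2$trace_id, sep = "\r")
    idx2 <- split(seq_len(nrow(ch2)), k2)
    m <- match(info$key[keep], names(idx2))
    l2 <- lapply(seq_along(m), function(i) {
      if (is.na(m[i])) numeric(lengths(ints)[i]) * NA_real_
      else ch2$intensity_au[idx2[[m[i]]]]
    })
    td$intensity2 <- IRanges::NumericList(l2)
  }
  fi <- mv$frame_interval_s[match(td$movie_id, mv$movie_id)]
  td$lifetime_s <- lengths(td$intensity) * fi
  if (any(mv$frame_interval_s != 1))
    warning("frame interval differs from 1 s; disassembly risk estimation ",
            "assumes sampling near the ~2 s clathrin exchange timescale")
  out <- lapply(split(seq_len(nrow(mv)), mv$condition), function(ii) {
    md <- mv[ii, , drop = FALSE]
    TraceSet(td[td$movie_id %in% md$movie_id, , drop = FALSE], md)
  })
  out
}

#' Write a TraceSet back to long-format trace and movie tables
#'
#' Inverse of \code{\link{readTraces}}: the written tables read back into an
#' identical \code{TraceSet} (at full double precision).
#'
#' @param ts A \linkS4class{TraceSet}.
#' @param trace_table_path,movie_table_path Output CSV paths.
#' @export
writeTraces <- function(ts, trace_table_path, movie_table_path) {
  stopifnot(is(ts, "TraceSet"))
  td <- ts@traceData
  md <- ts@movieData
  nf <- lengths(td$intensity)
  long <- data.frame(
    condition = rep(md$condition[match(td$movie_id, md$movie_id)], nf),
    day = rep(md$day[match(td$movie_id, md$movie_id)], nf),
    movie_id = rep(td$movie_id, nf),
    trace_id = rep(td$trace_id, nf),
    frame = unlist(lapply(seq_along(nf), function(i)
      td$start_frame[i] + seq_len(nf[i]) - 1L), use.names = FALSE),
    intensity_au = unlist(td$intensity, use.names = FALSE),
    valid = 1L, channel = 1L)
  if (!is.null(td$intensity2)) {
    long2 <- long
    long2$intensity_au <- unlist(td$intensity2, use.names = FALSE)
    long2$channel <- 2L
    long <- rbind(long, long2)
  }
  utils::write.csv(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                   trace_table_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(md[, .required_movie_cols], movie_table_path,
                   row.names = FALSE, quote = FALSE)
  invisible(trace_table_path)
}

#' Write classification results
#'
#' One row per valid trace with its category, edge flag and DAS features.
#' Refuses to write while unassigned categories remain unless
#' \code{force = TRUE}.
#'
#' @param ts A categorized \linkS4class{TraceSet}.
#' @param features Feature data.frame from \code{\link{computeDasFeatures}}
#'   (matched by movie_id/trace_id), or NULL to write categories only.
#' @param path Output CSV path.
#' @param force Write even if some traces are unassigned.
#' @export
writeClassification <- function(ts, features = NULL, path, force = FALSE) {
  stopifnot(is(ts, "TraceSet"))
  td <- ts@traceData
  if (!force && nrow(td) && any(td$category == "unassigned"))
    stop("unassigned categories present; classify first or use force = TRUE")
  md <- ts@movieData
  nr <- nrow(td)
  out <- data.frame(condition = md$condition[match(td$movie_id, md$movie_id)],
                    day = md$day[match(td$movie_id, md$movie_id)],
                    movie_id = as.character(td$movie_id),
                    trace_id = as.character(td$trace_id),
                    lifetime_s = as.numeric(td$lifetime_s),
                    category = as.character(td$category),
                    edge = as.integer(td$edge),
                    d1 = rep(NA_real_, nr), d2 = rep(NA_real_, nr),
                    d3 = rep(NA_real_, nr), stringsAsFactors = FALSE)
  if (!is.null(features) && nrow(out)) {
    m <- match(paste(out$movie_id, out$trace_id),
               paste(features$movie_id, features$trace_id))
    out$d1 <- features$d1[m]; out$d2 <- features$d2[m]; out$d3 <- features$d3[m]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classification table written by \code{writeClassification}
#'
#' @param path CSV path.
#' @return data.frame with one row per trace.
#' @export
readClassification <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(movie_id = "character", trace_id = "character"))
}
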