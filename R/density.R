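#' Max-normalized 2D feature density (DAS plot)
#'
#' Bins the (d1, d2) features on a fixed grid (bin widths 0.2 and 0.5,
#' origin anchored at 0), converts counts to a probability density, and
#' normalizes by the density maximum so the modal cell equals 1. When
#' categories are supplied, the AC and CCP modal cells are located as the
#' per-category argmax cells.
#'
#' @param features Feature data.frame; raw \code{d1}/\code{d2} are used by
#'   default (\code{normalized = TRUE} switches to d1n/d2n).
#' @param d1_width,d2_width Bin widths.
#' @param d1_range,d2_range Optional c(lo, hi) forcing a common grid across
#'   conditions (snapped outward to bin-width multiples).
#' @param categories Optional per-row AC/CCP/OT labels for mode location.
#' @param normalized Use normalized features instead of raw.
#' @param cols Feature column pair to bin (default d1/d2; e.g.
#'   \code{c("d2", "d3")} for the other landscape projections, typically
#'   with both widths 0.5).
#' @return List of class \code{dasDensity}: bin edges and midpoints,
#'   \code{rho} (density), \code{rho_norm} (max-normalized), \code{n},
#'   \code{modes}.
#' @export
dasDensity <- function(features, d1_width = 0.2, d2_width = 0.5,
                       d1_range = NULL, d2_range = NULL, categories = NULL,
                       normalized = FALSE, cols = c("d1", "d2")) {
  if (normalized) cols <- paste0(cols, "n")
  x <- features[[cols[1]]]; y <- features[[cols[2]]]
  if (is.null(x) || !length(x)) stop("empty feature input")
  edges <- function(v, w, rng) {
    if (is.null(rng)) rng <- range(v)
    lo <- floor(rng[1] / w) * w
    hi <- ceiling(rng[2] / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  }
  ex <- edges(x, d1_width, d1_range)
  ey <- edges(y, d2_width, d2_range)
  ix <- pmin(pmax(findInterval(x, ex, rightmost.closed = TRUE), 1L),
             length(ex) - 1L)
  iy <- pmin(pmax(findInterval(y, ey, rightmost.closed = TRUE), 1L),
             length(ey) - 1L)
  cnt <- matrix(tabulate((iy - 1L) * (length(ex) - 1L) + ix,
                         nbins = (length(ex) - 1L) * (length(ey) - 1L)),
                nrow = length(ex) - 1L)
  rho <- cnt / (length(x) * d1_width * d2_width)
  modes <- NULL
  if (!is.null(categories)) {
    modes <- lapply(c(AC = "AC", CCP = "CCP"), function(cc) {
      sel <- categories == cc
      if (!any(sel)) return(c(NA_real_, NA_real_))
      cc_cnt <- matrix(tabulate((iy[sel] - 1L) * (length(ex) - 1L) + ix[sel],
                                nbins = length(cnt)), nrow = nrow(cnt))
      w <- arrayInd(which.max(cc_cnt), dim(cc_cnt))
      c(d1 = (ex[w[1]] + ex[w[1] + 1]) / 2, d2 = (ey[w[2]] + ey[w[2] + 1]) / 2)
    })
  }
  structure(list(d1_edges = ex, d2_edges = ey,
                 d1_mid = (utils::head(ex, -1) + utils::tail(ex, -1)) / 2,
                 d2_mid = (utils::head(ey, -1) + utils::tail(ey, -1)) / 2,
                 rho = rho, rho_norm = rho / max(rho), n = length(x),
                 d1_width = d1_width, d2_width = d2_width, modes = modes),
            class = "dasDensity")
}

#' DAS difference map between two conditions
#'
#' Difference of the max-normalized densities, each first divided by its own
#' integral, with condition one acting as the control:
#' delta = rho2_norm / int(rho2_norm) - rho1_norm / int(rho1_norm).
#' The result integrates to zero, so gains (e.g. abortive-coat enrichment)
#' and losses (pit depletion) balance by construction.
#'
#' @param map1,map2 \code{dasDensity} objects on identical grids
#'   (control first).
#' @return List of class \code{dasDifference} with \code{delta} and the
#'   shared grid.
#' @export
dasDifference <- function(map1, map2) {
  stopifnot(inherits(map1, "dasDensity"), inherits(map2, "dasDensity"))
  if (!isTRUE(all.equal(map1$d1_edges, map2$d1_edges)) ||
      !isTRUE(all.equal(map1$d2_edges, map2$d2_edges)))
    stop("mismatched bin grids; rebuild both densities with common ranges")
  cell <- map1$d1_width * map1$d2_width
  nrm <- function(m) m$rho_norm / (sum(m$rho_norm) * cell)
  structure(list(delta = nrm(map2) - nrm(map1),
                 d1_edges = map1$d1_edges, d2_edges = map1$d2_edges,
                 d1_mid = map1$d1_mid, d2_mid = map1$d2_mid,
                 d1_width = map1$d1_width, d2_width = map1$d2_width),
            class = "dasDifference")
}

#' Export a density or difference map as a delimited matrix with bin-edge
#' headers
#'
#' @param map \code{dasDensity} or \code{dasDifference}.
#' @param path Output path (tab-separated; first row/column are bin
#'   midpoints).
#' @export
writeDensityMap <- function(map, path) {
  m <- if (inherits(map, "dasDifference")) map$delta else map$rho_norm
  out <- cbind(d1_mid = map$d1_mid, m)
  colnames(out) <- c("d1_mid", format(map$d2_mid, trim = TRUE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
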