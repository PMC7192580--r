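.feat_cols <- c("d1n", "d2n", "d3n")

featureMatrix <- function(features) {
  if (is.matrix(features)) return(features)
  cols <- if (all(.feat_cols %in% colnames(features))) .feat_cols
          else c("d1", "d2", "d3")
  as.matrix(features[, cols])
}

# squared Euclidean distances from rows of X to rows of M (k small)
.dist_to <- function(X, M) {
  d2 <- matrix(0, nrow(X), nrow(M))
  for (j in seq_len(nrow(M)))
    d2[, j] <- rowSums(sweep(X, 2, M[j, ])^2)
  d2
}

# k-means++ style seeding: iteratively pick points far from current seeds
.kmpp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      idx[j] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
    }
  }
  idx
}

# exact total-distance medoid update restricted to candidate points near the
# cluster mean; keeps the current medoid in the candidate set, so the
# objective never increases
.update_medoid <- function(Xc, cur_local, n_candidates = 200L) {
  m <- nrow(Xc)
  if (m == 1L) return(1L)
  ctr <- colMeans(Xc)
  d2c <- rowSums(sweep(Xc, 2, ctr)^2)
  cand <- order(d2c)[seq_len(min(n_candidates, m))]
  cand <- unique(c(cand, cur_local))
  tot <- vapply(cand, function(ci)
    sum(sqrt(rowSums(sweep(Xc, 2, Xc[ci, ])^2))), numeric(1))
  cand[which.min(tot)]
}

.kmedoids_once <- function(X, k, init_idx, max_iter = 50L) {
  med_idx <- init_idx
  assign_old <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- .dist_to(X, X[med_idx, , drop = FALSE])
    assign <- max.col(-d2, ties.method = "first")
    if (identical(assign, assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (!length(members)) next
      cur_local <- match(med_idx[j], members)
      if (is.na(cur_local)) cur_local <- 1L
      med_idx[j] <- members[.update_medoid(X[members, , drop = FALSE], cur_local)]
    }
  }
  d <- sqrt(.dist_to(X, X[med_idx, , drop = FALSE]))
  assign <- max.col(-d, ties.method = "first")
  list(medoid_idx = med_idx, assignment = assign,
       total_distance = sum(d[cbind(seq_len(nrow(X)), assign)]))
}

#' Fit a k-medoids classification model in DAS feature space
#'
#' Seeded k-means++ initializations followed by alternating
#' assignment/medoid-update iterations with an exact total-distance medoid
#' update over candidate points; the best of \code{n_restarts} runs by total
#' Euclidean distance is kept. Deterministic under a fixed seed.
#' \code{init} can supply additional warm-start medoid index sets.
#'
#' @param features Normalized feature data.frame (columns d1n, d2n, d3n) or
#'   a numeric matrix.
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param n_restarts Number of seeded restarts.
#' @param init Optional list of integer medoid index vectors used as extra
#'   warm starts.
#' @param provenance Label stored in the model.
#' @return A \linkS4class{DasModel} (unlabeled; see
#'   \code{\link{labelClusters}}).
#' @export
fitKmedoids <- function(features, k = 3L, seed = 1L, n_restarts = 10L,
                        init = NULL, provenance = "control") {
  X <- featureMatrix(features)
  k <- as.integer(k)
  if (nrow(unique(X)) < k)
    stop("k = ", k, " exceeds the number of distinct points")
  best <- NULL
  withSeed(seed, {
    starts <- lapply(seq_len(n_restarts), function(r) .kmpp_init(X, k))
    if (!is.null(init)) starts <- c(init, starts)
    for (st in starts) {
      # restart medoids must be distinct points
      if (nrow(unique(X[st, , drop = FALSE])) < k) next
      fit <- .kmedoids_once(X, k, st)
      if (is.null(best) || fit$total_distance < best$total_distance - 1e-12)
        best <- fit
    }
  })
  new("DasModel", k = k,
      medoids = X[best$medoid_idx, , drop = FALSE],
      medoidIndex = as.integer(best$medoid_idx),
      assignment = as.integer(best$assignment),
      totalDistance = best$total_distance,
      labelMap = rep(NA_character_, k), seed = as.numeric(seed),
      provenance = provenance)
}

#' @rdname DasModel-accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))
#' @rdname DasModel-accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname DasModel-accessors
#' @export
setGeneric("totalDistance", function(x) standardGeneric("totalDistance"))

#' Accessors for DasModel
#' @param x A \linkS4class{DasModel}.
#' @name DasModel-accessors
NULL
#' @rdname DasModel-accessors
setMethod("medoids", "DasModel", function(x) x@medoids)
#' @rdname DasModel-accessors
setMethod("labelMap", "DasModel", function(x) x@labelMap)
#' @rdname DasModel-accessors
setMethod("totalDistance", "DasModel", function(x) x@totalDistance)

setMethod("show", "DasModel", function(object) {
  cat("DasModel: k =", object@k, "| total distance =",
      format(object@totalDistance, digits = 6),
      "| provenance:", object@provenance, "\n")
  lab <- ifelse(is.na(object@labelMap), "?", object@labelMap)
  m <- cbind(label = lab, format(object@medoids, digits = 3))
  print(m, quote = FALSE)
})

#' Assign semantic AC/CCP/OT labels to fitted clusters
#'
#' The outlier cluster is the one with the highest mean normalized d3 (the
#' modified skewness that isolates bright transient traces); of the
#' remaining two, the abortive-coat cluster has the lower mean normalized
#' d1 (suppressed-risk regime) and the pit cluster the higher.
#'
#' @param model A k = 3 \linkS4class{DasModel}.
#' @param features The features the model was fitted on.
#' @return The model with \code{labelMap} populated.
#' @export
labelClusters <- function(model, features) {
  stopifnot(is(model, "DasModel"))
  if (model@k != 3L) stop("semantic labeling requires k = 3")
  X <- featureMatrix(features)
  g <- model@assignment
  m3 <- tapply(X[, 3L], factor(g, levels = 1:3), mean)
  if (anyNA(m3)) stop("empty cluster; cannot label")
  if (max(m3) - sort(m3, decreasing = TRUE)[2] < 1e-12)
    stop("tie in mean d3 between clusters; supply labels manually")
  ot <- which.max(m3)
  rest <- setdiff(1:3, ot)
  m1 <- tapply(X[, 1L], factor(g, levels = 1:3), mean)
  if (abs(m1[rest[1]] - m1[rest[2]]) < 1e-12)
    stop("tie in mean d1 between clusters; supply labels manually")
  ac <- rest[which.min(m1[rest])]
  ccp <- setdiff(rest, ac)
  lm <- character(3)
  lm[ot] <- "OT"; lm[ac] <- "AC"; lm[ccp] <- "CCP"
  model@labelMap <- lm
  validObject(model)
  model
}

#' Assign traces to the nearest medoid
#'
#' Euclidean nearest-medoid assignment with deterministic tie-breaking to
#' the lower cluster index. When the model carries semantic labels the
#' returned value is the AC/CCP/OT category per trace, otherwise the raw
#' cluster index.
#'
#' @param model A \linkS4class{DasModel}.
#' @param features Normalized features (control normalizer!).
#' @return Character categories (labeled model) or integer cluster indices.
#' @export
assignTraces <- function(model, features) {
  X <- featureMatrix(features)
  d2 <- .dist_to(X, model@medoids)
  idx <- max.col(-d2, ties.method = "first")
  if (anyNA(model@labelMap)) idx else model@labelMap[idx]
}

#' Elbow analysis of k-medoids total distance
#'
#' Fits k-medoids over \code{k_range}, warm-starting each k with the best
#' medoids of k-1 plus the point farthest from them (so the total distance
#' is non-increasing in k), and locates the elbow as the maximum discrete
#' second difference of total distance over interior k. An elbow strength
#' score (second difference relative to the total span of the curve) is
#' reported so that featureless decays can be recognized.
#'
#' @inheritParams fitKmedoids
#' @param k_range Increasing integer vector of cluster counts (length >= 3).
#' @return List with \code{k}, \code{total_distance}, \code{optimal_k},
#'   \code{second_difference}, \code{elbow_strength}.
#' @export
elbowAnalysis <- function(features, k_range = 1:7, seed = 1L,
                          n_restarts = 5L) {
  if (length(k_range) < 3L)
    stop("k_range must contain at least 3 values (second difference undefined)")
  stopifnot(all(diff(k_range) > 0))
  X <- featureMatrix(features)
  td <- numeric(length(k_range))
  prev <- NULL
  for (ii in seq_along(k_range)) {
    k <- k_range[ii]
    init <- NULL
    if (!is.null(prev) && length(prev) == k - 1L) {
      d2 <- .dist_to(X, X[prev, , drop = FALSE])
      far <- which.max(apply(d2, 1L, min))
      init <- list(c(prev, far))
    }
    fit <- fitKmedoids(X, k = k, seed = seed + k, n_restarts = n_restarts,
                       init = init)
    td[ii] <- fit@totalDistance
    prev <- fit@medoidIndex
  }
  sd2 <- diff(diff(td))                      # indexed by interior k
  opt <- k_range[which.max(sd2) + 1L]
  strength <- max(sd2) / max(td[1] - td[length(td)], .Machine$double.eps)
  list(k = k_range, total_distance = td, optimal_k = opt,
       second_difference = sd2, elbow_strength = strength)
}

#' Identify edge traces between the AC and CCP clusters
#'
#' Ranks all AC- and CCP-assigned traces by the absolute difference of
#' their distances to the AC and CCP medoids; the fraction with the
#' smallest difference (closest to the midplane between the two medoids)
#' are flagged as edge traces. The CCP percentage is reported both
#' including and excluding the edge set; outlier traces never enter the
#' edge pool.
#'
#' @param model A labeled k = 3 \linkS4class{DasModel}.
#' @param features Normalized features.
#' @param fraction Fraction of the AC+CCP pool to flag (default 0.10).
#' @return List with \code{edge} (logical per input row), \code{categories}
#'   (assigned categories), \code{ccp_pct_all}, \code{ccp_pct_noedge}.
#' @export
findEdgeTraces <- function(model, features, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (anyNA(model@labelMap)) stop("model must be labeled")
  X <- featureMatrix(features)
  cat_ <- assignTraces(model, features)
  d <- sqrt(.dist_to(X, model@medoids))
  iac <- which(model@labelMap == "AC"); iccp <- which(model@labelMap == "CCP")
  pool <- which(cat_ %in% c("AC", "CCP"))
  asym <- abs(d[pool, iac] - d[pool, iccp])
  n_edge <- as.integer(round(fraction * length(pool)))
  edge <- logical(length(cat_))
  if (n_edge > 0)
    edge[pool[order(asym)][seq_len(n_edge)]] <- TRUE
  ccp_all <- 100 * mean(cat_ == "CCP")
  keep <- !edge
  ccp_noedge <- 100 * sum(cat_ == "CCP" & keep) / sum(keep)
  list(edge = edge, categories = cat_, ccp_pct_all = ccp_all,
       ccp_pct_noedge = ccp_noedge)
}

#' Serialize / restore a DasModel as JSON
#'
#' @param model A \linkS4class{DasModel}.
#' @param path JSON path.
#' @export
writeDasModel <- function(model, path) {
  obj <- list(k = model@k, medoids = model@medoids,
              medoid_index = model@medoidIndex,
              total_distance = model@totalDistance,
              label_map = model@labelMap, seed = model@seed,
              provenance = model@provenance)
  jsonlite::write_json(obj, path, digits = NA, na = "null",
                       matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDasModel
#' @export
readDasModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  med <- matrix(as.numeric(o$medoids), nrow = o$k)
  colnames(med) <- .feat_cols
  new("DasModel", k = as.integer(o$k), medoids = med,
      medoidIndex = as.integer(o$medoid_index), assignment = integer(0),
      totalDistance = as.numeric(o$total_distance),
      labelMap = as.character(o$label_map), seed = as.numeric(o$seed),
      provenance = o$provenance)
}
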