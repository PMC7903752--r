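# Point-cloud morphometry on nuclei centroids: Delaunay and proximity cell
# graphs, convex-hull volume/surface, and centroid-matching segmentation
# evaluation (recall / precision / F score).

#' Delaunay cell graph (DCG) degrees
#'
#' Neighbour counts of the 3D Delaunay graph of a centroid cloud. Two
#' points are Delaunay neighbours iff their Voronoi cells share a proper
#' (two-dimensional) face, i.e. iff some point of the bisector plane is
#' strictly closer to the pair than to every other point. Each pairwise
#' test is solved as a small convex feasibility problem (quadratic program
#' with a slack margin), which handles degenerate cospherical
#' configurations canonically: for a regular octahedron the antipodal
#' cells touch only in a point and are not neighbours, giving degree 4
#' for every vertex.
#'
#' @param points numeric matrix (n x 3) of centroid coordinates, n >= 4,
#'   not coplanar.
#' @param margin slack (in units of the squared normalised cloud scale)
#'   below which a shared Voronoi boundary is considered degenerate.
#' @return list of class \code{"cell_graph"} with \code{degrees},
#'   \code{mean_degree} and \code{edges} (2-column matrix).
#' @export
delaunay_degrees <- function(points, margin = 1e-7) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4L) stop("invalid geometry: need at least 4 points")
  ## condition: centre and scale to unit RMS radius (Delaunay adjacency is
  ## similarity invariant)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2L, ctr)
  sc <- sqrt(mean(rowSums(pts^2)))
  if (sc <= 0) stop("invalid geometry: all points coincide")
  pts <- pts / sc
  ## coplanarity check via the covariance spectrum
  ev <- eigen(crossprod(pts) / n, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3L] < 1e-12 * ev[1L]) stop("invalid geometry: points are coplanar")

  sq <- rowSums(pts^2)
  adj <- matrix(FALSE, n, n)
  dmat <- as.matrix(stats::dist(pts))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      others <- setdiff(seq_len(n), c(i, j))
      mid <- (pts[i, ] + pts[j, ]) / 2
      ## Gabriel shortcut: empty open ball on the diameter implies an edge
      if (all(dmat[others, i]^2 + dmat[others, j]^2 >=
              dmat[i, j]^2 + margin)) {
        adj[i, j] <- TRUE
        next
      }
      ## feasibility: c on the bisector of (i, j) with
      ## |c - i|^2 <= |c - k|^2 - margin for all other k
      A_eq <- 2 * (pts[j, ] - pts[i, ])
      b_eq <- sq[j] - sq[i]
      A_in <- 2 * sweep(pts[others, , drop = FALSE], 2L, pts[i, ], "-")
      b_in <- sq[others] - sq[i]
      ## quadprog convention: minimise 1/2 c'Dc - d'c s.t. A'c >= b,
      ## first meq rows equalities. Our inequalities are A_in c <= b_in -
      ## margin, i.e. -A_in c >= margin - b_in.
      Amat <- t(rbind(A_eq, -A_in))
      bvec <- c(b_eq, margin - b_in)
      ok <- tryCatch({
        quadprog::solve.QP(Dmat = diag(3) * 2, dvec = 2 * mid,
                           Amat = Amat, bvec = bvec, meq = 1L)
        TRUE
      }, error = function(e) FALSE)
      adj[i, j] <- ok
    }
  }
  adj <- adj | t(adj)
  degrees <- rowSums(adj)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- unname(cbind(edges[, 1L], edges[, 2L]))
  structure(list(degrees = degrees, mean_degree = mean(degrees),
                 edges = edges),
            class = "cell_graph")
}

#' Proximity cell graph (PCG) degrees
#'
#' Neighbour counts of the graph connecting centroids closer than a
#' distance cutoff (strictly; 50 voxels by default, the scale of about
#' two cell diameters in the reference imaging geometry).
#'
#' @param points numeric matrix (n x 3).
#' @param cutoff neighbour distance cutoff in the same units as
#'   \code{points} (voxels by default).
#' @return list of class \code{"cell_graph"} with \code{degrees},
#'   \code{mean_degree} and \code{edges}.
#' @export
proximity_degrees <- function(points, cutoff = 50) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 1L) stop("need at least one point")
  if (n == 1L) {
    return(structure(list(degrees = 0, mean_degree = 0,
                          edges = matrix(integer(), 0L, 2L)),
                     class = "cell_graph"))
  }
  adj <- unname(as.matrix(stats::dist(pts)) < cutoff)
  diag(adj) <- FALSE
  degrees <- rowSums(adj)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- unname(cbind(edges[, 1L], edges[, 2L]))
  structure(list(degrees = degrees, mean_degree = mean(degrees),
                 edges = edges),
            class = "cell_graph")
}

#' Convex-hull volume and surface of a centroid cloud
#'
#' Approximates organoid volume and surface area by the convex hull of the
#' nuclei centroids (a stand-in for mesh-based surface approximation,
#' adequate for convex, near-spherical organoids).
#'
#' @param points numeric matrix (n x 3), n >= 4, not coplanar.
#' @return list with \code{volume} (cubic input units) and \code{surface}
#'   (squared input units).
#' @export
approximate_volume_surface <- function(points) {
  h <- convex_hull_3d(as.matrix(points))
  list(volume = h$volume, surface = h$area)
}

#' Match segmented centroids against ground truth
#'
#' For each ground-truth centroid, segmented centroids within the matching
#' radius are candidates and the closest is registered as a true positive.
#' Matching is one-to-one, resolved globally and greedily by ascending
#' pair distance (deterministic given stable input order). Unmatched
#' ground-truth centroids are false negatives, unmatched segmented
#' centroids false positives.
#'
#' @param gt,seg numeric matrices (rows are centroids, 3 columns) or data
#'   frames with columns \code{x}, \code{y}, \code{z}.
#' @param radius matching radius (10 voxels by default); candidate pairs
#'   must lie within this distance (inclusive).
#' @return list of class \code{"match_result"} with \code{TP}, \code{FP},
#'   \code{FN}, \code{recall}, \code{precision}, \code{F}, and
#'   \code{pairs} (matched index pairs with their distance).
#' @export
match_centroids <- function(gt, seg, radius = 10) {
  if (radius <= 0) stop("radius must be positive")
  as_mat <- function(a) {
    if (is.data.frame(a)) a <- a[, intersect(c("x", "y", "z"), names(a)), drop = FALSE]
    m <- as.matrix(a)
    storage.mode(m) <- "double"
    m
  }
  g <- as_mat(gt); s <- as_mat(seg)
  ng <- nrow(g); ns <- nrow(s)
  pairs <- data.frame(gt = integer(), seg = integer(), dist = numeric())
  if (ng == 0L && ns == 0L) {
    warning("both centroid sets are empty; metrics defined as 1")
    return(structure(list(TP = 0L, FP = 0L, FN = 0L, recall = 1, precision = 1,
                          F = 1, pairs = pairs), class = "match_result"))
  }
  if (ng > 0L && ns > 0L) {
    d2 <- outer(rowSums(g^2), rep(1, ns)) + outer(rep(1, ng), rowSums(s^2)) -
      2 * g %*% t(s)
    d <- sqrt(pmax(d2, 0))
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      dd <- d[cand]
      ord <- order(dd, cand[, 1L], cand[, 2L])  # stable on ties
      used_g <- logical(ng); used_s <- logical(ns)
      keep <- logical(length(ord))
      for (k in ord) {
        gi <- cand[k, 1L]; si <- cand[k, 2L]
        if (!used_g[gi] && !used_s[si]) {
          used_g[gi] <- TRUE; used_s[si] <- TRUE
          keep[k] <- TRUE
        }
      }
      pairs <- data.frame(gt = cand[keep, 1L], seg = cand[keep, 2L],
                          dist = d[cand[keep, , drop = FALSE]])
      pairs <- pairs[order(pairs$dist, pairs$gt), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  TP <- nrow(pairs)
  FN <- ng - TP
  FP <- ns - TP
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  Fv <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(TP = TP, FP = FP, FN = FN, recall = recall,
                 precision = precision, F = Fv, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("centroid matching: TP %d, FP %d, FN %d | recall %.3f, precision %.3f, F %.3f\n",
              x$TP, x$FP, x$FN, x$recall, x$precision, x$F))
  invisible(x)
}
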