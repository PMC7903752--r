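# Low-level 3D computational geometry shared by the simulator and the
# morphometry module: an incremental convex hull and a spherical Delaunay
# neighbour graph obtained by stereographic projection.

#' Convex hull of a 3D point cloud
#'
#' Incremental construction of the convex hull of a set of points in three
#' dimensions. Returns the triangular facets (outward oriented), the hull
#' vertices, the enclosed volume, the surface area and the hull edge list.
#'
#' @param pts numeric matrix with one row per point and three columns.
#' @param tol visibility tolerance; points within \code{tol} of a facet plane
#'   are treated as non-visible (i.e. coplanar points are not re-added).
#'   Defaults to \code{1e-9} times the cloud diameter.
#' @return A list of class \code{"hull3d"} with elements \code{faces}
#'   (m x 3 integer matrix of point indices, outward oriented),
#'   \code{vertices} (integer vector), \code{edges} (2-column integer matrix,
#'   each row sorted), \code{volume} and \code{area}.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' h <- convex_hull_3d(cube)
#' h$volume  # 1
#' h$area    # 6
#' @export
convex_hull_3d <- function(pts, tol = NULL) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("pts must have three columns")
  n <- nrow(pts)
  if (n < 4L) stop("invalid geometry: need at least 4 points for a 3D hull")
  if (!all(is.finite(pts))) stop("pts must be finite")

  diam <- sqrt(sum((apply(pts, 2L, max) - apply(pts, 2L, min))^2))
  if (diam == 0) stop("invalid geometry: all points coincide")
  if (is.null(tol)) tol <- 1e-9 * diam

  ## --- initial simplex: four affinely independent points -------------------
  i1 <- which.min(pts[, 1L])
  d1 <- sqrt(rowSums(sweep(pts, 2L, pts[i1, ])^2))
  i2 <- which.max(d1)
  if (d1[i2] <= tol) stop("invalid geometry: all points coincide")
  u <- (pts[i2, ] - pts[i1, ]) / d1[i2]
  rel <- sweep(pts, 2L, pts[i1, ])
  perp <- rel - outer(drop(rel %*% u), u)
  d2 <- sqrt(rowSums(perp^2))
  i3 <- which.max(d2)
  if (d2[i3] <= tol) stop("invalid geometry: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  d3 <- abs(drop(rel %*% nrm))
  i4 <- which.max(d3)
  if (d3[i4] <= tol) stop("invalid geometry: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  face_list <- vector("list", 8L * n)
  nf <- 0L
  normals <- matrix(0, 8L * n, 3L)
  offsets <- numeric(8L * n)
  alive <- logical(8L * n)

  add_face <- function(tri) {
    v1 <- pts[tri[2L], ] - pts[tri[1L], ]
    v2 <- pts[tri[3L], ] - pts[tri[1L], ]
    nn <- cross3(v1, v2)
    len <- sqrt(sum(nn^2))
    if (len <= .Machine$double.eps * diam^2) return(invisible(NULL))
    nn <- nn / len
    off <- sum(nn * pts[tri[1L], ])
    if (sum(nn * interior) > off) {  # orient outward
      tri <- tri[c(1L, 3L, 2L)]
      nn <- -nn
      off <- -off
    }
    nf <<- nf + 1L
    if (nf > length(offsets)) {  # grow storage (list grows on assignment)
      normals <<- rbind(normals, matrix(0, nf, 3L))
      offsets <<- c(offsets, numeric(nf))
      alive <<- c(alive, logical(nf))
    }
    face_list[[nf]] <<- tri
    normals[nf, ] <<- nn
    offsets[nf] <<- off
    alive[nf] <<- TRUE
    invisible(NULL)
  }
  for (k in seq_len(4L)) add_face(faces[k, ])

  ## --- incremental insertion ----------------------------------------------
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    idx <- which(alive[seq_len(nf)])
    vis <- idx[drop(normals[idx, , drop = FALSE] %*% pts[p, ]) - offsets[idx] > tol]
    if (length(vis) == 0L) next  # inside (or on) the hull
    ## horizon: undirected edges of visible faces that occur exactly once
    tris <- do.call(rbind, face_list[vis])
    ed <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
    key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[vis] <- FALSE
    for (h in seq_len(nrow(horizon))) {
      add_face(c(horizon[h, 1L], horizon[h, 2L], p))
    }
  }

  idx <- which(alive[seq_len(nf)])
  tris <- do.call(rbind, face_list[idx])
  ## ensure outward orientation for the volume sum (faces were oriented vs the
  ## initial interior point, which remains interior throughout)
  a <- pts[tris[, 1L], , drop = FALSE]
  b <- pts[tris[, 2L], , drop = FALSE]
  c_ <- pts[tris[, 3L], , drop = FALSE]
  cr <- cbind(
    (b[, 2L] - a[, 2L]) * (c_[, 3L] - a[, 3L]) - (b[, 3L] - a[, 3L]) * (c_[, 2L] - a[, 2L]),
    (b[, 3L] - a[, 3L]) * (c_[, 1L] - a[, 1L]) - (b[, 1L] - a[, 1L]) * (c_[, 3L] - a[, 3L]),
    (b[, 1L] - a[, 1L]) * (c_[, 2L] - a[, 2L]) - (b[, 2L] - a[, 2L]) * (c_[, 1L] - a[, 1L])
  )
  area <- sum(sqrt(rowSums(cr^2))) / 2
  a0 <- sweep(a, 2L, interior)
  volume <- abs(sum(a0[, 1L] * cr[, 1L] + a0[, 2L] * cr[, 2L] + a0[, 3L] * cr[, 3L]) / 6)
  ed <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  ed <- ed[!duplicated(ed), , drop = FALSE]
  structure(
    list(faces = tris, vertices = sort(unique(as.vector(tris))), edges = ed,
         volume = volume, area = area),
    class = "hull3d"
  )
}

# cross product of two length-3 vectors
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Neighbour graph of a (near-)spherical cell shell
#'
#' Computes the Delaunay triangulation of points radially projected onto the
#' unit sphere around their centre, via stereographic projection from one of
#' the data points followed by a planar Delaunay triangulation. For points in
#' convex position on a sphere this is exactly the convex-hull adjacency; for
#' a jittered monolayer it keeps every cell in the graph, which is the
#' physically meaningful neighbourhood for a cell shell.
#'
#' @param pts numeric matrix (n x 3) of cell positions, n >= 4.
#' @param centre optional centre of the shell; defaults to the centroid.
#' @return 2-column integer matrix of undirected edges (each row sorted,
#'   no duplicates), ordered lexicographically.
#' @export
shell_adjacency <- function(pts, centre = NULL) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("invalid geometry: need at least 4 cells for a shell graph")
  if (is.null(centre)) centre <- colMeans(pts)
  u <- sweep(pts, 2L, centre)
  r <- sqrt(rowSums(u^2))
  if (any(r <= 0)) stop("invalid geometry: a point coincides with the centre")
  u <- u / r

  ## pole = point with the largest angular clearance from its nearest
  ## neighbour, so the projected coordinates stay well conditioned
  g <- tcrossprod(u)
  diag(g) <- -Inf
  pole <- which.min(g[cbind(seq_len(n), max.col(g))])

  ## rotate pole to the north pole (Householder-free: Rodrigues rotation)
  z <- u[pole, ]
  target <- c(0, 0, 1)
  vv <- cross3(z, target)
  s <- sqrt(sum(vv^2))
  cthet <- sum(z * target)
  if (s < 1e-12) {
    rot <- if (cthet > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, vv[3L], -vv[2L], -vv[3L], 0, vv[1L], vv[2L], -vv[1L], 0), 3L, 3L)
    rot <- diag(3) + vx + vx %*% vx * ((1 - cthet) / s^2)
  }
  ur <- u %*% t(rot)

  others <- setdiff(seq_len(n), pole)
  denom <- 1 - ur[others, 3L]
  if (any(denom <= 1e-12)) stop("invalid geometry: duplicate direction at the projection pole")
  px <- ur[others, 1L] / denom
  py <- ur[others, 2L] / denom

  if (length(others) == 3L) {
    tri_edges <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
    hull_idx <- 1:3
  } else {
    tm <- interp::tri.mesh(px, py)
    tr <- interp::triangles(tm)
    tri_edges <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
    hull_idx <- interp::convex.hull(tm)$i
  }
  e1 <- cbind(others[tri_edges[, 1L]], others[tri_edges[, 2L]])
  e2 <- cbind(pole, others[hull_idx])
  ed <- rbind(e1, e2)
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  ed <- ed[!duplicated(ed[, 1L] * (n + 1) + ed[, 2L]), , drop = FALSE]
  ed[order(ed[, 1L], ed[, 2L]), , drop = FALSE]
}

# mean Euclidean length of the edges of a shell graph
mean_edge_length <- function(pts, edges) {
  if (nrow(edges) == 0L) return(NA_real_)
  d <- pts[edges[, 1L], , drop = FALSE] - pts[edges[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
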