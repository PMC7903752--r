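# Independent oracles and small fixture builders used across the tests.
# Each oracle re-derives its quantity by brute force, on a code path
# disjoint from the implementation it checks.

# Fibonacci lattice on a sphere (duplicated here on purpose: the tests
# must not trust the package's own lattice to build reference geometry)
fib_sphere <- function(N, R = 1) {
  i <- seq_len(N) - 1
  z <- 1 - (2 * i + 1) / N
  th <- 2 * pi * i / ((1 + sqrt(5)) / 2)
  r <- sqrt(pmax(0, 1 - z^2))
  R * cbind(r * cos(th), r * sin(th), z)
}

# Brute-force decline-phase scan, straight from the rule: for every
# trough (last frame of a non-increasing stretch), the reference is the
# latest running maximum since the end of the previous phase; a phase is
# recorded when the trough undercuts the reference by more than 5%.
oracle_declines <- function(x, thr = 0.05) {
  n <- length(x)
  troughs <- which(vapply(seq_len(n), function(j) {
    j > 1L && x[j] <= x[j - 1L] && (j == n || x[j + 1L] > x[j])
  }, logical(1L)))
  out <- NULL
  last_end <- 1L
  for (e in troughs) {
    if (e <= last_end) next
    seg <- x[last_end:e]
    refv <- max(seg)
    p <- last_end - 1L + max(which(seg == refv))
    if (p >= e) next
    if (x[e] < (1 - thr) * refv) {
      out <- rbind(out, c(start = p, end = e))
      last_end <- e
    }
  }
  if (is.null(out)) matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  else out
}

# Brute-force 3D Delaunay adjacency: a tetrahedron belongs to the
# triangulation iff its open circumsphere contains no other point; its
# six edges are Delaunay edges. Valid for generic (non-cospherical)
# configurations.
oracle_delaunay_adjacency <- function(p, tol = 1e-9) {
  n <- nrow(p)
  adj <- matrix(FALSE, n, n)
  for (c4 in utils::combn(n, 4L, simplify = FALSE)) {
    A <- 2 * (p[c4[2:4], , drop = FALSE] -
                matrix(p[c4[1L], ], 3L, 3L, byrow = TRUE))
    if (abs(det(A)) < 1e-9) next
    b <- rowSums(p[c4[2:4], , drop = FALSE]^2) - sum(p[c4[1L], ]^2)
    cc <- solve(A, b)
    r2 <- sum((p[c4[1L], ] - cc)^2)
    others <- setdiff(seq_len(n), c4)
    if (all(rowSums(sweep(p[others, , drop = FALSE], 2L, cc)^2) > r2 + tol)) {
      for (a in 1:3) for (b2 in (a + 1L):4L) {
        adj[c4[a], c4[b2]] <- adj[c4[b2], c4[a]] <- TRUE
      }
    }
  }
  adj
}

# Brute-force optimal one-to-one centroid assignment: maximises the
# number of matched pairs within the radius (recursion over ground-truth
# points; feasible up to ~7 points).
oracle_optimal_tp <- function(gt, seg, radius = 10) {
  ng <- nrow(gt); ns <- nrow(seg)
  if (ng == 0L || ns == 0L) return(0L)
  d <- as.matrix(stats::dist(rbind(gt, seg)))[seq_len(ng), ng + seq_len(ns),
                                              drop = FALSE]
  ok <- d <= radius
  best <- 0L
  rec <- function(gi, used, count) {
    if (count + (ng - gi + 1L) <= best) return()
    if (gi > ng) {
      best <<- max(best, count)
      return()
    }
    rec(gi + 1L, used, count)  # leave gi unmatched
    for (si in which(ok[gi, ])) {
      if (!used[si]) {
        used[si] <- TRUE
        rec(gi + 1L, used, count + 1L)
        used[si] <- FALSE
      }
    }
  }
  rec(1L, logical(ns), 0L)
  best
}

# random positive trace with drops, rises and plateaus, for the
# phase-detection equivalence tests
random_trace <- function(n, seed) {
  set.seed(seed)
  steps <- sample(c(-0.12, -0.06, -0.02, 0, 0.01, 0.03, 0.08), n - 1L,
                  replace = TRUE, prob = c(1, 1, 2, 2, 3, 2, 1))
  pmax(0.05, cumprod(c(1, 1 + steps)))
}
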