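# Seeded synthetic-data generators. Every generator produces one of the
# input shapes the analysis modules consume, together with its ground
# truth (attached as attributes, never inferred), so the whole pipeline is
# testable without any experimental download. A fixed seed gives
# bit-identical output.

#' Sawtooth projected-area trace with known oscillation events
#'
#' Builds a trace containing exactly \code{n_events} drops, each exceeding
#' the 5\% decline threshold, separated by linear recoveries of at least
#' \code{recovery_frames} frames (so every decline is followed by an
#' accepted expansion phase). The lead-in covers the four formation
#' frames plus a full expansion phase.
#'
#' @param n_events number of injected oscillation events (>= 0).
#' @param drop_fraction fractional depth of each drop (a value below 0.05
#'   injects declines that stay under the detection threshold).
#' @param recovery_frames frames per recovery ramp (>= 5 for an
#'   acceptable expansion phase).
#' @param baseline_slope upward slope of the ramps per frame (relative).
#' @param lead_in frames before the first drop (>= 9: 4 formation frames
#'   plus one full expansion phase).
#' @param start_area initial projected area in mm^2.
#' @param circ target circularity used to derive the perimeter column.
#' @param noise_sd multiplicative Gaussian noise (0 = noiseless).
#' @param seed RNG seed.
#' @param organoid_id,well_id identifiers for the output table.
#' @return data frame with columns \code{organoid_id}, \code{well_id},
#'   \code{t_h}, \code{area_mm2}, \code{perimeter_mm}; the injected event
#'   count and drop frame indices are attached as attributes
#'   \code{"n_events"} and \code{"drop_frames"}.
#' @export
make_sawtooth_trace <- function(n_events = 7, drop_fraction = 0.3,
                                recovery_frames = 8L, baseline_slope = 0.01,
                                lead_in = 9L, start_area = 0.05, circ = 0.9,
                                noise_sd = 0, seed = 1L,
                                organoid_id = "org1", well_id = "w1") {
  stopifnot(n_events >= 0, recovery_frames >= 1L, lead_in >= 5L)
  set.seed(seed)
  v <- numeric(0)
  cur <- 1
  ramp <- function(from, k) from * (1 + baseline_slope * seq_len(k))
  v <- c(cur, ramp(cur, lead_in - 1L))
  drop_frames <- integer(0)
  for (e in seq_len(n_events)) {
    cur <- v[length(v)]
    v <- c(v, cur * (1 - drop_fraction))
    drop_frames <- c(drop_frames, length(v))
    v <- c(v, ramp(v[length(v)], recovery_frames))
  }
  if (noise_sd > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_sd))
  area <- start_area * v
  out <- data.frame(
    organoid_id = organoid_id, well_id = well_id,
    t_h = (seq_along(area) - 1) * 0.5,
    area_mm2 = area,
    perimeter_mm = sqrt(4 * pi * area / circ),
    stringsAsFactors = FALSE)
  attr(out, "n_events") <- as.integer(n_events)
  attr(out, "drop_frames") <- drop_frames
  out
}

#' Growth curve from the piecewise exponential-linear model
#'
#' @param mode \code{"piecewise"}, \code{"exponential"} or
#'   \code{"linear"}.
#' @param N0 initial cell count.
#' @param r exponential rate (1/h).
#' @param t_star transition time (h; piecewise mode).
#' @param m linear slope (cells/h).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise (0 = noiseless).
#' @param t_end,dt time span and sampling interval in hours (30-min frames
#'   by default).
#' @param seed RNG seed.
#' @return a \code{\link{growth_curve}}; the generating parameters are
#'   attached as attribute \code{"truth"}.
#' @export
make_growth_curve <- function(mode = c("piecewise", "exponential", "linear"),
                              N0 = 9, r = 0.05, t_star = 60, m = 4,
                              noise_cv = 0, t_end = 144, dt = 0.5,
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  tt <- seq(0, t_end, by = dt)
  vv <- switch(mode,
    exponential = N0 * exp(r * tt),
    linear = N0 + m * tt,
    piecewise = ifelse(tt <= t_star, N0 * exp(r * tt),
                       N0 * exp(r * t_star) + m * (tt - t_star)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    vv <- vv * stats::rlnorm(length(vv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  gc <- growth_curve(tt, pmax(vv, .Machine$double.eps), units = "cells")
  attr(gc, "truth") <- list(mode = mode, N0 = N0, r = r, t_star = t_star, m = m)
  gc
}

#' Paired ground-truth / segmented centroid clouds
#'
#' Ground truth is a jittered spherical shell of nuclei centroids (the
#' monolayer geometry); the segmented cloud is derived from it by
#' per-point Gaussian displacement, random deletions (false negatives)
#' and spurious uniform additions (false positives), so the expected
#' evaluation metrics are known from the construction.
#'
#' @param N number of ground-truth centroids.
#' @param R shell radius in voxels.
#' @param jitter_sd radial/tangential jitter of the shell (voxels).
#' @param fn_rate per-point deletion probability.
#' @param fp_rate spurious points as a fraction of \code{N}.
#' @param displacement_sd per-axis Gaussian displacement of the kept
#'   points (voxels).
#' @param seed RNG seed.
#' @return list with data frames \code{gt} and \code{seg} (columns
#'   \code{id}, \code{t}, \code{x}, \code{y}, \code{z}) and a
#'   \code{truth} list (kept indices, deletion/addition counts).
#' @export
make_shell_cloud <- function(N = 200, R = 100, jitter_sd = 2, fn_rate = 0,
                             fp_rate = 0, displacement_sd = 0, seed = 1L) {
  set.seed(seed)
  i <- seq_len(N) - 1
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i + 1) / N
  theta <- 2 * pi * i / golden
  rr <- sqrt(pmax(0, 1 - z^2))
  gt <- R * cbind(rr * cos(theta), rr * sin(theta), z)
  if (jitter_sd > 0) gt <- gt + matrix(stats::rnorm(3 * N, 0, jitter_sd), N, 3L)
  keep <- stats::runif(N) >= fn_rate
  seg <- gt[keep, , drop = FALSE]
  if (displacement_sd > 0) {
    seg <- seg + matrix(stats::rnorm(3 * nrow(seg), 0, displacement_sd),
                        nrow(seg), 3L)
  }
  n_fp <- round(fp_rate * N)
  if (n_fp > 0) {
    u <- matrix(stats::rnorm(3 * n_fp), n_fp, 3L)
    u <- u / sqrt(rowSums(u^2)) * (1.2 * R * stats::runif(n_fp)^(1 / 3))
    seg <- rbind(seg, u)
  }
  as_df <- function(m) data.frame(id = seq_len(nrow(m)), t = 0,
                                  x = m[, 1L], y = m[, 2L], z = m[, 3L])
  list(gt = as_df(gt), seg = as_df(seg),
       truth = list(kept = which(keep), n_fn = sum(!keep), n_fp = n_fp))
}

#' Ensemble of projected-area traces for one well
#'
#' Emulates a well of organoids growing in parallel: lognormal initial
#' areas, per-organoid expansion slopes, and oscillation events injected
#' inversely with initial size (the smaller the organoid, the more
#' events), with perimeters consistent with a target circularity.
#'
#' @param n_organoids number of organoids in the well.
#' @param frames number of 0.5-h frames.
#' @param area_meanlog,area_sdlog lognormal parameters of the initial
#'   projected area (mm^2); \code{area_sdlog} is scaled by
#'   \code{heterogeneity}.
#' @param slope_mean,slope_sd per-organoid expansion slope (per hour, on
#'   the normalised scale); \code{slope_sd} is scaled by
#'   \code{heterogeneity}.
#' @param max_events largest injected event count (assigned to the
#'   smallest organoid; counts scale inversely with initial area).
#' @param heterogeneity 0 collapses the well onto identical organoids.
#' @param circ target circularity.
#' @param seed RNG seed.
#' @param well_id well identifier.
#' @return long-format trace data frame; per-organoid truth (initial
#'   areas, slopes, injected event counts) attached as attribute
#'   \code{"truth"}.
#' @export
make_well_ensemble <- function(n_organoids = 34, frames = 97L,
                               area_meanlog = log(0.02), area_sdlog = 0.8,
                               slope_mean = 0.11, slope_sd = 0.03,
                               max_events = 6L, heterogeneity = 1,
                               circ = 0.9, seed = 1L, well_id = "w1") {
  set.seed(seed)
  a0 <- stats::rlnorm(n_organoids, area_meanlog, area_sdlog * heterogeneity)
  slopes <- pmax(0.01, stats::rnorm(n_organoids, slope_mean,
                                    slope_sd * heterogeneity))
  ## smaller organoids oscillate more: event count decreases with the
  ## rank of the initial area
  if (heterogeneity == 0) {
    n_ev <- rep(as.integer(round(max_events / 2)), n_organoids)
  } else {
    rk <- rank(a0, ties.method = "first")
    n_ev <- as.integer(round(max_events * (n_organoids - rk) /
                               max(1L, n_organoids - 1L)))
  }
  out <- vector("list", n_organoids)
  truth <- data.frame(organoid_id = sprintf("org%02d", seq_len(n_organoids)),
                      initial_area = a0, slope = slopes, n_events = n_ev)
  for (k in seq_len(n_organoids)) {
    ## build a sawtooth with the assigned event count; frame budget fixed
    ev <- n_ev[k]
    rec <- if (ev > 0) max(5L, (frames - 10L) %/% max(1L, ev) - 1L) else 5L
    tr <- make_sawtooth_trace(
      n_events = ev, drop_fraction = 0.2, recovery_frames = rec,
      baseline_slope = slopes[k] * 0.5,
      lead_in = 9L, start_area = a0[k], circ = circ, noise_sd = 0,
      seed = seed + k, organoid_id = truth$organoid_id[k], well_id = well_id)
    ## pad or trim to the frame budget
    if (nrow(tr) > frames) tr <- tr[seq_len(frames), , drop = FALSE]
    if (nrow(tr) < frames) {
      extra <- frames - nrow(tr)
      last <- tr$area_mm2[nrow(tr)]
      grow <- last * (1 + slopes[k] * 0.25)^(seq_len(extra) / nrow(tr))
      add <- data.frame(organoid_id = truth$organoid_id[k], well_id = well_id,
                        t_h = tr$t_h[nrow(tr)] + 0.5 * seq_len(extra),
                        area_mm2 = grow,
                        perimeter_mm = sqrt(4 * pi * grow / circ))
      tr <- rbind(tr, add)
    }
    out[[k]] <- tr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- truth
  res
}
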