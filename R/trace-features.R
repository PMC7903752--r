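# Mesoscale feature extraction from projected-area time series of
# bright-field organoid recordings: well-wise normalisation, decline and
# expansion phases, size-oscillation events, expansion factors, circularity
# and culture-level summaries.
#
# Traces are long-format data frames with columns organoid_id, well_id,
# t_h, area_mm2 and optionally perimeter_mm, sampled every 0.5 h.

#' Normalise the traces of one or more wells
#'
#' Divides every projected area in a well by the median, across the well's
#' organoids, of the area at the fifth time point. The first four frames
#' are retained but flagged (\code{formation_frame}): segmentation during
#' organoid formation is unreliable, which is why the fifth frame anchors
#' the normalisation. Organoids with fewer than five time points are
#' excluded (with a message naming them).
#'
#' @param traces long-format data frame with columns \code{organoid_id},
#'   \code{well_id}, \code{t_h}, \code{area_mm2} (and optionally
#'   \code{perimeter_mm}).
#' @return the input with columns \code{area_norm} and
#'   \code{formation_frame} added; excluded organoid ids are attached as
#'   attribute \code{"excluded"}.
#' @export
normalise_traces <- function(traces) {
  req <- c("organoid_id", "well_id", "t_h", "area_mm2")
  miss <- setdiff(req, names(traces))
  if (length(miss)) stop("missing required column: ", paste(miss, collapse = ", "))
  traces <- traces[order(traces$well_id, traces$organoid_id, traces$t_h), ,
                   drop = FALSE]
  key <- paste(traces$well_id, traces$organoid_id, sep = "\r")
  n_frames <- stats::ave(traces$area_mm2, key, FUN = length)
  short <- unique(traces$organoid_id[n_frames < 5L])
  if (length(short)) {
    message("excluding organoid(s) with fewer than 5 time points: ",
            paste(short, collapse = ", "))
    drop_rows <- traces$organoid_id %in% short & n_frames < 5L
    traces <- traces[!drop_rows, , drop = FALSE]
    key <- key[!drop_rows]
  }
  if (nrow(traces) == 0L) stop("no organoid has at least 5 time points")
  frame_idx <- stats::ave(seq_len(nrow(traces)), key, FUN = seq_along)
  fifth <- traces[frame_idx == 5L, c("well_id", "area_mm2")]
  div <- tapply(fifth$area_mm2, fifth$well_id, stats::median)
  traces$area_norm <- traces$area_mm2 / as.numeric(div[as.character(traces$well_id)])
  traces$formation_frame <- frame_idx <= 4L
  attr(traces, "excluded") <- short
  traces
}

#' Detect decline phases in an area trace
#'
#' A decline phase starts at the time point after which the area declines
#' by more than 5\% (the reference is the running local maximum since the
#' end of the previous phase, making the rule scale-free) and ends when
#' the area increases again. A non-increasing run whose trough stays
#' within 5\% of the reference is not a phase.
#'
#' @param x numeric vector of (normalised) areas.
#' @param t time points in hours (default: 0.5-h frames).
#' @param drop_frac decline threshold as a fraction of the reference peak.
#' @return data frame with one row per phase: \code{start_idx},
#'   \code{end_idx} (1-based frame indices of the reference peak and the
#'   trough), \code{start_t}, \code{end_t}, \code{duration_h},
#'   \code{slope} (least-squares, per hour) and \code{depth_frac}.
#' @export
detect_decline_phases <- function(x, t = (seq_along(x) - 1) * 0.5,
                                  drop_frac = 0.05) {
  n <- length(x)
  out <- list()
  if (n >= 2L) {
    peak <- 1L
    j <- 2L
    while (j <= n) {
      if (x[j] >= x[peak]) {
        peak <- j
        j <- j + 1L
        next
      }
      ## inside a non-increasing run below the running peak: advance to the
      ## trough (the last frame before the values increase again)
      while (j < n && x[j + 1L] <= x[j]) j <- j + 1L
      if (x[j] < (1 - drop_frac) * x[peak]) {
        seg <- peak:j
        slope <- if (length(seg) > 1L)
          stats::cov(t[seg], x[seg]) / stats::var(t[seg]) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          start_idx = peak, end_idx = j, start_t = t[peak], end_t = t[j],
          duration_h = t[j] - t[peak], slope = slope,
          depth_frac = 1 - x[j] / x[peak])
        peak <- j  # reference resets at the phase end
      }
      j <- j + 1L
    }
  }
  if (length(out) == 0L) {
    data.frame(start_idx = integer(), end_idx = integer(),
               start_t = numeric(), end_t = numeric(),
               duration_h = numeric(), slope = numeric(),
               depth_frac = numeric())
  } else {
    do.call(rbind, out)
  }
}

#' Detect expansion phases between declines
#'
#' Candidate expansion phases are the intervals between the end of a
#' decline phase and the start of the next one (the trace start counts as
#' a virtual decline end, the trace end as a virtual decline start). A
#' candidate is accepted if it spans at least \code{min_frames} time
#' points and the Pearson correlation of the degree-1 (linear) fit exceeds
#' \code{min_r}.
#'
#' @inheritParams detect_decline_phases
#' @param declines result of \code{\link{detect_decline_phases}} on the
#'   same trace.
#' @param min_frames minimum number of frames of an accepted phase.
#' @param min_r minimum Pearson correlation of the linear fit.
#' @return data frame with one row per accepted phase: \code{start_idx},
#'   \code{end_idx}, \code{start_t}, \code{end_t}, \code{duration_h},
#'   \code{slope} (per hour) and \code{r}.
#' @export
detect_expansion_phases <- function(x, t = (seq_along(x) - 1) * 0.5,
                                    declines = detect_decline_phases(x, t),
                                    min_frames = 5L, min_r = 0.9) {
  n <- length(x)
  starts <- c(1L, declines$end_idx)
  ends <- c(declines$start_idx, n)
  out <- list()
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    if (b - a + 1L < min_frames) next
    seg <- a:b
    if (stats::sd(x[seg]) == 0 || stats::sd(t[seg]) == 0) next
    r <- stats::cor(t[seg], x[seg])
    if (!is.finite(r) || r <= min_r) next
    slope <- stats::cov(t[seg], x[seg]) / stats::var(t[seg])
    out[[length(out) + 1L]] <- data.frame(
      start_idx = a, end_idx = b, start_t = t[a], end_t = t[b],
      duration_h = t[b] - t[a], slope = slope, r = r)
  }
  if (length(out) == 0L) {
    data.frame(start_idx = integer(), end_idx = integer(),
               start_t = numeric(), end_t = numeric(),
               duration_h = numeric(), slope = numeric(), r = numeric())
  } else {
    do.call(rbind, out)
  }
}

#' Pair declines with expansions into size-oscillation events
#'
#' A size-oscillation event is a decline phase followed immediately by an
#' accepted expansion phase (i.e. an expansion starting at the decline's
#' trough). A terminal decline with no recovery is counted as a decline
#' but not as an event.
#'
#' @param declines,expansions phase tables from the detectors.
#' @return list with \code{count} and \code{events} (the paired subset of
#'   \code{declines} with the matched expansion index).
#' @export
oscillation_events <- function(declines, expansions) {
  if (nrow(declines) == 0L) {
    return(list(count = 0L, events = cbind(declines, expansion_row = integer())))
  }
  match_idx <- match(declines$end_idx, expansions$start_idx)
  paired <- !is.na(match_idx)
  ev <- declines[paired, , drop = FALSE]
  ev$expansion_row <- match_idx[paired]
  list(count = sum(paired), events = ev)
}

#' Average and maximum expansion factor
#'
#' The expansion factor of a phase is its fitted slope (per hour, on
#' normalised areas). Organoids without any accepted expansion phase have
#' no defined factor and are reported as \code{NA} (and excluded from
#' culture medians rather than contributing zeros).
#'
#' @param expansions phase table from
#'   \code{\link{detect_expansion_phases}}.
#' @return list with \code{average} and \code{maximum} (both \code{NA} if
#'   no phase was accepted).
#' @export
expansion_factors <- function(expansions) {
  if (nrow(expansions) == 0L) return(list(average = NA_real_, maximum = NA_real_))
  list(average = mean(expansions$slope), maximum = max(expansions$slope))
}

#' Circularity of a projected shape
#'
#' \eqn{4\pi \cdot area / perimeter^2}: 1 for a circle, smaller for every
#' other simple shape. Values below 0.6 indicate deficient segmentation.
#'
#' @param area,perimeter numeric vectors (perimeter > 0).
#' @return numeric vector of circularities.
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Tukey-fence outliers (1.5 x IQR)
#'
#' Flags values below the first quartile minus 1.5 IQR or above the third
#' quartile plus 1.5 IQR. Quartiles use linear interpolation (type 7),
#' pinned for reproducible masks.
#'
#' @param values numeric vector (NAs are never flagged).
#' @return logical mask of the same length.
#' @export
iqr_outliers <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[[2L]] - q[[1L]]
  out <- values < q[[1L]] - 1.5 * iqr | values > q[[2L]] + 1.5 * iqr
  out & !is.na(out)
}

#' Per-organoid feature extraction
#'
#' Runs the full mesoscale pipeline on a table of traces: well-wise
#' normalisation, phase detection on the normalised areas (skipping the
#' four flagged formation frames), event pairing, expansion factors,
#' area summaries, circularity-based quality control and outlier flags.
#'
#' @inheritParams normalise_traces
#' @param circularity_min organoids whose circularity drops below this at
#'   any frame are flagged \code{excluded} (deficient segmentation).
#' @return data frame with one row per organoid (id, well, frame count,
#'   area summaries, phase/event counts, expansion factors, circularity
#'   summary, \code{excluded} and \code{outlier} flags); the per-organoid
#'   phase tables are attached as attribute \code{"phases"}.
#' @export
extract_features <- function(traces, circularity_min = 0.6) {
  traces <- normalise_traces(traces)
  has_perim <- "perimeter_mm" %in% names(traces)
  rows <- list()
  phases <- list()
  key <- paste(traces$well_id, traces$organoid_id, sep = "\r")
  for (kk in unique(key)) {
    tr <- traces[key == kk, , drop = FALSE]
    oid <- tr$organoid_id[1L]
    keep <- !tr$formation_frame  # frames 5..n
    x <- tr$area_norm[keep]
    tt <- tr$t_h[keep]
    dec <- detect_decline_phases(x, tt)
    exp_ <- detect_expansion_phases(x, tt, dec)
    ev <- oscillation_events(dec, exp_)
    fac <- expansion_factors(exp_)
    circ <- if (has_perim) circularity(tr$area_mm2, tr$perimeter_mm) else NULL
    excluded <- if (has_perim) any(circ < circularity_min, na.rm = TRUE) else NA
    rows[[length(rows) + 1L]] <- data.frame(
      organoid_id = oid,
      well_id = tr$well_id[1L],
      n_frames = nrow(tr),
      initial_area = tr$area_mm2[1L],
      final_area = tr$area_mm2[nrow(tr)],
      min_area = min(tr$area_mm2),
      max_area = max(tr$area_mm2),
      final_area_norm = tr$area_norm[nrow(tr)],
      n_declines = nrow(dec),
      n_expansions = nrow(exp_),
      oscillation_events = ev$count,
      avg_expansion_factor = fac$average,
      max_expansion_factor = fac$maximum,
      mean_circularity = if (has_perim) mean(circ) else NA_real_,
      excluded = excluded,
      stringsAsFactors = FALSE)
    phases[[paste(tr$well_id[1L], oid, sep = "/")]] <-
      list(declines = dec, expansions = exp_, events = ev$events)
  }
  feat <- do.call(rbind, rows)
  feat$outlier <- iqr_outliers(feat$avg_expansion_factor)
  attr(feat, "phases") <- phases
  feat
}

#' Culture-level summary and well comparison
#'
#' Per-well medians and interquartile ranges of the final normalised area
#' and the expansion factors, plus a Kruskal-Wallis comparison of the
#' final normalised areas across wells. Organoids flagged excluded (bad
#' circularity) are dropped; undefined expansion factors are omitted from
#' the medians. When every observation is identical the Kruskal-Wallis
#' statistic is reported as H = 0 with p = 1 (the tie-corrected statistic
#' is undefined in that degenerate case); with a single well the
#' comparison is skipped with a message.
#'
#' @param features result of \code{\link{extract_features}}.
#' @return list with \code{per_well} (data frame) and \code{test} (list
#'   with \code{H}, \code{p_value}, \code{df}, or \code{NULL} if skipped).
#' @export
culture_summary <- function(features) {
  keep <- !(features$excluded %in% TRUE)
  f <- features[keep, , drop = FALSE]
  iqr_str <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
    q[[2L]] - q[[1L]]
  }
  per_well <- do.call(rbind, lapply(split(f, f$well_id), function(w) {
    data.frame(
      well_id = w$well_id[1L],
      n = nrow(w),
      median_final_area_norm = stats::median(w$final_area_norm),
      iqr_final_area_norm = iqr_str(w$final_area_norm),
      median_avg_expansion = stats::median(w$avg_expansion_factor, na.rm = TRUE),
      iqr_avg_expansion = iqr_str(w$avg_expansion_factor),
      median_events = stats::median(w$oscillation_events),
      stringsAsFactors = FALSE)
  }))
  rownames(per_well) <- NULL
  wells <- unique(f$well_id)
  test <- NULL
  if (length(wells) < 2L) {
    message("single well: across-well comparison skipped")
  } else if (stats::var(f$final_area_norm) == 0) {
    test <- list(H = 0, p_value = 1, df = length(wells) - 1L)
  } else {
    kt <- stats::kruskal.test(f$final_area_norm, factor(f$well_id))
    test <- list(H = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter))
  }
  list(per_well = per_well, test = test)
}
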