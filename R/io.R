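# Table readers/writers and the command-line dispatcher. All interchange
# is plain CSV with a header; floats are written with enough digits to
# round-trip exactly.

#' Read a projected-area trace table
#'
#' Reads a CSV with columns \code{organoid_id}, \code{well_id},
#' \code{t_h}, \code{area_mm2} and optionally \code{perimeter_mm}. Rows
#' with non-finite areas are dropped (and counted); the frame interval is
#' inferred and checked against the expected 0.5-h sampling.
#'
#' @param path CSV file path.
#' @param expected_dt expected frame interval in hours (warn on mismatch;
#'   use \code{NA} to skip the check).
#' @return trace data frame (sorted by well, organoid, time) with
#'   attributes \code{"dropped_rows"} and \code{"frame_interval"}.
#' @export
read_trace_table <- function(path, expected_dt = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path)
  req <- c("organoid_id", "well_id", "t_h", "area_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column: ", paste(miss, collapse = ", "))
  bad <- !is.finite(df$area_mm2)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite area dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$well_id, df$organoid_id, df$t_h), , drop = FALSE]
  rownames(df) <- NULL
  dts <- unlist(tapply(df$t_h, df$organoid_id, function(tt) diff(sort(tt)),
                       simplify = FALSE))
  dt <- if (length(dts)) stats::median(dts) else NA_real_
  if (is.finite(expected_dt) && is.finite(dt) &&
      abs(dt - expected_dt) > 1e-6) {
    warning(sprintf("frame interval %.3g h differs from the expected %.3g h",
                    dt, expected_dt))
  }
  if (!"perimeter_mm" %in% names(df)) {
    attr(df, "circularity_available") <- FALSE
  } else {
    attr(df, "circularity_available") <- TRUE
  }
  attr(df, "dropped_rows") <- sum(bad)
  attr(df, "frame_interval") <- dt
  df
}

#' Read a centroid table
#'
#' CSV with columns \code{id}, \code{t}, \code{x}, \code{y}, \code{z}
#' (voxel units).
#'
#' @param path CSV file path.
#' @return data frame of centroids.
#' @export
read_centroid_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path)
  miss <- setdiff(c("id", "t", "x", "y", "z"), names(df))
  if (length(miss)) stop("missing required column: ", paste(miss, collapse = ", "))
  df
}

# shared writer: deterministic column order, exact-round-trip floats,
# "\n" newlines
write_table <- function(records, path, columns = names(records)) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory")
  records <- as.data.frame(records)[, columns, drop = FALSE]
  fmt <- records
  for (cn in columns) {
    if (is.double(records[[cn]])) fmt[[cn]] <- sprintf("%.17g", records[[cn]])
  }
  lines <- c(paste(columns, collapse = ","),
             if (nrow(fmt)) do.call(paste, c(unname(fmt), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write per-organoid features
#' @param features data frame from \code{\link{extract_features}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_features <- function(features, path) {
  write_table(features, path)
}

#' Write a simulated trajectory
#' @param traj data frame from \code{\link{simulate_organoid}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_table(as.data.frame(traj), path,
              c("t", "N", "V_lumen", "R_fit", "n", "P", "sealed",
                "rupture_event"))
}

#' Write a centroid-matching result
#' @param match a \code{"match_result"} from
#'   \code{\link{match_centroids}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_match <- function(match, path) {
  summary_row <- data.frame(TP = match$TP, FP = match$FP, FN = match$FN,
                            recall = match$recall, precision = match$precision,
                            F = match$F)
  write_table(summary_row, path)
}

#' Read a simulation configuration file
#'
#' YAML file with two optional top-level maps: \code{params} (fields of
#' \code{\link{simulation_params}}) and \code{schedule} (fields of
#' \code{\link{division_schedule}}), plus optional \code{t_end},
#' \code{N0}, \code{R0}. Unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return list with validated \code{params}, \code{schedule} and run
#'   settings.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known_top <- c("params", "schedule", "t_end", "N0", "R0", "jitter",
                 "record_every")
  unk <- setdiff(names(cfg), known_top)
  if (length(unk)) stop("unknown configuration key: ", paste(unk, collapse = ", "))
  pargs <- cfg$params %||% list()
  unk <- setdiff(names(pargs), names(formals(simulation_params)))
  if (length(unk)) stop("unknown configuration key: params.", paste(unk, collapse = ", params."))
  sargs <- cfg$schedule %||% list()
  unk <- setdiff(names(sargs), names(formals(division_schedule)))
  if (length(unk)) stop("unknown configuration key: schedule.", paste(unk, collapse = ", schedule."))
  if (!is.null(sargs$table)) sargs$table <- as.data.frame(sargs$table)
  list(params = do.call(simulation_params, pargs),
       schedule = if (length(sargs)) do.call(division_schedule, sargs) else NULL,
       t_end = cfg$t_end %||% 100, N0 = cfg$N0 %||% 64, R0 = cfg$R0,
       jitter = cfg$jitter %||% 0.5, record_every = cfg$record_every %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
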