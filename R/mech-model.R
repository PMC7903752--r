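# Mechanical 3D agent-based model of a single-layer spherical organoid.
#
# Cells are agents on a closed shell around a fluid-filled lumen. Osmotic
# influx of a secreted substance inflates the lumen; the shell ruptures when
# the cells are pulled too far apart, vents the substance, and reseals once
# the cell-cell distances relax. Positions follow overdamped Langevin
# dynamics integrated with the Euler-Maruyama scheme.

#' Simulation parameters for the organoid shell model
#'
#' Constructs and validates the parameter set of the agent-based model.
#' Units are micrometres and hours throughout; forces are in arbitrary
#' consistent units (nanonewton-like), pressure in force per square
#' micrometre.
#'
#' Defaults are calibrated, not measured: they are chosen so that one cell
#' occupies a realistic area on the shell (rest length 20 um ~ one cell
#' diameter) and so that a 64-cell organoid under slow linear division
#' (1 cell/h) first ruptures on the scale of ten hours, while exponentially
#' dividing organoids stay below the rupture threshold.
#'
#' @param k_spring spring constant of cell-cell junctions (force/um).
#' @param ell0 rest length of the junction springs (um).
#' @param k_bend stiffness of the sphere-restoring (bending) force
#'   (force/um).
#' @param kappa osmotic pressure conversion constant: the lumped van 't Hoff
#'   factor \eqn{i_{vH} R T} in \eqn{\Pi = \kappa n / V}.
#' @param j_in substance secretion rate per cell (amount per cell per hour).
#' @param j_out substance outflux while the shell is ruptured (amount per
#'   hour) when \code{outflow = "constant"}; when
#'   \code{outflow = "pressure"} the outflux is \code{j_out * P} instead.
#' @param ell_rupt rupture threshold on the mean neighbour distance (um).
#' @param ell_seal reseal threshold on the mean neighbour distance (um);
#'   must be smaller than \code{ell_rupt}.
#' @param gamma drag coefficient (force * hour / um).
#' @param sigma noise amplitude of the positional SDE (um per sqrt hour).
#' @param dt integration time step (hours). Must satisfy the explicit-Euler
#'   stability heuristic \code{dt <= gamma / (4 * k_spring)}.
#' @param rho cell radius (um); daughters inherit it unchanged (cell growth
#'   is neglected).
#' @param p0 initial luminal pressure used to set the initial substance
#'   amount (about 10\% of the rupture-scale pressure by default).
#' @param eps_daughter tangential offset of a daughter cell at division, as
#'   a fraction of the cell radius.
#' @param rebuild_every rebuild the neighbour graph every this many steps
#'   (it is always rebuilt after a division).
#' @param outflow \code{"constant"} (default) or \code{"pressure"}.
#' @param seed integer seed controlling all randomness of a simulation.
#' @return A validated list of class \code{"simulation_params"}.
#' @export
simulation_params <- function(k_spring = 1, ell0 = 20, k_bend = 0.5,
                              kappa = 1, j_in = 3, j_out = 4000,
                              ell_rupt = 22, ell_seal = 21,
                              gamma = 1, sigma = 0.05, dt = 0.01,
                              rho = 10, p0 = 7e-4, eps_daughter = 0.2,
                              rebuild_every = 5L,
                              outflow = c("constant", "pressure"),
                              seed = 1L) {
  outflow <- match.arg(outflow)
  p <- list(k_spring = k_spring, ell0 = ell0, k_bend = k_bend, kappa = kappa,
            j_in = j_in, j_out = j_out, ell_rupt = ell_rupt,
            ell_seal = ell_seal, gamma = gamma, sigma = sigma, dt = dt,
            rho = rho, p0 = p0, eps_daughter = eps_daughter,
            rebuild_every = as.integer(rebuild_every), outflow = outflow,
            seed = as.integer(seed))
  num <- c("k_spring", "ell0", "k_bend", "kappa", "j_in", "j_out",
           "ell_rupt", "ell_seal", "gamma", "dt", "rho", "p0",
           "eps_daughter")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("parameter '%s' must be a positive finite scalar", f))
    }
  }
  if (!is.numeric(p$sigma) || p$sigma < 0) stop("parameter 'sigma' must be >= 0")
  if (p$ell_seal >= p$ell_rupt) stop("ell_seal must be smaller than ell_rupt")
  if (p$dt > p$gamma / (4 * p$k_spring)) {
    stop("dt exceeds the stability bound gamma / (4 * k_spring)")
  }
  if (p$rebuild_every < 1L) stop("rebuild_every must be >= 1")
  class(p) <- "simulation_params"
  p
}

#' Cell division schedule
#'
#' Describes how the realised cell number N(t) of a simulated organoid
#' grows. Rate modes draw division counts from Poisson distributions with
#' the instantaneous rate; with \code{stochastic = FALSE} (and in
#' \code{table} mode) the realised count deterministically tracks the target
#' curve by rounding.
#'
#' @param mode one of \code{"exponential"} (rate \code{r} per cell per
#'   hour), \code{"linear"} (\code{m} cells per hour),
#'   \code{"piecewise_exp_linear"} (exponential up to \code{t_star}, then a
#'   continuous linear continuation with slope \code{m}), or \code{"table"}
#'   (linear interpolation of a (time, target count) lookup table).
#' @param r exponential division rate (1/h).
#' @param m linear division rate (cells/h).
#' @param t_star transition time from exponential to linear growth (h).
#' @param table data frame with columns \code{t} and \code{count}
#'   (non-decreasing) for \code{mode = "table"}.
#' @param stochastic draw Poisson division counts (rate modes only).
#' @return A list of class \code{"division_schedule"}.
#' @export
division_schedule <- function(mode = c("exponential", "linear",
                                       "piecewise_exp_linear", "table"),
                              r = 0.05, m = 1, t_star = 60, table = NULL,
                              stochastic = TRUE) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(table) || !all(c("t", "count") %in% names(table))) {
      stop("table mode needs a data frame with columns 't' and 'count'")
    }
    if (is.unsorted(table$t, strictly = TRUE)) stop("table times must be strictly increasing")
    if (is.unsorted(table$count)) stop("table counts must be non-decreasing")
    stochastic <- FALSE
  }
  if (any(c(r, m) < 0)) stop("division rates must be >= 0")
  structure(list(mode = mode, r = r, m = m, t_star = t_star, table = table,
                 stochastic = isTRUE(stochastic)),
            class = "division_schedule")
}

# target cell count of the deterministic division modes
schedule_target <- function(schedule, t, n0) {
  switch(schedule$mode,
    exponential = n0 * exp(schedule$r * t),
    linear = n0 + schedule$m * t,
    piecewise_exp_linear = {
      ts <- schedule$t_star
      ifelse(t <= ts,
             n0 * exp(schedule$r * t),
             n0 * exp(schedule$r * ts) + schedule$m * (t - ts))
    },
    table = stats::approx(schedule$table$t, schedule$table$count, xout = t,
                          rule = 2)$y
  )
}

#' Initialise a spherical organoid shell
#'
#' Places \code{N0} cells quasi-uniformly on a sphere of radius \code{R0}
#' (Fibonacci lattice, optionally jittered), builds the neighbour graph,
#' and initialises the lumen so the osmotic pressure equals
#' \code{params$p0}.
#'
#' @param N0 initial number of cells (>= 4).
#' @param R0 shell radius in um. Defaults to the radius at which each cell
#'   occupies one hexagonal-packing area share at rest length.
#' @param params a \code{\link{simulation_params}} object.
#' @param jitter standard deviation (um) of isotropic Gaussian jitter added
#'   to the lattice positions (drawn from the current RNG stream).
#' @return A list of class \code{"organoid_state"} with elements
#'   \code{time}, \code{pos} (N x 3), \code{ids}, \code{radius}, \code{n}
#'   (lumen substance amount), \code{V_lumen}, \code{sealed}, \code{edges},
#'   \code{centre} and bookkeeping fields.
#' @export
initialize_sphere <- function(N0, R0 = NULL, params = simulation_params(),
                              jitter = 0) {
  if (N0 < 4L) stop("invalid geometry: need at least 4 cells (no hull below 4 points)")
  if (is.null(R0)) R0 <- shell_radius_for(N0, params$ell0)
  if (R0 <= 0) stop("R0 must be positive")
  i <- seq_len(N0) - 1
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i + 1) / N0
  theta <- 2 * pi * i / golden
  rr <- sqrt(pmax(0, 1 - z^2))
  pos <- R0 * cbind(rr * cos(theta), rr * sin(theta), z)
  if (jitter > 0) pos <- pos + matrix(stats::rnorm(3 * N0, sd = jitter), N0, 3L)
  edges <- shell_adjacency(pos)
  V0 <- 4 / 3 * pi * R0^3
  state <- list(
    time = 0,
    pos = pos,
    ids = seq_len(N0),
    radius = rep(params$rho, N0),
    next_id = N0 + 1L,
    n = params$p0 * V0 / params$kappa,
    V_lumen = V0,
    sealed = TRUE,
    edges = edges,
    centre = c(0, 0, 0),  # construction centre; tracked as the centroid later
    R_fit = mean(sqrt(rowSums(pos^2))),
    n0_cells = N0,
    steps_since_rebuild = 0L,
    rupture_event = FALSE
  )
  class(state) <- "organoid_state"
  state
}

# shell radius giving each of N cells a hexagonal-packing area share
# (sqrt(3)/2 * ell0^2) on the sphere surface
shell_radius_for <- function(N, ell0) ell0 * sqrt(sqrt(3) * N / (8 * pi))

#' Forces on every cell of the shell
#'
#' Computes the three force contributions of the model for each cell:
#' junction springs along the neighbour graph, luminal pressure pushing the
#' cells outward along the radial direction (ideal-gas/van 't Hoff law,
#' equal area share per cell), and a harmonic sphere-restoring force toward
#' the instantaneous best-fit radius (the bending term).
#'
#' @param state an \code{"organoid_state"}.
#' @param params a \code{\link{simulation_params}} object.
#' @return A list with \code{total}, \code{spring}, \code{pressure},
#'   \code{bending} (each N x 3), the scalar pressure \code{P}, and the
#'   best-fit radius \code{R_fit}.
#' @export
compute_forces <- function(state, params) {
  pos <- state$pos
  n_cells <- nrow(pos)
  centre <- colMeans(pos)
  rel <- sweep(pos, 2L, centre)
  d <- sqrt(rowSums(rel^2))
  d[d < 1e-12] <- 1e-12
  R_fit <- mean(d)
  rhat <- rel / d

  ## spring forces along neighbour edges (Newton's third law by construction)
  F_spring <- matrix(0, n_cells, 3L)
  edges <- state$edges
  if (nrow(edges) > 0L) {
    dvec <- pos[edges[, 1L], , drop = FALSE] - pos[edges[, 2L], , drop = FALSE]
    len <- sqrt(rowSums(dvec^2))
    bad <- len < 1e-9
    if (any(bad)) {
      warning("degenerate cell pair distance; repulsion capped")
      dvec[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3L, byrow = TRUE)
      len[bad] <- 1e-9
    }
    fmag <- -params$k_spring * (len - params$ell0)
    fmag[bad] <- params$k_spring * params$ell0  # capped repulsion
    f_on_1 <- dvec / len * fmag
    acc <- rowsum(rbind(f_on_1, -f_on_1), c(edges[, 1L], edges[, 2L]))
    idx <- as.integer(rownames(acc))
    F_spring[idx, ] <- acc
  }

  ## pressure force: P * a_i outward, equal area share a_i = 4 pi R^2 / N
  P <- params$kappa * state$n / state$V_lumen
  a_i <- 4 * pi * R_fit^2 / n_cells
  F_pressure <- rhat * (P * a_i)

  ## bending: harmonic restoring toward the best-fit sphere
  F_bending <- rhat * (-params$k_bend * (d - R_fit))

  total <- F_spring + F_pressure + F_bending
  list(total = total, spring = F_spring, pressure = F_pressure,
       bending = F_bending, P = P, R_fit = R_fit)
}

#' Update the lumen: secretion, rupture, venting, resealing
#'
#' Adds the substance secreted by all cells during \code{dt}, applies the
#' rupture rule (shell unseals when the mean neighbour distance exceeds
#' \code{ell_rupt}), vents substance while unsealed (floored at zero), and
#' reseals when the mean neighbour distance falls below \code{ell_seal}.
#' The lumen volume is recomputed from the best-fit radius.
#'
#' @inheritParams compute_forces
#' @param dt time increment in hours.
#' @return The updated \code{"organoid_state"}; \code{$rupture_event} is
#'   \code{TRUE} if the shell unsealed during this call.
#' @export
update_lumen <- function(state, params, dt) {
  n_cells <- nrow(state$pos)
  state$n <- state$n + params$j_in * n_cells * dt
  mnd <- mean_edge_length(state$pos, state$edges)
  state$rupture_event <- FALSE
  if (state$sealed && mnd > params$ell_rupt) {
    state$sealed <- FALSE
    state$rupture_event <- TRUE
  }
  if (!state$sealed) {
    out <- if (params$outflow == "constant") params$j_out * dt
           else params$j_out * (params$kappa * state$n / state$V_lumen) * dt
    state$n <- max(0, state$n - out)
    if (mnd < params$ell_seal) state$sealed <- TRUE
  }
  centre <- colMeans(state$pos)
  state$centre <- centre
  state$R_fit <- mean(sqrt(rowSums(sweep(state$pos, 2L, centre)^2)))
  state$V_lumen <- 4 / 3 * pi * state$R_fit^3
  state
}

#' Divide cells according to a schedule
#'
#' Realises the divisions falling into the step ending at
#' \code{state$time}. Deterministic modes round the target curve; rate
#' modes draw Poisson counts. Each daughter is placed a small tangential
#' offset away from its parent and inherits the parent radius (cell growth
#' is neglected). The neighbour graph is rebuilt after any division.
#'
#' @inheritParams compute_forces
#' @param schedule a \code{\link{division_schedule}}.
#' @param dt duration of the step being completed (hours).
#' @return The updated \code{"organoid_state"}.
#' @export
divide_cells <- function(state, schedule, params, dt) {
  n_cells <- nrow(state$pos)
  n_div <- if (schedule$stochastic) {
    lambda <- switch(schedule$mode,
      exponential = schedule$r * n_cells * dt,
      linear = schedule$m * dt,
      piecewise_exp_linear = if (state$time <= schedule$t_star)
        schedule$r * n_cells * dt else schedule$m * dt,
      table = stop("table mode is deterministic")
    )
    stats::rpois(1L, lambda)
  } else {
    target <- schedule_target(schedule, state$time, state$n0_cells)
    max(0L, as.integer(round(target)) - n_cells)
  }
  if (n_div == 0L) return(state)
  centre <- colMeans(state$pos)
  for (k in seq_len(n_div)) {
    parent <- sample.int(nrow(state$pos), 1L)
    radial <- state$pos[parent, ] - centre
    radial <- radial / max(sqrt(sum(radial^2)), 1e-12)
    v <- stats::rnorm(3L)
    v <- v - sum(v * radial) * radial
    nv <- sqrt(sum(v^2))
    v <- if (nv < 1e-12) cross3(radial, c(1, 0, 0)) else v / nv
    daughter <- state$pos[parent, ] + params$eps_daughter * state$radius[parent] * v
    state$pos <- rbind(state$pos, daughter)
    state$radius <- c(state$radius, state$radius[parent])
    state$ids <- c(state$ids, state$next_id)
    state$next_id <- state$next_id + 1L
  }
  state$edges <- shell_adjacency(state$pos)
  state$steps_since_rebuild <- 0L
  state
}

#' One Euler-Maruyama step of the organoid model
#'
#' Advances the positions by drift \code{F / gamma * dt} plus noise
#' \code{sigma * sqrt(dt) * xi} (standard normal \code{xi}; with
#' \code{sigma = 0} the map is the deterministic explicit Euler update and
#' no random numbers are consumed for the displacement), then updates the
#' lumen, applies scheduled divisions and advances time by \code{dt}.
#'
#' @inheritParams divide_cells
#' @param record_noise if \code{TRUE}, the noise matrix \code{xi} is
#'   attached to the result as attribute \code{"xi"}.
#' @return The updated \code{"organoid_state"}.
#' @export
step_organoid <- function(state, params, schedule = NULL,
                          record_noise = FALSE) {
  if (state$steps_since_rebuild >= params$rebuild_every) {
    state$edges <- shell_adjacency(state$pos)
    state$steps_since_rebuild <- 0L
  }
  f <- compute_forces(state, params)
  if (!all(is.finite(f$total))) {
    bad <- which(rowSums(!is.finite(f$total)) > 0L)[1L]
    stop(sprintf(
      "integration blow-up: non-finite force on cell id %d at t = %.4f h",
      state$ids[bad], state$time))
  }
  dt <- params$dt
  disp <- f$total / params$gamma * dt
  if (params$sigma > 0) {
    xi <- matrix(stats::rnorm(3L * nrow(state$pos)), ncol = 3L)
    disp <- disp + params$sigma * sqrt(dt) * xi
  } else {
    xi <- NULL
  }
  state$pos <- state$pos + disp
  state$steps_since_rebuild <- state$steps_since_rebuild + 1L
  state <- update_lumen(state, params, dt)
  state$time <- state$time + dt
  if (!is.null(schedule)) state <- divide_cells(state, schedule, params, dt)
  if (record_noise) attr(state, "xi") <- xi
  state
}

#' Simulate an organoid trajectory
#'
#' Runs the agent-based model from a fresh spherical shell for
#' \code{t_end} hours and records per-step summaries.
#'
#' @param params a \code{\link{simulation_params}} (its \code{seed} seeds
#'   all randomness of the run).
#' @param schedule a \code{\link{division_schedule}} or \code{NULL} for no
#'   division.
#' @param t_end simulated time horizon in hours.
#' @param N0 initial cell number.
#' @param R0 initial shell radius (default: packing radius for \code{N0}).
#' @param jitter initial position jitter in um.
#' @param record_every record one summary row every this many steps.
#' @return A data frame of class \code{"organoid_trajectory"} with columns
#'   \code{t}, \code{N}, \code{V_lumen}, \code{R_fit}, \code{n}, \code{P},
#'   \code{sealed}, \code{rupture_event} (0/1; ruptures between recorded
#'   rows are accumulated onto the next recorded row). The final state is
#'   attached as attribute \code{"final_state"}.
#' @export
simulate_organoid <- function(params = simulation_params(), schedule = NULL,
                              t_end = 100, N0 = 64, R0 = NULL, jitter = 0.5,
                              record_every = 1L) {
  if (t_end <= 0) stop("t_end must be positive")
  set.seed(params$seed)
  state <- initialize_sphere(N0, R0, params, jitter = jitter)
  n_steps <- ceiling(t_end / params$dt)
  n_rec <- floor(n_steps / record_every) + 1L
  out <- matrix(NA_real_, n_rec, 8L)
  colnames(out) <- c("t", "N", "V_lumen", "R_fit", "n", "P", "sealed",
                     "rupture_event")
  snap <- function(state, ruptures) {
    c(state$time, nrow(state$pos), state$V_lumen, state$R_fit, state$n,
      params$kappa * state$n / state$V_lumen, as.numeric(state$sealed),
      ruptures)
  }
  out[1L, ] <- snap(state, 0)
  rec <- 1L
  pending_ruptures <- 0
  for (s in seq_len(n_steps)) {
    state <- step_organoid(state, params, schedule)
    pending_ruptures <- pending_ruptures + as.numeric(state$rupture_event)
    if (s %% record_every == 0L) {
      rec <- rec + 1L
      out[rec, ] <- snap(state, pending_ruptures)
      pending_ruptures <- 0
    }
  }
  traj <- as.data.frame(out[seq_len(rec), , drop = FALSE])
  class(traj) <- c("organoid_trajectory", "data.frame")
  attr(traj, "params") <- params
  attr(traj, "final_state") <- state
  traj
}

#' @export
print.organoid_trajectory <- function(x, ...) {
  cat(sprintf(
    "organoid trajectory: %d records, t = [%g, %g] h, N = %d -> %d, %d rupture(s)\n",
    nrow(x), min(x$t), max(x$t), as.integer(x$N[1L]),
    as.integer(x$N[nrow(x)]), as.integer(sum(x$rupture_event))))
  invisible(x)
}
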