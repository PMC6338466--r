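# Langevin integration, neighbour bookkeeping, run scheduling, trajectory
# recording.  The inner loop lives in compiled code (src/engine.cpp); runs
# are bit-reproducible for a given master seed on a single thread.

#' Thermal force samples
#'
#' Gaussian random forces with zero mean and variance `2 gamma kBT / dt`
#' per component per step (the discrete-delta form of the
#' fluctuation-dissipation relation), independent across beads and
#' components.
#'
#' @param params an `mt_params`.
#' @param n_beads number of beads.
#' @param seed integer seed.
#' @return n_beads x 2 matrix of force components.
#' @export
thermal_force <- function(params, n_beads, seed = params$master_seed) {
  v <- cpp_thermal_samples(2L * n_beads, params$friction,
                           params$temperature, params$timestep,
                           as.double(seed))
  matrix(v, ncol = 2, byrow = TRUE)
}

#' Neighbour pair list
#'
#' All distinct bead pairs (i < j, each listed once) within `cutoff + skin`
#' under the minimum-image convention, built with a cell list (automatic
#' fallback to the all-pairs scan when the box holds fewer than three cells
#' per edge).  Exact: verified against the O(N^2) scan in the tests.
#'
#' @param state an `mt_state`.
#' @param cutoff interaction cutoff.
#' @param skin extra shell added to the cutoff (Verlet skin).
#' @return k x 2 integer matrix of bead indices.
#' @export
build_neighbor_pairs <- function(state, cutoff, skin = 0) {
  cpp_neighbor_pairs(unwrap_positions(state), state$filament,
                     state$box_edge, cutoff + skin, FALSE)
}

#' Advance a state by Langevin velocity-Verlet steps
#'
#' One (or more) velocity-Verlet steps with Langevin drag and thermal noise;
#' motor bonds are resampled at every force evaluation and act for exactly
#' one timestep.  Image flags are updated on wrap.  A bead displacement
#' exceeding `sigma/2` in one step raises an instability error.
#'
#' @param state an `mt_state`.
#' @param params an `mt_params`.
#' @param seed integer seed for thermostat and motor streams.
#' @param n_steps number of steps to take.
#' @return the advanced `mt_state`.
#' @export
langevin_step <- function(state, params, seed = params$master_seed,
                          n_steps = 1L) {
  res <- cpp_run(unwrap_positions(state), state$velocities, state$filament,
                 unclass(params), as.integer(n_steps), integer(0),
                 as.double(seed), FALSE)
  w <- wrap_positions(res$x_final, state$box_edge)
  state$positions <- w$positions
  state$image_flags <- w$image_flags
  state$velocities <- res$v_final
  state$time <- state$time + n_steps * params$timestep / params$rotation_time
  state
}

#' Log-block frame-save schedule
#'
#' Union of a fine prefix (every step), a mid-resolution block, and a coarse
#' uniform grid spanning the whole production run, so that lag times over
#' several decades are available without saving every step.
#'
#' @param production_steps total number of production steps.
#' @param fine_until save every step up to this step.
#' @param mid_every,mid_until save every `mid_every` steps up to `mid_until`.
#' @param coarse_every save every `coarse_every` steps throughout.
#' @return sorted integer vector of step indices (0 = production start).
#' @export
save_schedule <- function(production_steps, fine_until = 0,
                          mid_every = 0, mid_until = 0,
                          coarse_every = max(1L,
                                             production_steps %/% 400L)) {
  s <- c(0L, seq_len(min(fine_until, production_steps)))
  if (mid_every > 0 && mid_until > 0) {
    s <- c(s, seq(0L, min(mid_until, production_steps), by = mid_every))
  }
  s <- c(s, seq(0L, production_steps, by = coarse_every), production_steps)
  sort(unique(as.integer(s)))
}

#' Run a full simulation
#'
#' Equilibrates passively (motors forced off), optionally warms up with
#' motors on, then runs production saving unwrapped coordinates at the
#' scheduled steps together with the per-term energy ledger and the motor
#' bond count per saved frame.
#'
#' @param params an `mt_params`.
#' @param schedule list with `equilibration_steps` (passive),
#'   `warmup_steps` (active, default 0), `production_steps`, and either
#'   `save_every` (uniform cadence) or `save_steps` (explicit step indices,
#'   0 = production start).
#' @param seed master seed (defaults to `params$master_seed`).
#' @param init_state optional starting `mt_state`; defaults to
#'   [lattice_init()].
#' @param record_velocities keep per-frame velocities.
#' @return an `mt_traj`: frames (`[frame, bead, xy]`, unwrapped), `times`
#'   in units of `tauR` (0 = production start), `energies`, `motor_counts`,
#'   plus the parameter snapshot and seed needed to regenerate it.
#' @export
run_simulation <- function(params, schedule, seed = params$master_seed,
                           init_state = NULL, record_velocities = FALSE) {
  stopifnot(is.list(schedule))
  eq <- as.integer(schedule$equilibration_steps %||% 0L)
  wu <- as.integer(schedule$warmup_steps %||% 0L)
  np <- as.integer(schedule$production_steps)
  if (is.null(np) || np < 1) stop("production_steps must be >= 1",
                                  call. = FALSE)
  save_steps <- if (!is.null(schedule$save_steps)) {
    sort(unique(as.integer(schedule$save_steps)))
  } else if (!is.null(schedule$save_every)) {
    sort(unique(c(seq(0L, np, by = as.integer(schedule$save_every)), np)))
  } else {
    save_schedule(np)
  }
  if (any(save_steps < 0 | save_steps > np)) {
    stop("save steps outside production range", call. = FALSE)
  }

  st <- if (is.null(init_state)) lattice_init(params, seed) else init_state
  pl <- unclass(params)

  if (eq > 0) {
    pl_pass <- pl
    pl_pass$motor_probability <- 0
    res <- cpp_run(unwrap_positions(st), st$velocities, st$filament, pl_pass,
                   eq, integer(0), as.double(seed) * 8 + 1, FALSE)
    st <- replace_coords(st, res)
  }
  if (wu > 0) {
    res <- cpp_run(unwrap_positions(st), st$velocities, st$filament, pl,
                   wu, integer(0), as.double(seed) * 8 + 2, FALSE)
    st <- replace_coords(st, res)
  }
  res <- cpp_run(unwrap_positions(st), st$velocities, st$filament, pl,
                 np, save_steps, as.double(seed) * 8 + 3,
                 record_velocities)

  n <- nrow(st$positions)
  nfr <- length(save_steps)
  frames <- array(res$frames, dim = c(nfr, n, 2))
  energies <- as.data.frame(res$energies)
  names(energies) <- c("bond", "angle", "wca", "motor")
  out <- structure(list(
    frames       = frames,
    steps        = res$steps,
    times        = res$steps * params$timestep / params$rotation_time,
    filament     = st$filament,
    rank         = st$rank,
    params       = params,
    energies     = energies,
    motor_counts = res$motor_counts,
    seed         = seed,
    schedule     = list(equilibration_steps = eq, warmup_steps = wu,
                        production_steps = np)
  ), class = "mt_traj")
  if (record_velocities) {
    out$velocities <- array(res$velocities, dim = c(nfr, n, 2))
  }
  out
}

replace_coords <- function(state, res) {
  w <- wrap_positions(res$x_final, state$box_edge)
  state$positions <- w$positions
  state$image_flags <- w$image_flags
  state$velocities <- res$v_final
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mt_traj <- function(x, ...) {
  cat(sprintf(
    "<mt_traj> %d frames, %d beads / %d filaments, t = %.4g..%.4g tauR (pa = %g, phi = %.3g)\n",
    dim(x$frames)[1], dim(x$frames)[2], length(unique(x$filament)),
    min(x$times), max(x$times), x$params$motor_probability,
    x$params$surface_fraction))
  invisible(x)
}

#' Per-frame filament centres of mass
#'
#' @param traj an `mt_traj`.
#' @return array `[frame, filament, xy]` of unwrapped centre-of-mass
#'   coordinates.
#' @export
traj_com <- function(traj) {
  d <- dim(traj$frames)
  nf <- length(unique(traj$filament))
  nb <- d[2] / nf
  f4 <- array(traj$frames, dim = c(d[1], nb, nf, 2))
  com <- colMeans(aperm(f4, c(2, 1, 3, 4))) # mean over bead dim
  array(com, dim = c(d[1], nf, 2))
}

#' Per-frame filament end-to-end orientations
#'
#' @param traj an `mt_traj`.
#' @return array `[frame, filament, xy]` of unit orientation vectors
#'   (first to last bead).
#' @export
traj_orientations <- function(traj) {
  d <- dim(traj$frames)
  nf <- length(unique(traj$filament))
  nb <- d[2] / nf
  first <- which(traj$rank == 1)
  last <- which(traj$rank == nb)
  e <- traj$frames[, last, , drop = FALSE] -
    traj$frames[, first, , drop = FALSE]
  nrm <- sqrt(e[, , 1]^2 + e[, , 2]^2)
  if (any(nrm <= 0)) stop("zero end-to-end vector in trajectory",
                          call. = FALSE)
  e[, , 1] <- e[, , 1] / nrm
  e[, , 2] <- e[, , 2] / nrm
  e
}

#' Extract one frame of a trajectory as a state
#'
#' @param traj an `mt_traj`.
#' @param frame frame index (1-based).
#' @return an `mt_state` (velocities zero unless recorded).
#' @export
traj_frame <- function(traj, frame) {
  x <- traj$frames[frame, , ]
  v <- if (!is.null(traj$velocities)) traj$velocities[frame, , ] else
    matrix(0, dim(traj$frames)[2], 2)
  st <- new_state(x, v, traj$filament, traj$params$box_edge,
                  time = traj$times[frame])
  st
}
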