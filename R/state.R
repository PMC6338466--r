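# System state: bead positions in a periodic box, filament membership,
# initial-configuration generators.

new_state <- function(positions, velocities, filament, box_edge, time = 0) {
  n <- nrow(positions)
  image <- matrix(0L, n, 2)
  wrapped <- positions
  for (k in 1:2) {
    img <- floor(positions[, k] / box_edge)
    image[, k] <- as.integer(img)
    wrapped[, k] <- positions[, k] - img * box_edge
  }
  rank <- stats::ave(seq_len(n), filament, FUN = seq_along)
  structure(list(
    positions   = wrapped,
    image_flags = image,
    velocities  = velocities,
    filament    = as.integer(filament),
    rank        = as.integer(rank),
    box_edge    = box_edge,
    time        = time
  ), class = "mt_state")
}

#' @export
print.mt_state <- function(x, ...) {
  cat(sprintf("<mt_state> %d beads / %d filaments, box %.4g sigma, t = %.4g tauR\n",
              nrow(x$positions), length(unique(x$filament)), x$box_edge,
              x$time))
  invisible(x)
}

#' Unwrapped bead coordinates of a state
#'
#' Wrapped coordinates lie in `[0, Lb)^2`; the unwrapped position is
#' `wrapped + image_flags * Lb`, continuous across box crossings.
#'
#' @param state an `mt_state`.
#' @return n x 2 matrix of unwrapped coordinates.
#' @export
unwrap_positions <- function(state) {
  state$positions + state$image_flags * state$box_edge
}

#' Wrap coordinates into the periodic box
#'
#' @param x n x 2 coordinate matrix.
#' @param box_edge box edge length `Lb`.
#' @return list with `positions` (wrapped into `[0, Lb)`) and integer
#'   `image_flags` such that `positions + image_flags * Lb` reproduces `x`.
#' @export
wrap_positions <- function(x, box_edge) {
  img <- floor(x / box_edge)
  list(positions = x - img * box_edge,
       image_flags = matrix(as.integer(img), nrow(x), 2))
}

# minimum-image difference
min_image <- function(d, box_edge) d - box_edge * round(d / box_edge)

#' Per-filament centres of mass and orientations of a state
#'
#' The orientation is the end-to-end unit vector from the first to the last
#' bead of each filament; `bead_orientations` gives the per-bead local
#' orientation (direction of the bond to the next bead; the last bead of a
#' filament reuses the preceding bond).
#'
#' @param state an `mt_state`.
#' @return `filament_views`: list with `com` (nf x 2, unwrapped),
#'   `orientation` (nf x 2 unit vectors); `bead_orientations`: n x 2 matrix.
#' @export
filament_views <- function(state) {
  xu <- unwrap_positions(state)
  nf <- length(unique(state$filament))
  nb <- nrow(xu) / nf
  first <- which(state$rank == 1)
  last <- which(state$rank == nb)
  com <- rowsum(xu, state$filament) / nb
  e <- xu[last, , drop = FALSE] - xu[first, , drop = FALSE]
  nrm <- sqrt(rowSums(e^2))
  if (any(nrm <= 0)) stop("zero end-to-end vector", call. = FALSE)
  list(com = com, orientation = e / nrm)
}

#' @rdname filament_views
#' @export
bead_orientations <- function(state) {
  xu <- unwrap_positions(state)
  n <- nrow(xu)
  nxt <- c(seq_len(n - 1) + 1L, n)
  same <- c(state$filament[-1] == state$filament[-n], FALSE)
  from <- ifelse(same, seq_len(n), seq_len(n) - 1L)
  to <- ifelse(same, seq_len(n) + 1L, seq_len(n))
  d <- xu[to, , drop = FALSE] - xu[from, , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm <= 0)) stop("zero-length bond", call. = FALSE)
  d / nrm
}

#' Nematic-lattice initial configuration
#'
#' Places straight filaments on a nematic lattice (all axes along x), assigns
#' each filament a head/tail direction by a fair coin flip, applies a small
#' positional jitter, and draws velocities from the Maxwell distribution at
#' `kBT`.  Placement guarantees no inter-filament bead pair closer than
#' `sigma`; if the requested surface fraction cannot be accommodated the
#' function fails with a placement error.
#'
#' @param params an `mt_params`.
#' @param seed integer seed (defaults to `params$master_seed`).
#' @return an `mt_state`.
#' @export
lattice_init <- function(params, seed = params$master_seed) {
  p <- params
  Lb <- p$box_edge
  L <- filament_length(p)
  sig <- p$bead_diameter
  nf <- p$n_filaments
  nb <- p$beads_per_filament
  jit <- 0.05 * sig

  ncol_ <- max(1L, floor(Lb / (L + 1.2 * sig)))
  nrow_ <- ceiling(nf / ncol_)
  py <- Lb / nrow_
  px <- Lb / ncol_
  if (py < 1.1 * sig + 2 * jit || px < L + 1.1 * sig + 2 * jit) {
    stop(sprintf(
      "placement error: cannot place %d filaments of length %g in box %g without overlap",
      nf, L, Lb), call. = FALSE)
  }

  set.seed(seed)
  fil <- rep(seq_len(nf), each = nb)
  x <- numeric(nf * nb)
  y <- numeric(nf * nb)
  s <- seq(0, L, length.out = nb)
  k <- 0L
  for (f in seq_len(nf)) {
    row <- (f - 1L) %/% ncol_
    col <- (f - 1L) %% ncol_
    cx <- (col + 0.5) * px + runif(1, -jit, jit)
    cy <- (row + 0.5) * py + runif(1, -jit, jit)
    flip <- rbinom(1, 1, 0.5) == 1
    xs <- cx - L / 2 + (if (flip) rev(s) else s)
    x[k + seq_len(nb)] <- xs
    y[k + seq_len(nb)] <- cy
    k <- k + nb
  }
  vel <- matrix(rnorm(2 * nf * nb, sd = sqrt(p$temperature / p$bead_mass)),
                ncol = 2)
  st <- new_state(cbind(x, y), vel, fil, Lb)
  # verify the no-overlap guarantee
  pr <- build_neighbor_pairs(st, cutoff = sig)
  if (nrow(pr)) {
    inter <- st$filament[pr[, 1]] != st$filament[pr[, 2]]
    if (any(inter)) {
      stop("placement error: inter-filament bead pair closer than sigma",
           call. = FALSE)
    }
  }
  st
}

#' Two-filament test geometry
#'
#' Builds two straight filaments with a given lateral separation and
#' relative angle; `relative_polarity = "antiparallel"` reverses the bead
#' ordering of the second filament (flipping its orientation vector while
#' keeping the same bead positions).
#'
#' @param separation lateral distance between the filament axes (>= 0).
#' @param relative_angle angle (radians) between the two axes.
#' @param relative_polarity `"antiparallel"` or `"parallel"`.
#' @param params an `mt_params`; defaults to a two-filament set in a box of
#'   `4 L` so that periodic images do not interact.
#' @return an `mt_state` (velocities zero).
#' @export
two_filament_fixture <- function(separation,
                                 relative_angle = 0,
                                 relative_polarity = c("antiparallel",
                                                       "parallel"),
                                 params = NULL) {
  relative_polarity <- match.arg(relative_polarity)
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (is.null(params)) {
    params <- make_params(list(nf = 2, Lb = 4 * 10))
  }
  nb <- params$beads_per_filament
  L <- filament_length(params)
  Lb <- params$box_edge
  s <- seq(-L / 2, L / 2, length.out = nb)
  c1 <- c(Lb / 2, Lb / 2)
  x1 <- cbind(c1[1] + s, c1[2])
  u <- c(cos(relative_angle), sin(relative_angle))
  c2 <- c1 + c(0, separation)
  x2 <- cbind(c2[1] + s * u[1], c2[2] + s * u[2])
  if (relative_polarity == "antiparallel") x2 <- x2[rev(seq_len(nb)), ]
  new_state(rbind(x1, x2), matrix(0, 2 * nb, 2), rep(1:2, each = nb), Lb)
}

#' Measure the rotational diffusion time of a single passive filament
#'
#' Runs dilute passive filaments (`pa = 0`, non-interacting: one filament
#' per replicate box), computes the orientational autocorrelation, and fits
#' its exponential decay.  The fitted decay time is the rotational diffusion
#' time `tauR` that serves as the unit of time.  The bead-rod theory value
#' `gamma * r0^2 * sum(k^2) / kBT = 192.5` (21 beads at spacing `sigma/2`)
#' is the default `rotation_time` and the oracle this calibration is tested
#' against.
#'
#' @param params an `mt_params` (its filament geometry is used; density is
#'   ignored - the calibration runs one filament per box).
#' @param seed integer seed.
#' @param n_replicates number of independent filaments averaged.
#' @param t_max run length per replicate in units of the theory `tauR`.
#' @return the fitted `tauR` (internal time units) with attributes
#'   `ci` (95% interval) and `fit` (the lm fit of log-correlation vs lag).
#' @export
calibrate_tau_r <- function(params, seed = params$master_seed,
                            n_replicates = 6, t_max = 6) {
  p <- params
  p$n_filaments <- 1L
  p$motor_probability <- 0
  p$surface_fraction <- NULL
  p$box_edge <- 8 * filament_length(p)
  p <- make_params(unclass(p)[!vapply(unclass(p), is.null, TRUE)])
  p$motor_probability <- 0

  tau_theory <- p$rotation_time
  n_steps <- ceiling(t_max * tau_theory / p$timestep)
  save_every <- max(1L, round(0.02 * tau_theory / p$timestep))

  corrs <- NULL
  lags <- NULL
  for (rep_i in seq_len(n_replicates)) {
    st <- lattice_init(p, seed = seed + rep_i)
    traj <- run_simulation(p, schedule = list(
      equilibration_steps = round(0.05 * tau_theory / p$timestep),
      production_steps = n_steps, save_every = save_every
    ), seed = seed + rep_i, init_state = st)
    ors <- traj_orientations(traj)[, 1, ] # frames x 2
    nfr <- nrow(ors)
    max_off <- floor(nfr * 0.6)
    cc <- vapply(seq_len(max_off), function(off) {
      i <- seq_len(nfr - off)
      mean(rowSums(ors[i, , drop = FALSE] * ors[i + off, , drop = FALSE]))
    }, numeric(1))
    corrs <- if (is.null(corrs)) cc else corrs + cc
    lags <- traj$times[1 + seq_len(max_off)] - traj$times[1]
  }
  corrs <- corrs / n_replicates
  use <- corrs > 0.05
  if (sum(use) < 5 || min(corrs) > exp(-1)) {
    stop("calibration error: orientational correlation did not decay enough to fit",
         call. = FALSE)
  }
  # lags are in units of tau_theory; fit in internal time units
  t_int <- lags * tau_theory
  fit <- lm(log(corrs[use]) ~ t_int[use])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("calibration error: exponential fit failed to converge",
         call. = FALSE)
  }
  tau <- -1 / slope
  ci_sl <- suppressWarnings(confint(fit)[2, ])
  ci <- sort(-1 / ci_sl)
  structure(tau, ci = ci, fit = fit)
}
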