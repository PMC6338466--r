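# Extraction of the five characteristic streaming timescales and the
# derived demonstrations (chronology table, FRAP-style labelling, motile
# fraction, step-correlation colouring).
#
# Extrema are located on the log-lag grid and refined by parabolic
# interpolation; a significance gate of 3 standard errors guards against
# noise-picked extrema.

# parabolic refinement of an extremum at grid index k in log-lag
refine_log_parabola <- function(lags, values, k) {
  if (k <= 1 || k >= length(lags)) return(lags[k])
  x <- log(lags[(k - 1):(k + 1)])
  y <- values[(k - 1):(k + 1)]
  d2 <- y[1] - 2 * y[2] + y[3]
  if (!is.finite(d2) || d2 == 0) return(lags[k])
  xv <- x[2] - 0.5 * (x[3] - x[1]) * (y[3] - y[1]) / (2 * d2)
  xv <- min(max(xv, x[1]), x[3])
  exp(xv)
}

unresolved <- function(reason) {
  list(time = NA_real_, ci = c(NA_real_, NA_real_), resolved = FALSE,
       reason = reason)
}

resolved_time <- function(time, lags, k) {
  # conservative CI: the neighbouring grid interval around the extremum
  lo <- if (k > 1) lags[k - 1] else lags[k]
  hi <- if (k < length(lags)) lags[k + 1] else lags[k]
  list(time = time, ci = c(lo, hi), resolved = TRUE, reason = NULL)
}

#' Sliding time: lag of the negative minimum of Nd
#'
#' The lag at which the neighbour displacement correlation is most negative
#' marks maximal antialigned propulsion.  The minimum must be negative and
#' exceed 3 standard errors in depth, otherwise the time is reported as
#' unresolved (the expected outcome for passive systems, where Nd stays
#' positive).
#'
#' @param nd an `mt_corr` of kind `"Nd"`.
#' @return list with `time` (tauR), `ci`, `resolved`, `reason`.
#' @export
extract_tau_n_min <- function(nd) {
  v <- nd$value
  k <- which.min(v)
  se <- nd$stderr[k]
  if (!is.finite(v[k]) || v[k] >= 0 ||
      (is.finite(se) && -v[k] < 3 * se)) {
    return(unresolved("no significant negative minimum in Nd"))
  }
  if (k == 1 || k == length(v)) {
    return(unresolved("Nd minimum at the lag-range boundary (not bracketed)"))
  }
  resolved_time(refine_log_parabola(nd$lag, v, k), nd$lag, k)
}

#' Collective-migration time: lag of the positive maximum of Nd
#'
#' Mirrors [extract_tau_n_min()] for the positive lobe of Nd at
#' intermediate lags; unresolved when no significant positive maximum
#' exists (low surface fractions).
#'
#' @inheritParams extract_tau_n_min
#' @return list with `time`, `ci`, `resolved`, `reason`.
#' @export
extract_tau_n_max <- function(nd) {
  v <- nd$value
  k <- which.max(v)
  se <- nd$stderr[k]
  if (!is.finite(v[k]) || v[k] <= 0 ||
      (is.finite(se) && v[k] < 3 * se)) {
    return(unresolved("no significant positive maximum in Nd"))
  }
  if (k == 1 || k == length(v)) {
    return(unresolved("Nd maximum at the lag-range boundary (not bracketed)"))
  }
  resolved_time(refine_log_parabola(nd$lag, v, k), nd$lag, k)
}

#' Polarity-inversion time: half-decay of Q(tau)
#'
#' The first downward crossing of `Q = 0.5`, linearly interpolated in
#' log-lag.  Unresolved when Q never decays below one half within the lag
#' range.
#'
#' @param q an `mt_corr` of kind `"Q"`.
#' @return list with `time`, `ci`, `resolved`, `reason`.
#' @export
extract_tau_q_half <- function(q) {
  lag <- q$lag[q$lag > 0]
  v <- q$value[q$lag > 0]
  below <- which(v < 0.5)
  if (!length(below)) return(unresolved("Q never decays below 0.5"))
  k <- below[1]
  if (v[k] == 0.5 || k == 1) {
    return(resolved_time(lag[k], lag, k))
  }
  above <- k - 1
  if (v[above] == 0.5) {
    return(resolved_time(lag[above], lag, above))
  }
  x1 <- log(lag[above]); x2 <- log(lag[k])
  y1 <- v[above]; y2 <- v[k]
  xc <- x1 + (0.5 - y1) * (x2 - x1) / (y2 - y1)
  resolved_time(exp(xc), lag, k)
}

#' Activity time: lag of maximal parallel-velocity skew
#'
#' The lag at which the skew of the orientation-projected velocity
#' distribution peaks; the maximum must be positive and exceed 3 standard
#' errors.  Not defined for passive systems.
#'
#' @param skew an `mt_corr` of kind `"skew"`.
#' @return list with `time`, `ci`, `resolved`, `reason`.
#' @export
extract_tau_star <- function(skew) {
  v <- skew$value
  k <- which.max(v)
  se <- skew$stderr[k]
  if (!is.finite(v[k]) || v[k] <= 0 ||
      (is.finite(se) && v[k] < 3 * se)) {
    return(unresolved("no significant positive skew maximum"))
  }
  if (k == 1 || k == length(v)) {
    return(unresolved("skew maximum at the lag-range boundary (not bracketed)"))
  }
  resolved_time(refine_log_parabola(skew$lag, v, k), skew$lag, k)
}

#' Assemble the chronology of streaming timescales
#'
#' Computes the neighbour correlation, the polar-order relaxation, the skew
#' series, and the orientational correlation of a trajectory, extracts the
#' five characteristic times (sliding `tau_N_min`, polarity inversion
#' `tau_Q_half`, maximal activity `tau_star`, collective migration
#' `tau_N_max`, active rotation `tau_r`), and checks the chronology
#' ordering on the resolved entries (an inverted consecutive pair counts
#' as a violation only when the two confidence intervals are disjoint;
#' nearly simultaneous processes may tie within noise).
#'
#' @param traj an `mt_traj`.
#' @param lags lag grid in `tauR` (default log-spaced over the trajectory).
#' @param max_origins cap on time origins per lag.
#' @return an `mt_chronology` list: the five timescale entries, the
#'   component series, `ordering_ok`, and a parameter snapshot.
#' @export
assemble_chronology <- function(traj, lags = NULL, max_origins = 48L) {
  if (is.null(lags)) lags <- default_lags(traj$times, n = 20)
  nd <- neighbour_correlation(traj, lags, max_origins = max_origins)
  qs <- tryCatch(polar_order_deviation(traj, "antialigned", lags,
                                       max_origins = max_origins),
                 error = function(e) NULL)
  sk <- tryCatch(skew_series(traj, lags, max_origins = max_origins),
                 error = function(e) NULL)
  oc <- orientational_correlation(traj, lags, max_origins = max_origins)

  tau_n_min <- extract_tau_n_min(nd)
  tau_n_max <- extract_tau_n_max(nd)
  tau_q_half <- if (is.null(qs)) {
    unresolved("Q(tau) not computable")
  } else {
    extract_tau_q_half(qs)
  }
  tau_star <- if (is.null(sk)) {
    unresolved("skew series not computable")
  } else {
    extract_tau_star(sk)
  }
  fr <- fit_tau_r(oc)
  tau_r <- if (fr$resolved) {
    list(time = fr$tau_r, ci = fr$ci, resolved = TRUE, reason = NULL)
  } else {
    list(time = NA_real_, ci = c(fr$lower_bound, Inf), resolved = FALSE,
         reason = "orientational correlation did not decay below 1/e")
  }

  entries <- list(tau_n_min, tau_q_half, tau_star, tau_n_max, tau_r)
  resolved <- Filter(function(e) e$resolved, entries)
  # ordering on resolved entries; an inverted consecutive pair only counts
  # as a violation when the two confidence intervals are disjoint
  # (estimates of nearly simultaneous processes are allowed to tie)
  ordering_ok <- if (length(resolved) >= 2) {
    ok <- TRUE
    for (k in seq_len(length(resolved) - 1)) {
      a <- resolved[[k]]
      b <- resolved[[k + 1]]
      if (b$time < a$time &&
          max(a$ci[1], b$ci[1]) > min(a$ci[2], b$ci[2])) {
        ok <- FALSE
      }
    }
    ok
  } else {
    NA
  }

  structure(list(
    tau_n_min = tau_n_min, tau_q_half = tau_q_half, tau_star = tau_star,
    tau_n_max = tau_n_max, tau_r = tau_r,
    ordering_ok = ordering_ok,
    series = list(nd = nd, q = qs, skew = sk, orient = oc),
    params = list(phi = traj$params$surface_fraction,
                  pa = traj$params$motor_probability,
                  n_filaments = traj$params$n_filaments,
                  seed = traj$seed)
  ), class = "mt_chronology")
}

#' @export
print.mt_chronology <- function(x, ...) {
  cat(sprintf("<mt_chronology> phi = %.3g, pa = %g, nf = %d, seed = %s\n",
              x$params$phi, x$params$pa, x$params$n_filaments,
              format(x$params$seed)))
  lbl <- c(tau_n_min = "sliding            tau_N,min",
           tau_q_half = "polarity inversion tau_Q/2 ",
           tau_star = "maximal activity   tau_*   ",
           tau_n_max = "collective motion  tau_N,max",
           tau_r = "active rotation    tau_r   ")
  for (k in names(lbl)) {
    e <- x[[k]]
    if (e$resolved) {
      cat(sprintf("  %s = %8.4g tauR  [%.3g, %.3g]\n", lbl[[k]], e$time,
                  e$ci[1], e$ci[2]))
    } else {
      cat(sprintf("  %s   unresolved (%s)\n", lbl[[k]], e$reason))
    }
  }
  if (!is.na(x$ordering_ok)) {
    cat(sprintf("  chronology ordering on resolved entries: %s\n",
                if (x$ordering_ok) "holds" else "VIOLATED"))
  }
  invisible(x)
}

#' FRAP-style labelling of a circular region
#'
#' Labels the beads inside a circle at the first frame and reports their
#' positions (and rasterised density images) at the initial frame and after
#' a given horizon, emulating photobleaching/photoconversion experiments.
#' In a polar-aligned region the labelled spot stays compact; across an
#' antialigned interface it is sheared into separating streams.
#'
#' @param traj an `mt_traj`.
#' @param center circle centre (wrapped coordinates); default box centre.
#' @param radius circle radius (default four filament lengths, capped below
#'   half the box).
#' @param horizon time horizon in `tauR` (default: last frame).
#' @param raster_bins number of raster bins per box edge.
#' @return list with `labels` (bead indices), `initial`/`final` (wrapped
#'   positions of labelled beads), `density_initial`/`density_final`
#'   (raster matrices), `rg_initial`/`rg_final` (radii of gyration about
#'   the unwrapped label centroid), `horizon`.
#' @export
frap_emulation <- function(traj, center = NULL, radius = NULL,
                           horizon = NULL, raster_bins = 64L) {
  Lb <- traj$params$box_edge
  L <- filament_length(traj$params)
  if (is.null(center)) center <- c(Lb / 2, Lb / 2)
  if (is.null(radius)) radius <- 4 * L
  if (radius >= Lb / 2) {
    stop("labelling circle does not fit in the box (radius >= Lb/2)",
         call. = FALSE)
  }
  frame_end <- if (is.null(horizon)) {
    length(traj$times)
  } else {
    which.min(abs(traj$times - (traj$times[1] + horizon)))
  }
  x0 <- matrix(traj$frames[1, , ], ncol = 2)
  x1 <- matrix(traj$frames[frame_end, , ], ncol = 2)
  w0 <- x0 - Lb * floor(x0 / Lb)
  dx <- min_image(w0[, 1] - center[1], Lb)
  dy <- min_image(w0[, 2] - center[2], Lb)
  labels <- which(dx^2 + dy^2 <= radius^2)
  if (!length(labels)) stop("no beads inside the labelling circle",
                            call. = FALSE)
  raster <- function(x) {
    w <- x - Lb * floor(x / Lb)
    bx <- pmin(pmax(ceiling(w[, 1] / Lb * raster_bins), 1), raster_bins)
    by <- pmin(pmax(ceiling(w[, 2] / Lb * raster_bins), 1), raster_bins)
    m <- matrix(0L, raster_bins, raster_bins)
    for (k in seq_along(bx)) m[bx[k], by[k]] <- m[bx[k], by[k]] + 1L
    m
  }
  rg <- function(x) {
    c <- colMeans(x)
    sqrt(mean((x[, 1] - c[1])^2 + (x[, 2] - c[2])^2))
  }
  a <- x0[labels, , drop = FALSE]
  b <- x1[labels, , drop = FALSE]
  list(labels = labels,
       initial = a - Lb * floor(a / Lb),
       final = b - Lb * floor(b / Lb),
       density_initial = raster(a), density_final = raster(b),
       rg_initial = rg(a), rg_final = rg(b),
       horizon = traj$times[frame_end] - traj$times[1])
}

#' Step-correlation colouring of filament trajectories
#'
#' Cosine of the angle between consecutive centre-of-mass displacement
#' vectors over a fixed window, per filament: values near +1 mark
#' persistent streaming, values near 0 diffusion, values near -1 reversals.
#' Zero-length steps are masked as `NA`.
#'
#' @param traj an `mt_traj`.
#' @param window step duration in `tauR`.
#' @return matrix `[step, filament]` of cosines in `[-1, 1]`.
#' @export
step_correlation_colouring <- function(traj, window) {
  com <- traj_com(traj)
  times <- traj$times
  grid <- seq(min(times), max(times), by = window)
  if (length(grid) < 3) stop("window too large for trajectory span",
                             call. = FALSE)
  idx <- vapply(grid, function(t) which.min(abs(times - t)), integer(1))
  idx <- unique(idx)
  steps <- lapply(seq_len(length(idx) - 1), function(k) {
    frame_slice(com, idx[k + 1]) - frame_slice(com, idx[k])
  })
  out <- matrix(NA_real_, length(steps) - 1, dim(com)[2])
  for (k in seq_len(length(steps) - 1)) {
    a <- steps[[k]]
    b <- steps[[k + 1]]
    na <- sqrt(rowSums(a^2))
    nb <- sqrt(rowSums(b^2))
    ok <- na > 0 & nb > 0
    out[k, ok] <- (rowSums(a * b) / (na * nb))[ok]
  }
  out
}

#' Fraction of motile filaments
#'
#' Fraction of (filament, time-origin) samples whose centre-of-mass
#' displacement within the window reaches the threshold.  The window and
#' threshold are explicit because the experimental motility criterion is a
#' choice; the defaults are one `tauR` and half a filament length.
#'
#' @param traj an `mt_traj`.
#' @param window observation window in `tauR`.
#' @param threshold displacement threshold in `sigma`.
#' @param max_origins cap on time origins.
#' @return fraction in `[0, 1]`.
#' @export
motile_fraction <- function(traj, window = 1,
                            threshold = filament_length(traj$params) / 2,
                            max_origins = 32L) {
  if (window > max(traj$times) - min(traj$times)) {
    stop("window exceeds trajectory span", call. = FALSE)
  }
  com <- traj_com(traj)
  pr <- lag_pairs(traj$times, window, max_origins = max_origins)
  if (!nrow(pr)) stop("window exceeds trajectory span", call. = FALSE)
  hits <- vapply(seq_len(nrow(pr)), function(k) {
    d <- frame_slice(com, pr[k, 2]) - frame_slice(com, pr[k, 1])
    mean(sqrt(d[, 1]^2 + d[, 2]^2) >= threshold)
  }, numeric(1))
  mean(hits)
}
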