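# Correlation functions and order parameters computed from trajectories:
# MSD, parallel-velocity distributions and their skew, spatio-temporal
# displacement correlations (Cd, Nd), motor-weighted local polar order and
# its relaxation (psi, Q), orientational correlation and tau_r, and the
# active diffusion coefficient.

# ---- correlation-series container ------------------------------------------

corr_series <- function(lag, value, stderr, kind, n = NA_integer_) {
  out <- data.frame(lag = lag, value = value, stderr = stderr, n = n)
  attr(out, "kind") <- kind
  class(out) <- c("mt_corr", "data.frame")
  out
}

#' @export
print.mt_corr <- function(x, ...) {
  cat(sprintf("<mt_corr> kind = %s, %d lags in [%.4g, %.4g] tauR\n",
              attr(x, "kind"), nrow(x), min(x$lag), max(x$lag)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.mt_corr <- function(x, ..., log = "x") {
  graphics::plot(x$lag, x$value, log = log, xlab = "lag (tauR)",
                 ylab = attr(x, "kind"), type = "b", ...)
  graphics::arrows(x$lag, x$value - x$stderr, x$lag, x$value + x$stderr,
                   length = 0.02, angle = 90, code = 3, col = "grey50")
  invisible(x)
}

# ---- multiple-time-origin machinery ----------------------------------------

# [frame, entity, xy] array slice at one frame as an n x 2 matrix (robust to
# dimension dropping when there is a single entity)
frame_slice <- function(a, i) matrix(a[i, , ], ncol = 2)

# frame-index pairs (i, j) with t_j - t_i ~ lag; origins subsampled evenly
# down to max_origins.  Returns a 2-column matrix (possibly empty).
lag_pairs <- function(times, lag, rtol = 0.05, max_origins = 64L) {
  if (lag == 0) {
    i <- seq_along(times)
    if (length(i) > max_origins) {
      i <- i[unique(round(seq(1, length(i), length.out = max_origins)))]
    }
    return(cbind(i, i))
  }
  tol <- rtol * lag
  target <- times + lag
  j_lo <- findInterval(target, times)
  j_hi <- pmin(j_lo + 1L, length(times))
  j_lo <- pmax(j_lo, 1L)
  err_lo <- abs(times[j_lo] - target)
  err_hi <- abs(times[j_hi] - target)
  j <- ifelse(err_hi < err_lo, j_hi, j_lo)
  err <- pmin(err_lo, err_hi)
  keep <- which(err <= tol & j > seq_along(times))
  if (!length(keep)) return(cbind(integer(0), integer(0)))
  if (length(keep) > max_origins) {
    keep <- keep[unique(round(seq(1, length(keep), length.out =
                                    max_origins)))]
  }
  cbind(keep, j[keep])
}

default_lags <- function(times, n = 25) {
  dt_min <- min(diff(sort(unique(times))))
  span <- (max(times) - min(times)) / 2
  if (span <= dt_min) stop("trajectory too short for lag analysis",
                           call. = FALSE)
  exp(seq(log(dt_min), log(span), length.out = n))
}

# block-averaged standard error over origins (rows of a sample matrix or a
# vector of per-origin values)
block_stderr <- function(per_origin, n_blocks = 8L) {
  m <- length(per_origin)
  if (m < 2) return(NA_real_)
  nb <- min(n_blocks, m)
  idx <- cut(seq_len(m), nb, labels = FALSE)
  bm <- tapply(per_origin, idx, mean)
  stats::sd(bm) / sqrt(nb)
}

# ---- MSD and parallel velocity ---------------------------------------------

#' Mean squared displacement of filament centres of mass
#'
#' Per-filament centre-of-mass squared displacement, averaged over filaments
#' and multiple time origins; standard errors from block averaging over
#' origins.  Lags exceeding the trajectory span are dropped with a warning.
#'
#' @param traj an `mt_traj`.
#' @param lags lag times in `tauR` (default: log-spaced over the available
#'   range).
#' @param max_origins cap on the number of time origins per lag.
#' @return an `mt_corr` with kind `"MSD"`.
#' @export
msd <- function(traj, lags = NULL, max_origins = 64L) {
  com <- traj_com(traj)
  times <- traj$times
  if (is.null(lags)) lags <- default_lags(times)
  res <- lapply(lags, function(lg) {
    pr <- lag_pairs(times, lg, max_origins = max_origins)
    if (!nrow(pr)) return(NULL)
    per_origin <- vapply(seq_len(nrow(pr)), function(k) {
      d <- frame_slice(com, pr[k, 2]) - frame_slice(com, pr[k, 1])
      mean(d[, 1]^2 + d[, 2]^2)
    }, numeric(1))
    c(lag = mean(times[pr[, 2]] - times[pr[, 1]]),
      value = mean(per_origin),
      stderr = block_stderr(per_origin),
      n = nrow(pr) * dim(com)[2])
  })
  dropped <- vapply(res, is.null, TRUE)
  if (any(dropped)) {
    warning(sum(dropped), " lag(s) outside the trajectory span were dropped")
  }
  res <- do.call(rbind, res[!dropped])
  if (is.null(res)) stop("no usable lags", call. = FALSE)
  corr_series(res[, "lag"], res[, "value"], res[, "stderr"], "MSD",
              res[, "n"])
}

#' Orientation-projected velocity samples
#'
#' One sample per (filament, time origin): the centre-of-mass displacement
#' over the lag projected on the filament's end-to-end orientation at the
#' origin time, divided by the lag.  Samples with an undefined orientation
#' are skipped (count in attribute `n_skipped`).
#'
#' @param traj an `mt_traj`.
#' @param lag lag time in `tauR`.
#' @param max_origins cap on the number of time origins.
#' @return numeric vector of `v_parallel` samples (sigma per tauR) with
#'   attributes `n_skipped` and `n_origins`.
#' @export
parallel_velocity_samples <- function(traj, lag, max_origins = 64L) {
  samples <- pv_samples_by_origin(traj, lag, max_origins)
  v <- unlist(samples)
  skipped <- sum(!is.finite(v))
  v <- v[is.finite(v)]
  structure(v, n_skipped = skipped, n_origins = length(samples))
}

# parallel-velocity samples grouped by time origin (one vector per origin)
pv_samples_by_origin <- function(traj, lag, max_origins = 64L) {
  com <- traj_com(traj)
  ors <- traj_orientations(traj)
  times <- traj$times
  pr <- lag_pairs(times, lag, max_origins = max_origins)
  if (!nrow(pr)) stop("lag exceeds trajectory span", call. = FALSE)
  lapply(seq_len(nrow(pr)), function(k) {
    tau <- times[pr[k, 2]] - times[pr[k, 1]]
    d <- frame_slice(com, pr[k, 2]) - frame_slice(com, pr[k, 1])
    p <- frame_slice(ors, pr[k, 1])
    (d[, 1] * p[, 1] + d[, 2] * p[, 2]) / tau
  })
}

#' Sample skewness
#'
#' Population standardised third central moment `m3 / m2^(3/2)`.
#'
#' @param x numeric sample (NAs removed).
#' @return the skewness; `NA` with attribute `error` when the variance is
#'   zero.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    return(structure(NA_real_, error = "zero variance"))
  }
  mean((x - m)^3) / m2^1.5
}

#' Skewness of the parallel-velocity distribution across lags
#'
#' @param traj an `mt_traj`.
#' @param lags lag times in `tauR`.
#' @param max_origins cap on time origins per lag.
#' @return an `mt_corr` with kind `"skew"`; standard errors come from block
#'   averaging over time origins (origins are correlated, so the
#'   independent-sample `sqrt(6/n)` formula would be optimistic).
#' @export
skew_series <- function(traj, lags = NULL, max_origins = 64L) {
  if (is.null(lags)) lags <- default_lags(traj$times)
  rows <- lapply(lags, function(lg) {
    by_origin <- tryCatch(pv_samples_by_origin(traj, lg, max_origins),
                          error = function(e) NULL)
    if (is.null(by_origin)) return(NULL)
    v <- unlist(by_origin)
    v <- v[is.finite(v)]
    if (length(v) < 100) return(NULL)
    nb <- min(8L, length(by_origin))
    blk <- cut(seq_along(by_origin), nb, labels = FALSE)
    bs <- vapply(seq_len(nb), function(b) {
      as.numeric(skewness(unlist(by_origin[blk == b])))
    }, numeric(1))
    bs <- bs[is.finite(bs)]
    se <- if (length(bs) > 1) stats::sd(bs) / sqrt(length(bs)) else
      sqrt(6 / length(v))
    c(lag = lg, value = as.numeric(skewness(v)), stderr = se,
      n = length(v))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) stop("no lag produced >= 100 velocity samples",
                          call. = FALSE)
  corr_series(rows[, "lag"], rows[, "value"], rows[, "stderr"], "skew",
              rows[, "n"])
}

# ---- displacement correlations ---------------------------------------------

#' Spatio-temporal displacement correlation Cd(r, tau)
#'
#' For centre-of-mass displacements `d_i` over lag `tau`,
#' `Cd(r, tau) = < sum_{i != j} d_i . d_j delta(r - r_ij) > /
#'  (c0 < sum_{i != j} delta(r - r_ij) >)` with `c0 = < sum_i d_i^2 / N >`;
#' pair distances are taken at the origin time under the minimum-image
#' convention and binned.  Empty bins are `NA` (undefined), not zero.
#'
#' @param traj an `mt_traj`.
#' @param lag lag time in `tauR`.
#' @param r_bins bin edges (default width `sigma/2` from 0 to `Lb/2`).
#' @param max_origins cap on time origins.
#' @param com optional precomputed [traj_com()] array.
#' @return an `mt_spatial_corr` data frame with `r` (bin centres), `value`,
#'   `npairs`; attributes `lag`, `c0`, and `per_origin` (per-origin,
#'   per-bin correlation values used for error estimates).
#' @export
displacement_correlation <- function(traj, lag, r_bins = NULL,
                                     max_origins = 64L, com = NULL) {
  Lb <- traj$params$box_edge
  sig <- traj$params$bead_diameter
  if (is.null(r_bins)) r_bins <- seq(0, Lb / 2, by = sig / 2)
  if (is.null(com)) com <- traj_com(traj)
  times <- traj$times
  pr <- lag_pairs(times, lag, max_origins = max_origins)
  if (!nrow(pr)) stop("lag exceeds trajectory span", call. = FALSE)
  nbin <- length(r_bins) - 1
  nor <- nrow(pr)
  dot_sum <- matrix(0, nor, nbin)
  cnt <- matrix(0, nor, nbin)
  c0_o <- numeric(nor)
  for (k in seq_len(nor)) {
    x0 <- frame_slice(com, pr[k, 1])
    d <- frame_slice(com, pr[k, 2]) - x0
    dx <- min_image(outer(x0[, 1], x0[, 1], "-"), Lb)
    dy <- min_image(outer(x0[, 2], x0[, 2], "-"), Lb)
    rij <- sqrt(dx^2 + dy^2)
    dot <- tcrossprod(d)
    ut <- upper.tri(rij)
    bin <- findInterval(rij[ut], r_bins, rightmost.closed = FALSE)
    ok <- bin >= 1 & bin <= nbin
    bs <- rowsum(cbind(dot[ut][ok], 1), bin[ok])
    idx <- as.integer(rownames(bs))
    dot_sum[k, idx] <- bs[, 1]
    cnt[k, idx] <- bs[, 2]
    c0_o[k] <- mean(d[, 1]^2 + d[, 2]^2)
  }
  c0 <- mean(c0_o)
  num <- colSums(dot_sum)
  den <- colSums(cnt)
  value <- ifelse(den > 0, num / (c0 * den), NA_real_)
  per_origin <- dot_sum / pmax(cnt, 1) / c0
  per_origin[cnt == 0] <- NA_real_
  out <- data.frame(r = (r_bins[-1] + r_bins[-length(r_bins)]) / 2,
                    value = value, npairs = den)
  attr(out, "lag") <- mean(times[pr[, 2]] - times[pr[, 1]])
  attr(out, "c0") <- c0
  attr(out, "per_origin") <- per_origin
  class(out) <- c("mt_spatial_corr", "data.frame")
  out
}

#' Neighbour displacement correlation Nd(tau)
#'
#' `Nd(tau) = Cd(sigma, tau)`: the displacement-displacement correlation in
#' the contact bin (the distance bin containing `r = sigma`), as a function
#' of lag.  Negative values at short lags signal antiparallel sliding of
#' neighbouring filaments; a positive lobe at intermediate lags signals
#' collective migration.
#'
#' @param traj an `mt_traj`.
#' @param lags lag times in `tauR`.
#' @param max_origins cap on time origins per lag.
#' @return an `mt_corr` with kind `"Nd"`.
#' @export
neighbour_correlation <- function(traj, lags = NULL, max_origins = 64L) {
  if (is.null(lags)) lags <- default_lags(traj$times)
  sig <- traj$params$bead_diameter
  com <- traj_com(traj)
  r_bins <- seq(0, traj$params$box_edge / 2, by = sig / 2)
  contact <- findInterval(sig, r_bins)
  rows <- lapply(lags, function(lg) {
    cd <- tryCatch(displacement_correlation(traj, lg, r_bins, max_origins,
                                            com),
                   error = function(e) NULL)
    if (is.null(cd)) return(NULL)
    po <- attr(cd, "per_origin")[, contact]
    po <- po[is.finite(po)]
    c(lag = attr(cd, "lag"), value = cd$value[contact],
      stderr = block_stderr(po), n = cd$npairs[contact])
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) stop("no usable lags", call. = FALSE)
  corr_series(rows[, "lag"], rows[, "value"], rows[, "stderr"], "Nd",
              rows[, "n"])
}

# ---- local polar order ------------------------------------------------------

# perfect-overlap normaliser: raw partition sum of two identical straight
# filaments (beads at spacing r0)
qij_normaliser <- function(params) {
  nb <- params$beads_per_filament
  r0 <- params$bond_rest_length
  km <- params$motor_stiffness
  deq <- params$motor_rest_length
  dtm <- params$motor_cutoff
  kBT <- params$temperature
  d <- abs(outer(seq_len(nb), seq_len(nb), "-")) * r0
  w <- exp(-0.5 * km * (d - deq)^2 / kBT)
  w[d > dtm] <- 0
  sum(w)
}

#' Pairwise motor partition function q_ij
#'
#' Boltzmann-weighted count of available motor binding sites between two
#' filaments: `sum over bead pairs of exp(-U_mot(m)/kBT)` for extensions
#' within the motor cutoff (zero weight beyond), normalised by the
#' perfect-overlap self-value so that two filaments with identical bead
#' coordinates give exactly 1 and far-apart filaments give 0.
#'
#' @param filament_a,filament_b filament indices.
#' @param state an `mt_state`.
#' @param params an `mt_params`.
#' @return scalar in `[0, 1]` (up to thermal distortion of the filaments).
#' @export
motor_partition <- function(filament_a, filament_b, state, params) {
  xu <- unwrap_positions(state)
  xa <- xu[state$filament == filament_a, , drop = FALSE]
  xb <- xu[state$filament == filament_b, , drop = FALSE]
  raw <- cpp_qij_raw(xa, xb, state$box_edge, params$motor_stiffness,
                     params$motor_rest_length, params$motor_cutoff,
                     params$temperature)
  raw / qij_normaliser(params)
}

classify_psi <- function(psi, qsum) {
  cls <- rep("mixed", length(psi))
  cls[!is.na(psi) & psi > 0.5] <- "polar"
  cls[!is.na(psi) & psi < -0.5] <- "antipolar"
  cls[qsum <= 0 | is.na(psi)] <- "isolated"
  factor(cls, levels = c("polar", "antipolar", "mixed", "isolated"))
}

#' Local polar order parameter psi
#'
#' Motor-weighted mean orientation overlap of a filament's neighbourhood:
#' `psi(i) = sum_{j != i} (p_i . p_j) q_ij / sum_{j != i} q_ij` with
#' filament-level end-to-end orientations and bead-pair-resolved partition
#' weights `q_ij`.  Environments are classified as polar (`psi > 0.5`),
#' antipolar (`psi < -0.5`), mixed (boundaries included), or isolated (no
#' neighbour within motor range).
#'
#' @param state an `mt_state`.
#' @param params an `mt_params`.
#' @return data frame with `psi`, `qsum`, and `class` per filament.
#' @export
local_polar_order <- function(state, params) {
  xu <- unwrap_positions(state)
  res <- cpp_local_polar_order(xu, state$filament, state$box_edge,
                               params$motor_stiffness,
                               params$motor_rest_length,
                               params$motor_cutoff, params$temperature,
                               params$beads_per_filament)
  data.frame(psi = res$psi, qsum = res$qsum,
             class = classify_psi(res$psi, res$qsum))
}

#' Per-frame local polar order of a trajectory
#'
#' @param traj an `mt_traj`.
#' @param frames frame indices (default all).
#' @return matrix `[frame, filament]` of psi values.
#' @export
psi_series <- function(traj, frames = seq_len(dim(traj$frames)[1])) {
  p <- traj$params
  out <- vapply(frames, function(fr) {
    res <- cpp_local_polar_order(traj$frames[fr, , ], traj$filament,
                                 p$box_edge, p$motor_stiffness,
                                 p$motor_rest_length, p$motor_cutoff,
                                 p$temperature, p$beads_per_filament)
    res$psi
  }, numeric(length(unique(traj$filament))))
  t(out)
}

#' Relaxation of local polar order Q(tau)
#'
#' Tracks the mean `psi` of the filaments that start (at each time origin)
#' in an antialigned (or polar) environment, and normalises its relaxation
#' towards the stationary value: `Q(tau) = (A(tau) - psi_inf) /
#' (A(0) - psi_inf)` where `A(tau)` is the subset-mean `psi` a lag `tau`
#' later and `psi_inf` is estimated from the final decade of lags.
#' `Q(0) = 1` and `Q -> 0` at long lags; the half-decay defines the
#' polarity-inversion time.
#'
#' @param traj an `mt_traj`.
#' @param subset `"antialigned"` (default) or `"polar"`: the environment
#'   class selected at the origin time.
#' @param lags lag times in `tauR` (0 is always included).
#' @param psi optional precomputed [psi_series()] matrix.
#' @param max_origins cap on time origins per lag.
#' @return an `mt_corr` with kind `"Q"`; attributes `psi0` and `psi_inf`.
#' @export
polar_order_deviation <- function(traj, subset = c("antialigned", "polar"),
                                  lags = NULL, psi = NULL,
                                  max_origins = 48L) {
  subset <- match.arg(subset)
  target <- if (subset == "antialigned") "antipolar" else "polar"
  if (is.null(psi)) psi <- psi_series(traj)
  times <- traj$times
  if (is.null(lags)) lags <- default_lags(times, n = 20)
  lags <- sort(unique(c(0, lags)))
  rows <- lapply(lags, function(lg) {
    pr <- lag_pairs(times, lg, max_origins = max_origins)
    if (!nrow(pr)) return(NULL)
    per_origin <- vapply(seq_len(nrow(pr)), function(k) {
      cls <- classify_psi(psi[pr[k, 1], ],
                          rep(1, ncol(psi))) # qsum handled via NA psi
      sel <- which(cls == target)
      if (!length(sel)) return(NA_real_)
      mean(psi[pr[k, 2], sel], na.rm = TRUE)
    }, numeric(1))
    per_origin <- per_origin[is.finite(per_origin)]
    if (!length(per_origin)) return(NULL)
    c(lag = if (lg == 0) 0 else mean(times[pr[, 2]] - times[pr[, 1]]),
      value = mean(per_origin), stderr = block_stderr(per_origin),
      n = length(per_origin))
  })
  keep <- !vapply(rows, is.null, TRUE)
  rows <- do.call(rbind, rows[keep])
  if (is.null(rows) || nrow(rows) < 4) {
    stop("too few usable lags for Q(tau)", call. = FALSE)
  }
  A <- rows[, "value"]
  lag_v <- rows[, "lag"]
  psi0 <- A[lag_v == 0][1]
  tail_sel <- lag_v >= max(lag_v) / 10 & lag_v > 0
  psi_inf <- mean(A[tail_sel])
  denom <- psi0 - psi_inf
  if (!is.finite(denom) || abs(denom) < 1e-8) {
    stop("degenerate Q(tau) normaliser: <psi_0> == <psi_inf>",
         call. = FALSE)
  }
  q <- (A - psi_inf) / denom
  se <- rows[, "stderr"] / abs(denom)
  out <- corr_series(lag_v, q, se, "Q", rows[, "n"])
  attr(out, "psi0") <- psi0
  attr(out, "psi_inf") <- psi_inf
  out
}

# ---- orientational correlation and active diffusion -------------------------

#' Orientational autocorrelation of filament axes
#'
#' `C(tau) = < p(t) . p(t + tau) >` over filaments and time origins, with
#' `p` the end-to-end unit vector.
#'
#' @param traj an `mt_traj`.
#' @param lags lag times in `tauR`.
#' @param max_origins cap on time origins per lag.
#' @return an `mt_corr` with kind `"orient"`.
#' @export
orientational_correlation <- function(traj, lags = NULL,
                                      max_origins = 64L) {
  ors <- traj_orientations(traj)
  times <- traj$times
  if (is.null(lags)) lags <- default_lags(times)
  rows <- lapply(lags, function(lg) {
    pr <- lag_pairs(times, lg, max_origins = max_origins)
    if (!nrow(pr)) return(NULL)
    per_origin <- vapply(seq_len(nrow(pr)), function(k) {
      a <- frame_slice(ors, pr[k, 1])
      b <- frame_slice(ors, pr[k, 2])
      mean(a[, 1] * b[, 1] + a[, 2] * b[, 2])
    }, numeric(1))
    c(lag = mean(times[pr[, 2]] - times[pr[, 1]]),
      value = mean(per_origin), stderr = block_stderr(per_origin),
      n = nrow(pr) * dim(ors)[2])
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) stop("no usable lags", call. = FALSE)
  corr_series(rows[, "lag"], rows[, "value"], rows[, "stderr"], "orient",
              rows[, "n"])
}

#' Fit the orientational decay time tau_r
#'
#' Exponential fit `C(tau) = exp(-tau / tau_r)` over the lags where the
#' correlation exceeds 0.05.  When the correlation never decays below
#' `exp(-1)` within the trajectory, a lower bound is flagged instead of a
#' value.
#'
#' @param series an `mt_corr` of kind `"orient"`.
#' @return list with `tau_r`, `ci` (95%), `fit`, `lower_bound` (NA or the
#'   largest lag when only a bound is available), and `resolved`.
#' @export
fit_tau_r <- function(series) {
  if (min(series$value) > exp(-1)) {
    return(list(tau_r = NA_real_, ci = c(NA_real_, NA_real_), fit = NULL,
                lower_bound = max(series$lag), resolved = FALSE))
  }
  use <- series$value > 0.05
  if (sum(use) < 3) stop("too few points above 0.05 for the tau_r fit",
                         call. = FALSE)
  fit <- lm(log(value) ~ lag, data = series[use, ])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("tau_r fit failed to converge", call. = FALSE)
  }
  ci_sl <- suppressWarnings(confint(fit)[2, ])
  list(tau_r = -1 / slope, ci = sort(-1 / ci_sl), fit = fit,
       lower_bound = NA_real_, resolved = TRUE)
}

#' Long-lag (active) diffusion coefficient
#'
#' Slope of the MSD versus lag over lags beyond `tau_r`, divided by 4
#' (two dimensions).  Requires an actual diffusive window: the log-log
#' slope over the selected lags must be near 1, otherwise an error flag is
#' returned.
#'
#' @param msd_series an `mt_corr` of kind `"MSD"`.
#' @param tau_r orientational decay time in `tauR`.
#' @return list with `DA`, `loglog_slope`, `ok`, `reason`.
#' @export
active_diffusion <- function(msd_series, tau_r) {
  sel <- msd_series$lag > tau_r
  if (sum(sel) < 3) {
    return(list(DA = NA_real_, loglog_slope = NA_real_, ok = FALSE,
                reason = "no diffusive window beyond tau_r"))
  }
  s <- msd_series[sel, ]
  ll <- unname(coef(lm(log(value) ~ log(lag), data = s))[2])
  if (ll < 0.5 || ll > 1.5) {
    return(list(DA = NA_real_, loglog_slope = ll, ok = FALSE,
                reason = "window is not diffusive (log-log slope far from 1)"))
  }
  slope <- unname(coef(lm(value ~ lag, data = s))[2])
  list(DA = slope / 4, loglog_slope = ll, ok = TRUE, reason = NULL)
}
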