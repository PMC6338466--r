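# Timescale extractors on constructed series, chronology assembly on
# scaled-down active runs, FRAP emulation, trajectory colouring, motile
# fraction.

test_that("extractors are exact on constructed series", {
  lags <- exp(seq(log(0.01), log(20), length.out = 30))

  # injected minimum at tau = 0.1
  v <- 0.05 - 0.3 * exp(-(log(lags) - log(0.1))^2 / 0.5)
  nd <- corr_series_for_test(lags, v, stderr = rep(0.005, 30), kind = "Nd")
  tmin <- extract_tau_n_min(nd)
  expect_true(tmin$resolved)
  expect_equal(tmin$time, 0.1, tolerance = 0.05)

  # injected maximum at tau = 10
  v2 <- -0.05 + 0.3 * exp(-(log(lags) - log(10))^2 / 0.5)
  nd2 <- corr_series_for_test(lags, v2, stderr = rep(0.005, 30),
                              kind = "Nd")
  tmax <- extract_tau_n_max(nd2)
  expect_true(tmax$resolved)
  expect_equal(tmax$time, 10, tolerance = 0.05)

  # all-positive series: no sliding minimum (passive behaviour)
  nd3 <- corr_series_for_test(lags, 0.05 + 0.02 * exp(-lags),
                              stderr = rep(0.002, 30), kind = "Nd")
  expect_false(extract_tau_n_min(nd3)$resolved)
  # flat noise: no significant maximum either
  nd4 <- corr_series_for_test(lags, rep(0.001, 30),
                              stderr = rep(0.01, 30), kind = "Nd")
  expect_false(extract_tau_n_max(nd4)$resolved)

  # skew peak at tau = 2
  sk <- corr_series_for_test(lags, 1.5 * exp(-(log(lags) - log(2))^2),
                             stderr = rep(0.01, 30), kind = "skew")
  tstar <- extract_tau_star(sk)
  expect_true(tstar$resolved)
  expect_equal(tstar$time, 2, tolerance = 0.05)
  # negative-only skew: unresolved
  skn <- corr_series_for_test(lags, -0.2 - 0.01 * lags,
                              stderr = rep(0.01, 30), kind = "skew")
  expect_false(extract_tau_star(skn)$resolved)
})

test_that("Q half-decay crossing is exact for exponential and grid cases", {
  lags <- exp(seq(log(0.01), log(10), length.out = 40))
  tau0 <- 0.7
  q <- corr_series_for_test(c(0, lags), c(1, exp(-lags / tau0)),
                            stderr = rep(0.001, 41), kind = "Q")
  tq <- extract_tau_q_half(q)
  expect_true(tq$resolved)
  expect_equal(tq$time, log(2) * tau0, tolerance = 0.02)

  # crossing exactly on a grid point
  lg <- c(0.1, 0.2, 0.4, 0.8)
  qv <- c(0.9, 0.7, 0.5, 0.2)
  tq2 <- extract_tau_q_half(corr_series_for_test(lg, qv, kind = "Q"))
  expect_equal(tq2$time, 0.4, tolerance = 1e-12)

  # never crossing: unresolved
  q3 <- corr_series_for_test(lg, c(0.95, 0.9, 0.85, 0.8), kind = "Q")
  expect_false(extract_tau_q_half(q3)$resolved)
})

test_that("chronology of a scaled-down active run is ordered and reproducible", {
  lags <- active_lags()
  runs <- list(small_active_run(1.0, 0.3, seed = 23),
               small_active_run(1.0, 0.3, seed = 24),
               small_active_run(1.0, 0.4, seed = 25))
  reports <- lapply(runs, function(tr) {
    assemble_chronology(tr, lags = lags)
  })
  for (rep_ in reports) {
    # sliding must be resolved in an active system at these densities
    expect_true(rep_$tau_n_min$resolved)
    # order of resolved early-time entries: tau_N_min <= tau_Q/2 (<= tau_*)
    if (!is.na(rep_$ordering_ok)) expect_true(rep_$ordering_ok)
  }
  # seed-to-seed agreement of the sliding time within joint grid CIs
  t1 <- reports[[1]]$tau_n_min
  t2 <- reports[[2]]$tau_n_min
  expect_lt(max(t1$ci[1], t2$ci[1]), min(t1$ci[2], t2$ci[2]))
})

test_that("polarity inversion is stationary: antialigned and polar starts agree", {
  act <- active_run()
  lags <- active_lags()
  psi <- psi_series(act)
  qa <- polar_order_deviation(act, "antialigned", lags, psi = psi)
  qp <- polar_order_deviation(act, "polar", lags, psi = psi)
  ta <- extract_tau_q_half(qa)
  tp <- extract_tau_q_half(qp)
  expect_true(ta$resolved && tp$resolved)
  # joint grid confidence intervals overlap (closed intervals)
  expect_lte(max(ta$ci[1], tp$ci[1]), min(ta$ci[2], tp$ci[2]))
})

test_that("passive systems leave active timescales unresolved", {
  traj <- passive_run()
  lags <- exp(seq(log(3e-3), log(0.45), length.out = 12))
  rep_ <- assemble_chronology(traj, lags = lags)
  expect_false(rep_$tau_n_min$resolved)   # Nd stays positive
  expect_false(rep_$tau_star$resolved)    # no positive skew peak
})

test_that("characteristic times decrease with motor activity", {
  lags <- active_lags()
  runs <- list(small_active_run(0.25, 0.3, seed = 21),
               small_active_run(0.5, 0.3, seed = 22),
               small_active_run(1.0, 0.3, seed = 23))
  nd_list <- lapply(runs, function(tr) neighbour_correlation(tr, lags))
  tmins <- vapply(nd_list, function(nd) extract_tau_n_min(nd)$time,
                  numeric(1))
  # resolved times decrease with pa (Spearman rho < 0 on resolved entries)
  res <- !is.na(tmins)
  expect_gt(sum(res), 1)
  expect_lt(cor(c(0.25, 0.5, 1.0)[res], tmins[res], method = "spearman"),
            0)
  # orientational memory at a fixed lag decays faster for higher pa
  oc <- vapply(runs, function(tr) {
    mean(orientational_correlation(tr, lags = c(0.4, 0.6))$value)
  }, numeric(1))
  expect_true(all(diff(oc) < 0))
})

test_that("FRAP emulation separates a hand-built antialigned toy", {
  # two interleaved blocks of filaments advected in opposite directions:
  # initially one connected blob, finally two well-separated blocks
  nf <- 20
  nb <- 5
  Lb <- 120
  nfr <- 11
  frames <- array(0, dim = c(nfr, nf * nb, 2))
  fil <- rep(seq_len(nf), each = nb)
  base_y <- 26 + 0.9 * (seq_len(nf) - 1) # rows 0.9 sigma apart
  for (f in seq_len(nf)) {
    dir <- if (f %% 2 == 0) 1 else -1    # alternate rows antialigned
    for (t in seq_len(nfr)) {
      shift <- dir * 2.5 * (t - 1)
      idx <- (f - 1) * nb + seq_len(nb)
      frames[t, idx, 1] <- 28 + seq(0, 2, by = 0.5) + shift
      frames[t, idx, 2] <- base_y[f]
    }
  }
  tr <- structure(list(
    frames = frames, steps = seq_len(nfr) - 1L,
    times = seq(0, 1, length.out = nfr),
    filament = fil, rank = rep(seq_len(nb), nf),
    params = make_params(list(nf = nf, nb = nb, Lb = Lb)),
    seed = 0), class = "mt_traj")
  res <- frap_emulation(tr, center = c(29, 34.5), radius = 10, horizon = 1)
  expect_equal(res$horizon, 1)
  expect_equal(length(res$labels), nf * nb)
  # labelled beads split into two separating clusters (single linkage at
  # 2 sigma): 1 cluster initially, 2 at the horizon
  count_clusters <- function(x) {
    hc <- hclust(dist(x), method = "single")
    max(cutree(hc, h = 2))
  }
  expect_equal(count_clusters(res$initial), 1)
  expect_equal(count_clusters(res$final), 2)

  # horizon 0: identical to the initial disk
  res0 <- frap_emulation(tr, center = c(29, 34.5), radius = 10, horizon = 0)
  expect_equal(res0$final, res0$initial)

  # circle larger than the box errors
  expect_error(frap_emulation(tr, radius = 70), "radius")
})

test_that("labelled region spreads more in active than passive systems", {
  pas <- passive_run()
  act <- active_run()
  horizon <- 0.5
  r <- 2 * filament_length(pas$params)
  f_p <- frap_emulation(pas, radius = r, horizon = horizon)
  f_a <- frap_emulation(act, radius = r, horizon = horizon)
  growth_p <- f_p$rg_final - f_p$rg_initial
  growth_a <- f_a$rg_final - f_a$rg_initial
  expect_gt(growth_a, growth_p)
})

test_that("step correlation colouring flags streaming vs reversal", {
  nfr <- 21
  times <- seq(0, 2, length.out = nfr)
  # filament 1: straight ballistic; filament 2: perfect zig-zag
  com <- array(0, dim = c(nfr, 2, 2))
  com[, 1, 1] <- seq(0, 10, length.out = nfr)
  com[, 2, 1] <- rep(c(0, 1), length.out = nfr)
  tr <- structure(list(
    frames = array(rep(com, each = 1), dim = c(nfr, 4, 2)),
    steps = seq_len(nfr), times = times,
    filament = c(1L, 1L, 2L, 2L), rank = c(1L, 2L, 1L, 2L),
    params = make_params(list(nf = 2, nb = 2, Lb = 100)),
    seed = 0), class = "mt_traj")
  # rebuild frames from the COM paths (two coincident beads per filament)
  for (f in 1:2) {
    for (k in 1:2) {
      tr$frames[, (f - 1) * 2 + 1, k] <- com[, f, k]
      tr$frames[, (f - 1) * 2 + 2, k] <- com[, f, k] + 0.25
    }
  }
  cc <- step_correlation_colouring(tr, window = 0.1)
  expect_true(all(abs(cc[, 1] - 1) < 1e-10))
  expect_true(all(abs(cc[, 2] + 1) < 1e-10))

  # isotropic random walk: mean near zero
  set.seed(17)
  nfr2 <- 400
  com2 <- array(0, dim = c(nfr2, 1, 2))
  com2[, 1, ] <- apply(matrix(rnorm(2 * nfr2), ncol = 2), 2, cumsum)
  tr2 <- structure(list(
    frames = array(0, dim = c(nfr2, 2, 2)), steps = seq_len(nfr2),
    times = seq(0, 4, length.out = nfr2),
    filament = c(1L, 1L), rank = c(1L, 2L),
    params = make_params(list(nf = 1, nb = 2, Lb = 1000)),
    seed = 0), class = "mt_traj")
  for (k in 1:2) {
    tr2$frames[, 1, k] <- com2[, 1, k]
    tr2$frames[, 2, k] <- com2[, 1, k] + 0.25
  }
  cc2 <- step_correlation_colouring(tr2, window = 0.01)
  expect_lt(abs(mean(cc2, na.rm = TRUE)), 3 / sqrt(sum(is.finite(cc2))))
})

test_that("motile fraction respects trivial thresholds", {
  traj <- passive_run()
  expect_equal(motile_fraction(traj, window = 0.5, threshold = 0), 1)
  expect_equal(motile_fraction(traj, window = 0.5, threshold = 1e6), 0)
  expect_error(motile_fraction(traj, window = 100), "window")

  # frozen trajectory: zero for any positive threshold
  frozen <- traj
  for (f in seq_len(dim(frozen$frames)[1])) {
    frozen$frames[f, , ] <- traj$frames[1, , ]
  }
  expect_equal(motile_fraction(frozen, window = 0.5, threshold = 0.01), 0)

  # activity increases the motile fraction
  act <- active_run()
  mf_a <- motile_fraction(act, window = 0.5,
                          threshold = filament_length(act$params) / 4)
  mf_p <- motile_fraction(traj, window = 0.5,
                          threshold = filament_length(traj$params) / 4)
  expect_gt(mf_a, mf_p)
})
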