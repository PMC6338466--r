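# Shared fixtures: simulation runs are expensive, so each named run is
# built lazily on first use and cached for the whole test session.
# Problem sizes are scaled down (tens of filaments, ~1 tauR of production)
# relative to production-scale studies; the methods vignette records the
# choices.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, builder(), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

steps_per_tau <- function(params) params$rotation_time / params$timestep

# passive bulk system: phi = 0.3, 50 filaments, 2 tauR of production
# (long enough to reach the terminal diffusive regime beyond the caging
# shoulder)
passive_run <- function() {
  cached("passive", function() {
    p <- make_params(list(nf = 50, phi = 0.3, pa = 0, seed = 5))
    spt <- steps_per_tau(p)
    run_simulation(p, list(
      equilibration_steps = round(0.2 * spt),
      production_steps = round(2.0 * spt),
      save_every = 256
    ), seed = 5, record_velocities = TRUE)
  })
}

# same system saved every step for the inertial (ballistic) window
fine_passive_run <- function() {
  cached("fine_passive", function() {
    p <- make_params(list(nf = 50, phi = 0.3, pa = 0, seed = 6))
    spt <- steps_per_tau(p)
    run_simulation(p, list(
      equilibration_steps = round(0.1 * spt),
      production_steps = 6000L,
      save_every = 4L
    ), seed = 6)
  })
}

# the main active system: phi = 0.3, pa = 1, 100 filaments; active warm-up
# long enough for the motor-count plateau, then 1.5 tauR of production
active_run <- function() {
  cached("active", function() {
    p <- make_params(list(nf = 100, phi = 0.3, pa = 1, seed = 11))
    spt <- steps_per_tau(p)
    np <- round(1.5 * spt)
    run_simulation(p, list(
      equilibration_steps = round(0.3 * spt),
      warmup_steps = round(2.5 * spt),
      production_steps = np,
      save_steps = save_schedule(np, mid_every = 128, mid_until = 26000,
                                 coarse_every = 1024)
    ), seed = 11)
  })
}

# dilute free beads for thermostat statistics and the Einstein relation;
# jittered grid placement keeps every pair well outside the WCA range
free_beads_run <- function() {
  cached("free_beads", function() {
    set.seed(12)
    nfree <- 300L
    p <- make_params(list(nf = nfree, nb = 1, Lb = 400, pa = 0))
    g <- expand.grid(x = seq(10, 390, by = 20), y = seq(10, 390, by = 20))
    g <- g[seq_len(nfree), ]
    x0 <- as.matrix(g) + matrix(runif(2 * nfree, -3, 3), ncol = 2)
    st <- new_state_for_test(x0, matrix(rnorm(2 * nfree), ncol = 2),
                             seq_len(nfree), 400)
    st <- langevin_step(st, p, seed = 13, n_steps = round(5 / p$timestep))
    run_simulation(p, list(production_steps = round(150 / p$timestep),
                           save_every = 1500L),
                   seed = 14, init_state = st, record_velocities = TRUE)
  })
}

new_state_for_test <- function(...) mtstream:::new_state(...)

# small active systems across pa / phi for trend and chronology checks
small_active_run <- function(pa, phi = 0.3, seed = 20, production = 1.2) {
  key <- sprintf("small_pa%s_phi%s_s%d_t%s", pa, phi, seed, production)
  cached(key, function() {
    p <- make_params(list(nf = 60, phi = phi, pa = pa, seed = seed))
    spt <- steps_per_tau(p)
    np <- round(production * spt)
    run_simulation(p, list(
      equilibration_steps = round(0.2 * spt),
      warmup_steps = round(0.3 * spt),
      production_steps = np,
      save_steps = save_schedule(np, mid_every = 256, mid_until = 40000,
                                 coarse_every = 1024)
    ), seed = seed)
  })
}

# dilute passive reference (nearly free filaments)
dilute_passive_run <- function() {
  cached("dilute_passive", function() {
    p <- make_params(list(nf = 8, phi = 0.02, pa = 0, seed = 7))
    spt <- steps_per_tau(p)
    run_simulation(p, list(
      equilibration_steps = round(0.1 * spt),
      production_steps = round(1.0 * spt),
      save_every = 512
    ), seed = 7)
  })
}

# default lag grid for the scaled-down active analyses
active_lags <- function() exp(seq(log(2e-3), log(0.7), length.out = 16))

# hand-made correlation series for extractor and fit oracles
corr_series_for_test <- function(lag, value,
                                 stderr = rep(1e-3 * max(abs(value)),
                                              length(lag)),
                                 kind = "MSD") {
  mtstream:::corr_series(lag, value, stderr, kind)
}

# numerical gradient of a potential-energy function of the flat coordinate
# vector, central differences
num_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# bent two-filament configuration used by the gradient checks
bent_state <- function(seed = 3, amplitude = 0.15) {
  set.seed(seed)
  p <- make_params(list(nf = 2, Lb = 40))
  st <- two_filament_fixture(1.05, 0, "antiparallel", p)
  xu <- unwrap_positions(st)
  xu <- xu + matrix(rnorm(length(xu), sd = amplitude / 3), ncol = 2)
  w <- wrap_positions(xu, st$box_edge)
  st$positions <- w$positions
  st$image_flags <- w$image_flags
  list(state = st, params = p)
}
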