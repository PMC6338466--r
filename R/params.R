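# Model parameters, reduced units, and configuration parsing.

# canonical field names and their defaults (reduced units: sigma = kBT = m =
# gamma = 1).  rotation_time is the bead-rod theory value for a 21-bead
# filament at spacing sigma/2; calibrate_tau_r() measures it from dynamics.
.param_defaults <- function() {
  tau_R <- 192.5
  list(
    n_filaments       = NULL,
    beads_per_filament = 21L,
    bead_diameter     = 1.0,
    bond_rest_length  = 0.5,
    bond_stiffness    = 2000,
    bend_modulus      = 200,
    wca_epsilon       = 1.0,
    wca_cutoff        = 2^(1 / 6),
    motor_stiffness   = 1.0,
    motor_rest_length = 1.0,
    motor_cutoff      = 2.0,
    motor_probability = 1.0,
    bead_mass         = 1.0,
    friction          = 1.0,
    temperature       = 1.0,
    timestep          = 5.31e-6 * tau_R,
    box_edge          = NULL,
    surface_fraction  = NULL,
    rotation_time     = tau_R,
    master_seed       = 1L
  )
}

.param_aliases <- c(
  nf = "n_filaments", nb = "beads_per_filament", sigma = "bead_diameter",
  r0 = "bond_rest_length", ks = "bond_stiffness", kappa = "bend_modulus",
  eps = "wca_epsilon", km = "motor_stiffness", deq = "motor_rest_length",
  dt_motor = "motor_cutoff", pa = "motor_probability", m = "bead_mass",
  gamma = "friction", kBT = "temperature", dt = "timestep", Lb = "box_edge",
  phi = "surface_fraction", tau_R = "rotation_time", seed = "master_seed"
)

#' Contour length of a filament
#'
#' The filament length is the contour spanned by the bead centres,
#' `L = (nb - 1) * r0`; with the default 21 overlapping beads at spacing
#' `sigma/2` this gives the aspect ratio `L/sigma = 10`.
#'
#' @param params an `mt_params` object (or any list with
#'   `beads_per_filament` and `bond_rest_length`).
#' @return filament length in units of `sigma`.
#' @export
filament_length <- function(params) {
  (params$beads_per_filament - 1) * params$bond_rest_length
}

#' Build a validated simulation parameter set
#'
#' Populates the full reduced-unit parameter set from a key-value
#' configuration, applying defaults for omitted entries.  Either the box
#' edge `Lb` or the surface fraction `phi` must be supplied (the other is
#' derived from the closed relation `phi = nf * L * sigma / Lb^2`); giving
#' both is allowed only when they are consistent.
#'
#' Canonical names (`n_filaments`, `surface_fraction`, ...) and the short
#' field-notation aliases (`nf`, `phi`, `pa`, `ks`, `kappa`, ...) are both
#' accepted; unknown keys are hard errors.
#'
#' @param config named list (or `mt_params`) of parameter values.
#' @return an object of class `mt_params`.
#' @examples
#' p <- make_params(list(nf = 1250, phi = 0.3))
#' p$box_edge # ~ 204.1 sigma
#' @export
make_params <- function(config = list()) {
  defaults <- .param_defaults()
  config <- as.list(config)
  keys <- names(config)
  if (length(config) && (is.null(keys) || any(!nzchar(keys)))) {
    stop("all configuration entries must be named", call. = FALSE)
  }
  canon <- ifelse(keys %in% names(.param_aliases),
                  .param_aliases[keys], keys)
  unknown <- setdiff(canon, names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(canon)) {
    stop("duplicate configuration key(s): ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  }
  names(config) <- canon
  p <- modifyList(defaults, config)

  if (is.null(p$n_filaments)) stop("n_filaments (nf) is required",
                                   call. = FALSE)
  p$n_filaments <- as.integer(p$n_filaments)
  p$beads_per_filament <- as.integer(p$beads_per_filament)
  p$master_seed <- as.integer(p$master_seed)

  for (k in c("bead_diameter", "bond_rest_length", "bond_stiffness",
              "bend_modulus", "wca_epsilon", "wca_cutoff", "motor_stiffness",
              "motor_rest_length", "motor_cutoff", "bead_mass", "friction",
              "timestep", "rotation_time")) {
    if (!is.numeric(p[[k]]) || p[[k]] <= 0) {
      stop(sprintf("parameter '%s' must be a positive number", k),
           call. = FALSE)
    }
  }
  if (p$temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (p$n_filaments < 1) stop("n_filaments must be >= 1", call. = FALSE)
  if (p$beads_per_filament < 1) {
    stop("beads_per_filament must be >= 1", call. = FALSE)
  }
  if (!is.numeric(p$motor_probability) || p$motor_probability < 0 ||
      p$motor_probability > 1) {
    stop("motor_probability (pa) must lie in [0, 1]", call. = FALSE)
  }

  L <- filament_length(p)
  area <- p$n_filaments * L * p$bead_diameter
  if (is.null(p$box_edge) && is.null(p$surface_fraction)) {
    stop("one of box_edge (Lb) or surface_fraction (phi) is required",
         call. = FALSE)
  }
  if (is.null(p$box_edge)) {
    if (p$surface_fraction <= 0) {
      stop("surface_fraction must be > 0", call. = FALSE)
    }
    p$box_edge <- sqrt(area / p$surface_fraction)
  } else if (is.null(p$surface_fraction)) {
    if (p$box_edge <= 0) stop("box_edge must be > 0", call. = FALSE)
    p$surface_fraction <- area / p$box_edge^2
  } else {
    implied <- area / p$box_edge^2
    if (abs(implied - p$surface_fraction) >
        1e-9 * max(abs(implied), abs(p$surface_fraction))) {
      stop(sprintf(
        "inconsistent box_edge/surface_fraction pair: Lb = %g implies phi = %g, got phi = %g",
        p$box_edge, implied, p$surface_fraction), call. = FALSE)
    }
    p$surface_fraction <- implied
  }

  structure(p, class = "mt_params")
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params> 2D filament-motor system (reduced units)\n")
  cat(sprintf("  filaments: %d x %d beads (L = %g sigma), box %.4g sigma, phi = %.4g\n",
              x$n_filaments, x$beads_per_filament, filament_length(x),
              x$box_edge, x$surface_fraction))
  cat(sprintf("  motors: pa = %g, km = %g, deq = %g, cutoff = %g\n",
              x$motor_probability, x$motor_stiffness, x$motor_rest_length,
              x$motor_cutoff))
  cat(sprintf("  ks = %g, kappa = %g, eps = %g; dt = %.4g (%.3g tauR), tauR = %g\n",
              x$bond_stiffness, x$bend_modulus, x$wca_epsilon, x$timestep,
              x$timestep / x$rotation_time, x$rotation_time))
  invisible(x)
}

#' Physical conversion table for the reduced parameter set
#'
#' The model is parameterised on biological microtubule/kinesin values; this
#' table gives the mapping between one internal unit and physical units:
#' `sigma` = 25 nm (MT diameter), `kBT` = 4.11 pN nm (room temperature),
#' and the remaining constants that follow from them.  It is metadata only;
#' all computation is done in reduced units.
#'
#' @return named list of physical values with attributes describing units.
#' @export
physical_units <- function() {
  list(
    sigma_nm            = 25,
    kBT_pN_nm           = 4.11,
    length_L_um         = 0.625,
    epsilon_pN_nm       = 4.11,
    kappa_pN_nm2        = 2.055e4,
    ks_pN_per_nm        = 13.15,
    km_pN_per_nm        = 6.6e-3,
    deq_nm              = 25,
    viscosity_Pa_s      = 1,
    motor_dwell_time_s  = 4.16e-4
  )
}

#' Read a flat key-value configuration file
#'
#' Parses a minimal TOML-like dialect: one `key = value` pair per line,
#' `#` comments, blank lines ignored.  Values are parsed as numbers,
#' `true`/`false`, or (optionally quoted) strings.  The result can be passed
#' to [make_params()]; unknown keys are rejected there.
#'
#' @param path path to the configuration file.
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (!grepl("=", line, fixed = TRUE)) {
      stop(sprintf("config parse error at line %d: expected 'key = value'", i),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!nzchar(key)) {
      stop(sprintf("config parse error at line %d: empty key", i),
           call. = FALSE)
    }
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) {
      out[[key]] <- num
    } else if (tolower(val) %in% c("true", "false")) {
      out[[key]] <- tolower(val) == "true"
    } else {
      out[[key]] <- val
    }
  }
  out
}
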