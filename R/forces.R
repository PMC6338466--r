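# Passive potentials (bond, angle, WCA) and the effective-motor interaction.
#
# Each *_energy_forces() function returns a "force-field contribution": a
# list with the per-bead force matrix and the term's total energy.  Forces
# are exact negative gradients of the energies (verified against finite
# differences in the test suite).

state_coords <- function(state) {
  list(x = unwrap_positions(state), fil = state$filament,
       Lb = state$box_edge)
}

#' Harmonic bond energy and forces
#'
#' `U = ks/2 * sum (r - r0)^2` over adjacent bead pairs of the same
#' filament.
#'
#' @param state an `mt_state`.
#' @param params an `mt_params`.
#' @return list with `forces` (n x 2) and `energy`.
#' @export
bond_energy_forces <- function(state, params) {
  s <- state_coords(state)
  cpp_bond_forces(s$x, s$fil, s$Lb, params$bond_stiffness,
                  params$bond_rest_length)
}

#' Bending energy and forces
#'
#' `U = (kappa / r0) * sum (1 - cos theta)` over interior bead triplets of
#' each filament, where `theta` is the angle between consecutive bond
#' vectors (zero for a straight filament).
#'
#' @inheritParams bond_energy_forces
#' @return list with `forces` (n x 2) and `energy`.
#' @export
angle_energy_forces <- function(state, params) {
  s <- state_coords(state)
  cpp_angle_forces(s$x, s$fil, s$Lb, params$bend_modulus,
                   params$bond_rest_length)
}

#' WCA excluded-volume energy and forces
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones:
#' `U = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps` for `r < 2^(1/6) sigma`,
#' zero beyond; continuous at the cutoff.  Applied to every bead pair except
#' directly bonded (adjacent same-filament) pairs.
#'
#' @inheritParams bond_energy_forces
#' @param neighbor_pairs optional two-column matrix of candidate bead pairs
#'   (1-based); defaults to all pairs within the WCA cutoff.
#' @return list with `forces` (n x 2) and `energy`.
#' @export
wca_energy_forces <- function(state, params, neighbor_pairs = NULL) {
  s <- state_coords(state)
  if (is.null(neighbor_pairs)) {
    neighbor_pairs <- cpp_neighbor_pairs(
      s$x, s$fil, s$Lb, params$wca_cutoff * params$bead_diameter, TRUE)
  }
  cpp_wca_forces(s$x, s$fil, neighbor_pairs, s$Lb, params$wca_epsilon,
                 params$bead_diameter)
}

#' Antialignment eligibility of a candidate motor bond
#'
#' A motor can only bind a bead pair whose local filament orientations are
#' antialigned with respect to the connecting vector: with
#' `m_ij = r_i - r_j` (minimum image) the printed condition is
#' `p_i . m_ij > 0` and `p_j . m_ij < 0` (both strict).  Exactly parallel
#' orientations can never satisfy both inequalities.
#'
#' @param p_i,p_j unit orientation vectors of the two beads.
#' @param m_ij connecting vector `r_i - r_j` (minimum image).
#' @return logical.
#' @export
motor_eligible <- function(p_i, p_j, m_ij) {
  sum(p_i * m_ij) > 0 && sum(p_j * m_ij) < 0
}

#' Motor binding rate
#'
#' `k_on(m) = pa * exp(-U_mot(m) / kBT)` for extensions `m < d_t` (the motor
#' cutoff, two bead diameters), zero at and beyond the cutoff, with
#' `U_mot = km/2 (m - deq)^2`.  Just below the cutoff the rate ratio
#' `k_on / pa` approaches `exp(-1/2)` for the default stiffness.
#'
#' @param m_ij scalar motor extension(s), >= 0.
#' @param params an `mt_params`.
#' @return binding probability per candidate pair per timestep.
#' @export
motor_binding_rate <- function(m_ij, params) {
  u <- 0.5 * params$motor_stiffness *
    (m_ij - params$motor_rest_length)^2 / max(params$temperature, 1e-300)
  ifelse(m_ij < params$motor_cutoff,
         params$motor_probability * exp(-u), 0)
}

#' Sample the transient motor bonds of one timestep
#'
#' For each inter-filament bead pair within the motor cutoff that satisfies
#' the antialignment condition, an independent Bernoulli draw with
#' probability [motor_binding_rate()] decides whether a motor binds for this
#' step.  At most one motor forms per bead pair per step; a bead may be
#' bound to several partners.  The binding geometry is oriented so that the
#' (almost always extended) motor springs propel each filament toward its
#' plus end, matching the skew of parallel-velocity distributions towards
#' positive values.
#'
#' @inheritParams bond_energy_forces
#' @param seed integer seed for the Bernoulli draws.
#' @return a `MotorBondSet`: list with `pairs` (k x 2 bead indices,
#'   1-based), `extensions`, `bond_vectors` (`m_ij = r_i - r_j`), `energy`.
#' @export
sample_motor_bonds <- function(state, params, seed = params$master_seed) {
  s <- state_coords(state)
  cpp_sample_motor_bonds(
    s$x, s$fil, s$Lb, params$motor_stiffness, params$motor_rest_length,
    params$motor_cutoff, params$motor_probability, params$temperature,
    as.double(seed))
}

#' Forces exerted by a set of motor bonds
#'
#' Each motor is a harmonic spring of rest length `deq` and stiffness `km`:
#' force magnitude `km * (m - deq)` along the bond, contracting when
#' extended, expanding when compressed, equal and opposite on the two beads.
#'
#' @inheritParams bond_energy_forces
#' @param bonds a `MotorBondSet` from [sample_motor_bonds()].
#' @return list with `forces` (n x 2) and `energy`.
#' @export
motor_forces <- function(bonds, state, params) {
  s <- state_coords(state)
  cpp_motor_forces(s$x, bonds$pairs, s$Lb, params$motor_stiffness,
                   params$motor_rest_length)
}

#' Total deterministic force field with per-term energy ledger
#'
#' Sums bond, angle, WCA, and (if `bonds` given) motor contributions.
#' Thermal and drag forces are not included; the internal forces sum to zero
#' over the whole system.
#'
#' @inheritParams bond_energy_forces
#' @param bonds optional `MotorBondSet`.
#' @return list with `forces` (n x 2) and `ledger` (named energies).
#' @export
force_field <- function(state, params, bonds = NULL) {
  b <- bond_energy_forces(state, params)
  a <- angle_energy_forces(state, params)
  w <- wca_energy_forces(state, params)
  F <- b$forces + a$forces + w$forces
  ledger <- c(bond = b$energy, angle = a$energy, wca = w$energy, motor = 0)
  if (!is.null(bonds) && nrow(bonds$pairs)) {
    m <- motor_forces(bonds, state, params)
    F <- F + m$forces
    ledger["motor"] <- m$energy
  }
  list(forces = F, ledger = ledger)
}
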