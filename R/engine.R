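# The hPF-MD integrator.  Nonbonded interactions act through smoothed
# per-species density fields: particles are assigned to a cubic mesh by
# cloud-in-cell (CIC) weights, the density functional
#   W = sum_cells v/phi0 [ 1/2 sum_ij chi_ij phi_i phi_j
#                          + kappa_inv/2 (sum_i phi_i - phi0)^2 ]
# yields per-species external potentials V_i = dW/dphi_i, and the force
# on each particle is the exact negative gradient of the discretized W
# (derivative of the CIC weights contracted with V).  Bonded forces are
# harmonic; electrostatics, when enabled, solves the Poisson equation
# spectrally on the same mesh.  Integration is velocity-Verlet in the
# NVT ensemble with an Andersen thermostat; the fields are held frozen
# between updates (quasi-instantaneous field approximation).

#' Simulation configuration
#'
#' @param n_steps number of integration steps.
#' @param dt time step, ps (default 0.03, i.e. 30 fs).
#' @param temperature thermostat target, K.
#' @param collision_frequency Andersen collision frequency, 1/ps; each
#'   step every particle's velocity is redrawn from the
#'   Maxwell-Boltzmann distribution with probability
#'   `collision_frequency * dt`.
#' @param field_update_interval steps between density-field updates.
#' @param mesh_cells mesh cells per box edge; default targets a cell
#'   edge of about 0.4 nm, the coarse-grained bead diameter scale.
#' @param seed integer RNG seed.
#' @param electrostatics_on solve mesh electrostatics (requires tail
#'   charges in the force field)?
#' @param thermostat logical; disable for microcanonical checks.
#' @param frame_stride steps between emitted frames (must be a multiple
#'   of `field_update_interval`); default about 100 frames per run.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_steps, dt = 0.03, temperature = 300,
                       collision_frequency = 7,
                       field_update_interval = 20, mesh_cells = NULL,
                       seed = 1, electrostatics_on = FALSE,
                       thermostat = TRUE, frame_stride = NULL) {
  stopifnot(dt > 0, n_steps >= 1)
  if (collision_frequency * dt > 1)
    stop("collision probability nu*dt exceeds 1")
  if (!is.null(mesh_cells) && mesh_cells < 4)
    stop("mesh_cells must be >= 4")
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 temperature = temperature,
                 collision_frequency = collision_frequency,
                 field_update_interval = as.integer(field_update_interval),
                 mesh_cells = mesh_cells, seed = as.integer(seed),
                 electrostatics_on = electrostatics_on,
                 thermostat = thermostat, frame_stride = frame_stride),
            class = "sim_config")
}

# Default mesh: cell edge of about 0.4 nm, the CG bead diameter scale.
# Coarser cells fail to couple the compressibility penalty at the bead
# scale (distinct molecules can then superimpose completely, wiping
# out the short-range correlation hole); much finer cells hold well
# under one particle each, so the density fields degenerate into shot
# noise and the mean-field driving forces wash out.
default_mesh <- function(box_edge) max(4L, as.integer(round(box_edge / 0.4)))

#' Assign particles to per-species density meshes
#'
#' Cloud-in-cell (trilinear) assignment: each particle spreads linearly
#' over the eight mesh cells whose centers surround it, conserving the
#' per-species particle count exactly.
#'
#' @param state a [system_state()].
#' @param mesh_cells cells per box edge.
#' @param species_levels mesh species order; defaults to the sorted
#'   labels present in `state`.
#' @return an object of class `density_field` with number-density
#'   meshes `phi` (nm^-3, dims `c(m, m, m, n_species)`), the reference
#'   total density `phi0`, and an empty potential slot `V`.
#' @export
assign_density <- function(state, mesh_cells = default_mesh(state$box_edge),
                           species_levels = sort(unique(state$species))) {
  L <- state$box_edge
  idx <- match(state$species, species_levels)
  if (anyNA(idx)) stop("state contains species absent from species_levels")
  phi <- cic_assign_cpp(state$positions, idx, length(species_levels), L,
                        as.integer(mesh_cells))
  structure(list(n_cells = as.integer(mesh_cells), cell_edge = L / mesh_cells,
                 box_edge = L, species = species_levels, phi = phi,
                 phi0 = nrow(state$positions) / L^3, V = NULL),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("density_field:", x$n_cells, "^3 cells of", signif(x$cell_edge, 3),
      "nm, species", paste(x$species, collapse = " "),
      ", phi0 =", signif(x$phi0, 4), "nm^-3,",
      if (is.null(x$V)) "potentials not set\n" else "potentials set\n")
  invisible(x)
}

chi_submatrix <- function(chi, species) {
  if (!all(species %in% chi$species))
    stop("species mismatch between density field and interaction matrix")
  chi$values[species, species, drop = FALSE]
}

#' Populate the external potential meshes
#'
#' Per species i and mesh cell,
#' \deqn{V_i = \frac{1}{\phi_0}\Big[\sum_j \tilde\chi_{ij}\phi_j
#'   + \kappa^{-1}\big(\sum_j \phi_j - \phi_0\big)\Big]}
#' in kJ/mol.  In the homogeneous reference state of a single
#' non-interacting species the potential vanishes.
#'
#' @param field a `density_field`.
#' @param chi a [chi_matrix()] covering the field's species.
#' @return the field with `V` populated (same dims as `phi`).
#' @export
field_potential <- function(field, chi) {
  X <- chi_submatrix(chi, field$species)
  m3 <- field$n_cells^3
  S <- length(field$species)
  phi_mat <- matrix(field$phi, m3, S)
  phitot <- rowSums(phi_mat)
  V <- (phi_mat %*% X + chi$kappa_inv * (phitot - field$phi0)) / field$phi0
  field$V <- array(V, dim = c(field$n_cells, field$n_cells, field$n_cells, S))
  field$kappa_inv <- chi$kappa_inv
  field
}

#' Total field interaction energy
#'
#' The discretized density functional summed over mesh cells (kJ/mol).
#' Zero for the homogeneous single-species reference state and in the
#' ideal-gas limit (all \eqn{\tilde\chi = 0}, \eqn{\kappa^{-1} = 0}).
#'
#' @param field a `density_field`.
#' @param chi a [chi_matrix()].
#' @return energy in kJ/mol.
#' @export
interaction_energy <- function(field, chi) {
  X <- chi_submatrix(chi, field$species)
  m3 <- field$n_cells^3
  S <- length(field$species)
  phi_mat <- matrix(field$phi, m3, S)
  phitot <- rowSums(phi_mat)
  v <- field$cell_edge^3
  (v / field$phi0) * (0.5 * sum(phi_mat * (phi_mat %*% X)) +
                        0.5 * chi$kappa_inv * sum((phitot - field$phi0)^2))
}

#' Field forces on particles
#'
#' The exact negative gradient of the discretized interaction energy
#' with respect to particle positions: the derivative of each
#' particle's CIC weights contracted with its species' potential mesh.
#' Equivalently, a two-point difference of `V` between the adjacent
#' mesh planes bracketing the particle, weighted by the transverse CIC
#' weights.
#'
#' @param state a [system_state()].
#' @param field a `density_field` with `V` populated (see
#'   [field_potential()]).
#' @return N x 3 force matrix, kJ/mol/nm.
#' @export
field_forces <- function(state, field) {
  if (is.null(field$V)) stop("field potentials not populated")
  idx <- match(state$species, field$species)
  if (anyNA(idx)) stop("state contains species absent from the field")
  cic_field_forces_cpp(state$positions, idx, field$V, state$box_edge)
}

# Global bond table (1-based particle indices) for a state under a
# force field; molecules are contiguous index blocks.
system_bonds <- function(state, ff) {
  bonds <- list(); kb <- list(); r0 <- list()
  start <- which(!duplicated(state$molecule_id))
  for (si in seq_along(start)) {
    tp <- ff$topologies[[state$molecule_name[start[si]]]]
    if (is.null(tp))
      stop("no topology named '", state$molecule_name[start[si]],
           "' in force field")
    if (nrow(tp$bonds) > 0) {
      bonds[[length(bonds) + 1L]] <- tp$bonds + start[si] - 1L
      kb[[length(kb) + 1L]] <- tp$kb
      r0[[length(r0) + 1L]] <- tp$r0
    }
  }
  if (length(bonds) == 0)
    list(bonds = matrix(integer(0), 0, 2), kb = numeric(0), r0 = numeric(0))
  else
    list(bonds = do.call(rbind, bonds), kb = unlist(kb), r0 = unlist(r0))
}

system_charges <- function(state, ff) {
  q <- numeric(nrow(state$positions))
  start <- which(!duplicated(state$molecule_id))
  for (si in seq_along(start)) {
    tp <- ff$topologies[[state$molecule_name[start[si]]]]
    q[start[si] + seq_along(tp$charges) - 1L] <- tp$charges
  }
  q
}

#' Bonded forces and energy
#'
#' Harmonic bonds \eqn{E = \tfrac12 k_b (r - r_0)^2} under the minimum
#' image convention.  A bond longer than half the box edge is rejected
#' (minimum image ambiguous).
#'
#' @param state a [system_state()].
#' @param ff an `hpf_forcefield`.
#' @return list with `forces` (N x 3, kJ/mol/nm) and `energy` (kJ/mol).
#' @export
bonded_forces <- function(state, ff) {
  b <- system_bonds(state, ff)
  bonded_forces_cpp(state$positions, b$bonds, b$kb, b$r0, state$box_edge)
}

# Spectral Poisson solve on the mesh: charges spread by CIC, potential
# from the continuum Green's function (zero-mean), field by ik
# differentiation.  Returns E meshes, dims c(m, m, m, 3), in units such
# that q*E is a force in kJ/mol/nm.
poisson_efield <- function(positions, charges, box_edge, mesh_cells,
                           epsilon_r) {
  m <- as.integer(mesh_cells)
  L <- box_edge
  # charge density from the same CIC kernel as the number densities:
  # spread unit weights per distinct charge value and scale (the
  # default model has only three values, 0 and +-0.4).
  rho <- array(0, dim = c(m, m, m))
  for (qv in setdiff(unique(charges), 0)) {
    s2 <- charges == qv
    d <- cic_assign_cpp(positions[s2, , drop = FALSE],
                        rep(1L, sum(s2)), 1L, L, m)
    rho <- rho + qv * array(d, dim = c(m, m, m))
  }
  freq <- c(0:(ceiling(m / 2) - 1), -(floor(m / 2):1))
  kx <- 2 * pi * freq / L
  kd <- kx
  if (m %% 2 == 0) kd[m / 2 + 1] <- 0  # no derivative at the Nyquist mode
  k2 <- outer(outer(kx^2, kx^2, `+`), kx^2, `+`)
  rhohat <- fft(rho)
  psihat <- rhohat * (4 * pi * COULOMB_CONST / epsilon_r) /
    ifelse(k2 == 0, Inf, k2)
  E <- array(0, dim = c(m, m, m, 3))
  karr <- list(array(rep(kd, times = m * m), dim = c(m, m, m)),
               array(rep(rep(kd, each = m), times = m), dim = c(m, m, m)),
               array(rep(kd, each = m * m), dim = c(m, m, m)))
  for (d in 1:3)
    E[, , , d] <- Re(fft(-1i * karr[[d]] * psihat, inverse = TRUE)) / m^3
  E
}

#' Mesh electrostatic forces
#'
#' Partial charges are spread to the mesh with the same CIC kernel as
#' the densities; the Poisson equation is solved in reciprocal space
#' (periodic, zero-mean potential) with relative dielectric constant
#' `ff$epsilon_r`; the field is interpolated back to the particles.
#' The system must be net-neutral.
#'
#' @param state a [system_state()].
#' @param ff an `hpf_forcefield` with tail charges.
#' @param mesh_cells cells per box edge.
#' @return N x 3 force matrix, kJ/mol/nm.
#' @export
electrostatic_forces <- function(state, ff,
                                 mesh_cells = default_mesh(state$box_edge)) {
  q <- system_charges(state, ff)
  if (abs(sum(q)) > 1e-9)
    stop("system has net charge ", sum(q), ": mesh electrostatics ",
         "requires a neutral system")
  if (all(q == 0)) return(matrix(0, nrow(state$positions), 3))
  E <- poisson_efield(state$positions, q, state$box_edge, mesh_cells,
                      ff$epsilon_r)
  cic_interp_vec_cpp(state$positions, E, state$box_edge) * q
}

#' Run an hPF-MD simulation
#'
#' Velocity-Verlet integration in the NVT ensemble.  The density field
#' and potentials (and, when enabled, the electrostatic field) are
#' recomputed every `field_update_interval` steps and frozen in
#' between; the Andersen thermostat redraws each particle's velocity
#' from the Maxwell-Boltzmann distribution with probability
#' `collision_frequency * dt` per step.  Fully reproducible from
#' `cfg$seed`.
#'
#' @param state initial [system_state()].
#' @param ff an `hpf_forcefield`.
#' @param cfg a [sim_config()].
#' @return an [hpf_trajectory()] whose frames hold unwrapped
#'   coordinates; `$log` is a data frame with columns `step`, `time`,
#'   `kinetic_T`, `field_W`, `bonded_E`.
#' @export
run_hpf <- function(state, ff, cfg) {
  L <- state$box_edge
  m <- if (is.null(cfg$mesh_cells)) default_mesh(L) else
    as.integer(cfg$mesh_cells)
  fui <- cfg$field_update_interval
  if (cfg$n_steps %% fui != 0)
    stop("n_steps must be a multiple of field_update_interval")
  stride <- if (is.null(cfg$frame_stride))
    max(fui, fui * max(1L, (cfg$n_steps %/% fui) %/% 100L)) else
      as.integer(cfg$frame_stride)
  if (stride %% fui != 0)
    stop("frame_stride must be a multiple of field_update_interval")
  set.seed(cfg$seed)

  sp_levels <- ff$chi$species
  idx <- match(state$species, sp_levels)
  if (anyNA(idx)) stop("state species not covered by the force field")
  masses <- ff_masses(ff)[state$species]
  q <- system_charges(state, ff)
  if (!cfg$electrostatics_on) q[] <- 0
  if (cfg$electrostatics_on && abs(sum(q)) > 1e-9)
    stop("net charge must be zero for mesh electrostatics")
  b <- system_bonds(state, ff)
  n <- nrow(state$positions)
  phi0 <- n / L^3
  p_coll <- min(1, cfg$collision_frequency * cfg$dt)
  kBT <- kB * cfg$temperature

  pos <- state$positions  # unwrapped from here on
  vel <- state$velocities
  frames <- list(pos)
  times <- state$time
  log_rows <- list()
  n_seg <- cfg$n_steps %/% fui
  use_elec <- cfg$electrostatics_on && any(q != 0)

  for (seg in seq_len(n_seg)) {
    posw <- wrap_positions(pos, L)
    phi <- cic_assign_cpp(posw, idx, length(sp_levels), L, m)
    fld <- structure(list(n_cells = m, cell_edge = L / m, box_edge = L,
                          species = sp_levels, phi = phi, phi0 = phi0,
                          V = NULL),
                     class = "density_field")
    fld <- field_potential(fld, ff$chi)
    E <- if (use_elec)
      poisson_efield(posw, q, L, m, ff$epsilon_r) else NULL
    res <- integrate_segment_cpp(pos, vel, masses, q, idx, fld$V, E,
                                 b$bonds, b$kb, b$r0, L, fui, cfg$dt,
                                 p_coll, kBT, cfg$thermostat)
    pos <- res$positions
    vel <- res$velocities
    step <- seg * fui
    if (!all(is.finite(pos)) || !all(is.finite(vel))) {
      dump <- tempfile("hpfmd-diagnostic-", fileext = ".csv")
      write.csv(data.frame(frames[[length(frames)]]), dump,
                row.names = FALSE)
      stop("non-finite coordinates at step ", step,
           "; last good frame dumped to ", dump)
    }
    if (step %% stride == 0) {
      frames[[length(frames) + 1L]] <- pos
      times <- c(times, state$time + step * cfg$dt)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, time = state$time + step * cfg$dt,
        kinetic_T = 2 * res$kinetic_energy / (3 * n * kB),
        field_W = interaction_energy(fld, ff$chi),
        bonded_E = res$bonded_energy)
    }
  }
  hpf_trajectory(L, state$species, state$molecule_id, state$molecule_name,
                 times, frames, velocities = vel,
                 log = do.call(rbind, log_rows),
                 config = unclass(cfg))
}
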