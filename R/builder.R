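# System construction: composition arithmetic reproducing the simulated
# setups, random sequential placement, Maxwell-Boltzmann velocities, and
# synthetic fixtures (planted clusters, Brownian walkers) that carry
# their own ground truth so every analysis stage is testable without
# running the engine.

#' System specification
#'
#' @param concentration surfactant concentration, mM.
#' @param box_edge cubic box edge, nm.
#' @param solvent `"W"` or `"C"`.
#' @param seed integer RNG seed.
#' @param temperature K.
#' @return an object of class `system_spec`.
#' @export
system_spec <- function(concentration, box_edge, solvent = "W", seed = 1,
                        temperature = 300) {
  stopifnot(concentration >= 0, box_edge > 0)
  structure(list(concentration = concentration, box_edge = box_edge,
                 solvent = solvent, seed = as.integer(seed),
                 temperature = temperature),
            class = "system_spec")
}

#' One-frame particle configuration
#'
#' Positions are wrapped into the half-open periodic box `[0, L)`
#' (corner-origin, GRO convention).  Particles sharing a `molecule_id`
#' form one contiguous topology instance.
#'
#' @param box_edge nm.
#' @param positions N x 3 matrix, nm.
#' @param velocities N x 3 matrix, nm/ps.
#' @param species per-particle species label.
#' @param molecule_id per-particle integer molecule id.
#' @param molecule_name per-particle topology name.
#' @param time frame time, ps.
#' @return an object of class `system_state`.
#' @export
system_state <- function(box_edge, positions, velocities, species,
                         molecule_id, molecule_name, time = 0) {
  positions <- wrap_positions(as.matrix(positions), box_edge)
  structure(list(box_edge = box_edge, positions = positions,
                 velocities = as.matrix(velocities), species = species,
                 molecule_id = as.integer(molecule_id),
                 molecule_name = molecule_name, time = time),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state:", nrow(x$positions), "beads,",
      length(unique(x$molecule_id)), "molecules, box", x$box_edge,
      "nm, t =", x$time, "ps\n")
  invisible(x)
}

wrap_positions <- function(x, L) {
  y <- x - L * floor(x / L)
  y[y >= L] <- 0
  y
}

#' Surfactant molecule count for a target concentration
#'
#' Nearest integer to \eqn{c N_A V} with `c` in mol/L and the box
#' volume converted to liters.  Reproduces the published simulation
#' compositions, e.g. 330 molecules at 200 mM in a 14 nm box and 661 at
#' 50 mM in a 28 nm box.
#'
#' @param concentration mM.
#' @param box_edge nm.
#' @return integer molecule count.
#' @examples
#' molecule_count(200, 14)  # 330
#' @export
molecule_count <- function(concentration, box_edge) {
  stopifnot(concentration >= 0, box_edge >= 0)
  as.integer(round(concentration * 1e-3 * N_AVOGADRO * box_edge^3 * 1e-24))
}

# Bulk fill densities (molecules/nm^3) and the volume displaced per
# surfactant molecule.  rho_W from liquid water at 0.997 g/mL; rho_C
# from liquid cyclohexane at 0.779 g/mL; v_adoh back-computed so the
# published compositions are matched within 1%.
SOLVENT_DENSITY <- c(W = 33.33, C = 5.574)
SOLVENT_MAPPING <- c(W = 4, C = 1)
V_ADOH <- 0.89

#' Solvent bead count filling the box around the solute
#'
#' Number of solvent beads occupying the volume left by `n_solute`
#' surfactant molecules: `round((box_edge^3 - n_solute * v_solute) *
#' rho / m)` with mapping `m` = 4 for water (one bead per four
#' molecules) and 1 for cyclohexane.
#'
#' @param box_edge nm.
#' @param n_solute surfactant molecule count.
#' @param solvent `"W"` or `"C"`.
#' @param v_solute displaced volume per surfactant molecule, nm^3.
#' @return integer solvent bead count.
#' @examples
#' solvent_count(28, 661, "W")  # ~178,000
#' @export
solvent_count <- function(box_edge, n_solute, solvent, v_solute = V_ADOH) {
  stopifnot(n_solute >= 0)
  if (!solvent %in% names(SOLVENT_DENSITY))
    stop("unknown solvent label '", solvent, "'")
  avail <- box_edge^3 - n_solute * v_solute
  if (avail < 0)
    stop("negative available volume: ", n_solute,
         " solute molecules do not fit in a ", box_edge, " nm box")
  as.integer(round(avail * SOLVENT_DENSITY[[solvent]] /
                     SOLVENT_MAPPING[[solvent]]))
}

mb_velocities <- function(masses, temperature) {
  n <- length(masses)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(kB * temperature / masses)
  # remove center-of-mass drift
  p <- colSums(v * masses)
  sweep(v, 2, p / sum(masses))
}

ff_masses <- function(ff) {
  m <- vapply(ff$beads, `[[`, 0, "mass")
  names(m) <- vapply(ff$beads, `[[`, "", "name")
  m
}

#' Build an initial system
#'
#' Random sequential placement of whole molecules (freely jointed
#' chains at their bond lengths) with a minimum inter-bead distance,
#' followed by Maxwell-Boltzmann velocities at the requested
#' temperature with zero total momentum.  Composition follows
#' [molecule_count()] and [solvent_count()].  Reproducible from
#' `spec$seed`.
#'
#' @param spec a [system_spec()].
#' @param ff an `hpf_forcefield` providing the `ADOH` and solvent
#'   topologies.
#' @param min_dist minimum inter-bead distance during placement, nm.
#' @param max_trials placement attempts per molecule before giving up.
#' @return a [system_state()].
#' @export
build_system <- function(spec, ff, min_dist = 0.25, max_trials = 2000) {
  if (!spec$solvent %in% names(ff$topologies))
    stop("force field lacks a topology for solvent '", spec$solvent, "'")
  n_adoh <- molecule_count(spec$concentration, spec$box_edge)
  n_solv <- solvent_count(spec$box_edge, n_adoh, spec$solvent)
  adoh <- ff$topologies[["ADOH"]]
  set.seed(spec$seed)
  res <- build_positions_cpp(
    template_id = c(rep(1L, n_adoh), rep(2L, n_solv)),
    bond_lengths = list(adoh$r0, numeric(0)),
    L = spec$box_edge, min_dist = min_dist, max_trials = max_trials)
  nb <- length(adoh$beads)
  species <- c(rep(adoh$beads, n_adoh), rep(spec$solvent, n_solv))
  molecule_id <- c(rep(seq_len(n_adoh), each = nb),
                   if (n_solv > 0) n_adoh + seq_len(n_solv))
  molecule_name <- c(rep("ADOH", n_adoh * nb), rep(spec$solvent, n_solv))
  masses <- ff_masses(ff)[species]
  vel <- mb_velocities(masses, spec$temperature)
  system_state(spec$box_edge, res$positions, vel, species, molecule_id,
               molecule_name, time = 0)
}

#' Planted-cluster fixture
#'
#' Surfactant-only configuration whose ground-truth cluster partition
#' is the `sizes` list.  Within a cluster, molecule centers sit
#' `intra_spacing` apart along a line (so any clustering cutoff above
#' `intra_spacing` plus the molecular extent connects them); clusters
#' are placed on a coarse grid so that inter-cluster gaps exceed
#' `2 * max_cutoff`.  The planted partition is attached as the
#' `ground_truth` attribute.
#'
#' @param sizes integer vector of cluster sizes.
#' @param box_edge nm.
#' @param intra_spacing nm between neighboring molecule centers in a
#'   cluster.
#' @param seed integer seed for the small positional jitter.
#' @param max_cutoff largest clustering cutoff (nm) the fixture must
#'   stay unambiguous for.
#' @return a [system_state()] of 5-bead `ADOH` molecules with attribute
#'   `ground_truth` (list with `sizes` and per-molecule `labels`).
#' @export
make_planted_clusters <- function(sizes, box_edge, intra_spacing = 0.4,
                                  seed = 1, max_cutoff = 2.0) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  k <- ceiling(length(sizes)^(1 / 3))
  g <- box_edge / k
  extent <- (max(sizes) - 1) * intra_spacing + 0.2
  if (g - extent <= 2 * max_cutoff)
    stop("infeasible geometry: clusters of extent ", round(extent, 2),
         " nm cannot keep gaps > ", 2 * max_cutoff, " nm in a ",
         box_edge, " nm box")
  set.seed(seed)
  centers <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                   z = seq_len(k)))[seq_along(sizes), ,
                                                    drop = FALSE]
  centers <- (centers - 0.5) * g
  # compact 5-bead molecule: beads on a tight ring around the center
  off <- 0.06 * cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5), 0)
  pos <- NULL
  labels <- integer(0)
  for (ci in seq_along(sizes)) {
    for (mi in seq_len(sizes[ci])) {
      com <- centers[ci, ] + c((mi - 1) * intra_spacing, 0, 0)
      jit <- matrix(runif(15, -0.02, 0.02), 5, 3)
      pos <- rbind(pos, sweep(off + jit, 2, com, `+`))
      labels <- c(labels, ci)
    }
  }
  n_mol <- sum(sizes)
  st <- system_state(box_edge, pos, matrix(0, n_mol * 5, 3),
                     species = rep(c("A", "E", "E", "E", "T"), n_mol),
                     molecule_id = rep(seq_len(n_mol), each = 5),
                     molecule_name = rep("ADOH", n_mol * 5))
  attr(st, "ground_truth") <- list(sizes = sizes, labels = labels)
  st
}

#' Trajectory container
#'
#' Frames store unwrapped coordinates; wrapped coordinates are derived
#' on demand by [frame_state()].
#'
#' @param box_edge nm.
#' @param species,molecule_id,molecule_name per-particle metadata.
#' @param times frame times, ps.
#' @param frames list of N x 3 unwrapped coordinate matrices, nm.
#' @param velocities optional final-frame velocity matrix.
#' @param log optional per-interval data frame (step, time, kinetic
#'   temperature, field energy, bonded energy).
#' @param config optional run configuration echo.
#' @return an object of class `hpf_trajectory`.
#' @export
hpf_trajectory <- function(box_edge, species, molecule_id, molecule_name,
                           times, frames, velocities = NULL, log = NULL,
                           config = NULL) {
  stopifnot(length(times) == length(frames))
  structure(list(box_edge = box_edge, species = species,
                 molecule_id = as.integer(molecule_id),
                 molecule_name = molecule_name, times = times,
                 frames = frames, velocities = velocities, log = log,
                 config = config),
            class = "hpf_trajectory")
}

#' @export
print.hpf_trajectory <- function(x, ...) {
  cat("hpf_trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "particles, box", x$box_edge, "nm, t =",
      x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `hpf_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame as a `system_state`
#'
#' @param traj an `hpf_trajectory`.
#' @param i frame index (1-based).
#' @param wrapped wrap coordinates into the periodic box?
#' @return a [system_state()].
#' @export
frame_state <- function(traj, i, wrapped = TRUE) {
  x <- traj$frames[[i]]
  if (wrapped) x <- wrap_positions(x, traj$box_edge)
  st <- system_state(traj$box_edge, x, matrix(0, nrow(x), 3), traj$species,
                     traj$molecule_id, traj$molecule_name,
                     time = traj$times[i])
  if (!wrapped) st$positions <- x
  st
}

#' Brownian-walker fixture trajectory
#'
#' Independent Gaussian displacements with variance `2 * D * dt` per
#' Cartesian component per step (total `6 D dt`), the ground truth for
#' Einstein-relation diffusion fitting.  Unwrapped coordinates are
#' retained; the planted `D` is attached as attribute `ground_truth`.
#'
#' @param n_particles number of walkers.
#' @param D diffusion coefficient, nm^2/ps.
#' @param n_frames number of frames (including the initial one).
#' @param dt frame spacing, ps.
#' @param box_edge nm.
#' @param seed integer seed.
#' @return an `hpf_trajectory`.
#' @export
make_brownian_trajectory <- function(n_particles, D, n_frames, dt,
                                     box_edge, seed = 1) {
  stopifnot(D >= 0, n_frames >= 1)
  set.seed(seed)
  x0 <- matrix(runif(3 * n_particles, 0, box_edge), n_particles, 3)
  frames <- vector("list", n_frames)
  frames[[1]] <- x0
  sdv <- sqrt(2 * D * dt)
  for (i in seq_len(n_frames - 1))
    frames[[i + 1]] <- frames[[i]] +
      matrix(rnorm(3 * n_particles, sd = sdv), n_particles, 3)
  traj <- hpf_trajectory(box_edge, species = rep("P", n_particles),
                         molecule_id = seq_len(n_particles),
                         molecule_name = rep("P", n_particles),
                         times = (seq_len(n_frames) - 1) * dt,
                         frames = frames)
  attr(traj, "ground_truth") <- list(D = D)
  traj
}
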