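test_that("CIC assignment spreads weight correctly and conserves counts", {
  # one particle exactly at a cell center: full weight in that cell
  st <- system_state(4, matrix(c(0.5, 0.5, 0.5), 1), matrix(0, 1, 3),
                     "W", 1L, "W")
  fld <- assign_density(st, 4)
  expect_equal(fld$phi[1, 1, 1, 1], 1)  # cell volume is 1 nm^3
  expect_equal(sum(fld$phi), 1)
  # one particle at a cell corner: 1/8 in each of the 8 cells
  st2 <- system_state(4, matrix(c(1, 1, 1), 1), matrix(0, 1, 3),
                      "W", 1L, "W")
  fld2 <- assign_density(st2, 4)
  w <- fld2$phi[1:2, 1:2, 1:2, 1]
  expect_equal(as.vector(w), rep(1 / 8, 8))
  # random states conserve per-species counts to 1e-9 relative
  for (seed in 1:3) {
    st3 <- random_state(500, 7.3, c("A", "E", "W"), seed)
    f3 <- assign_density(st3, 6)
    v <- f3$cell_edge^3
    for (s in seq_along(f3$species)) {
      ns <- sum(st3$species == f3$species[s])
      expect_lt(abs(sum(f3$phi[, , , s]) * v - ns) / max(ns, 1), 1e-9)
    }
  }
})

test_that("field potentials match the density functional cell-by-cell", {
  ff <- default_adoh_forcefield("W")
  m <- 4
  mk_field <- function(phi_list, phi0, L = 4) {
    S <- length(phi_list)
    phi <- array(0, c(m, m, m, S))
    for (s in seq_len(S)) phi[, , , s] <- phi_list[[s]]
    structure(list(n_cells = m, cell_edge = L / m, box_edge = L,
                   species = names(phi_list), phi = phi, phi0 = phi0,
                   V = NULL), class = "density_field")
  }
  phi0 <- 8
  # homogeneous pure solvent at the reference density: zero potential
  fC <- field_potential(mk_field(list(C = phi0), phi0), ff$chi)
  expect_equal(max(abs(fC$V)), 0)
  # pure W at phi0: a head bead there feels chi(A, W) = 33.75 kJ/mol
  fW <- field_potential(mk_field(list(A = 0 * phi0, W = phi0 + 0 * phi0),
                                 phi0), ff$chi)
  expect_equal(fW$V[2, 3, 1, 1], 33.75)
  # half W, half E: V_E = chi(E, W)/2 = 0.75 kJ/mol
  fE <- field_potential(mk_field(list(E = phi0 / 2 + 0 * phi0,
                                      W = phi0 / 2 + 0 * phi0), phi0),
                        ff$chi)
  expect_equal(fE$V[1, 1, 1, 1], 0.75)
  expect_error(field_potential(mk_field(list(Z = phi0), phi0), ff$chi),
               "species mismatch")
})

test_that("interaction energy vanishes in reference states and penalizes mixing", {
  ff <- default_adoh_forcefield("W")
  st <- random_state(400, 6, c("A", "W"), seed = 2)
  fld <- assign_density(st, 6, species_levels = ff$chi$species)
  # ideal-gas limit: all chi = 0, kappa_inv = 0
  chi0 <- chi_matrix(ff$chi$species, matrix(0, 5, 5), kappa_inv = 0)
  expect_equal(interaction_energy(fld, chi0), 0)
  # uniform single species at the reference density
  stW <- random_state(400, 6, "W", seed = 3)
  fldW <- assign_density(stW, 1)  # single cell -> exactly uniform
  expect_equal(interaction_energy(fldW, ff$chi), 0, tolerance = 1e-10)
  # demixed two-species slabs cost less than the mixed state for chi > 0
  m <- 4
  mk <- function(wA) {
    phi <- array(0, c(m, m, m, 2))
    phi[, , , 1] <- 8 * wA
    phi[, , , 2] <- 8 * (1 - wA)
    structure(list(n_cells = m, cell_edge = 1, box_edge = 4,
                   species = c("A", "W"), phi = phi, phi0 = 8, V = NULL),
              class = "density_field")
  }
  mixed <- mk(array(0.5, c(m, m, m)))
  wdem <- array(0, c(m, m, m)); wdem[1:2, , ] <- 1
  demixed <- mk(wdem)
  expect_gt(interaction_energy(mixed, ff$chi) -
              interaction_energy(demixed, ff$chi), 0)
})

test_that("field forces equal the finite-difference gradient of the energy", {
  ff <- default_adoh_forcefield("W")
  st <- random_state(30, 4, c("A", "E", "W"), seed = 7)
  mesh <- 4
  fld <- field_potential(assign_density(st, mesh,
                                        species_levels = ff$chi$species),
                         ff$chi)
  F <- field_forces(st, fld)
  delta <- 1e-4
  for (p in c(1, 9, 23)) {
    for (d in 1:3) {
      xp <- st$positions; xp[p, d] <- xp[p, d] + delta
      xm <- st$positions; xm[p, d] <- xm[p, d] - delta
      f_fd <- -(config_field_energy(xp, st, ff$chi, mesh) -
                  config_field_energy(xm, st, ff$chi, mesh)) / (2 * delta)
      expect_lt(abs(F[p, d] - f_fd) / max(abs(f_fd), 1e-3), 1e-4)
    }
  }
  # uniform potential: zero force everywhere
  fld0 <- fld
  fld0$V[] <- 3.3
  expect_equal(max(abs(field_forces(st, fld0))), 0)
  # linear ramp in V_A of slope s: force -s on A, 0 transverse
  m <- 8; L <- 8
  stA <- system_state(L, matrix(c(3.21, 4.6, 2.2), 1), matrix(0, 1, 3),
                      "A", 1L, "ADOH")
  fldA <- structure(list(n_cells = m, cell_edge = 1, box_edge = L,
                         species = "A",
                         phi = array(1, c(m, m, m, 1)), phi0 = 1,
                         V = array(rep(0.5 * (seq_len(m) - 0.5),
                                       times = m * m), c(m, m, m, 1))),
                    class = "density_field")
  FA <- field_forces(stA, fldA)
  expect_equal(FA[1, ], c(-0.5, 0, 0), tolerance = 1e-10)
})

test_that("bonded forces obey Hooke's law and its finite-difference oracle", {
  ff <- default_adoh_forcefield("W")
  dimer_ff <- forcefield(ff$beads, ff$chi,
                         list(molecule_topology("DIM", c("E", "E"),
                                                cbind(1, 2), 1250, 0.28)))
  mk <- function(r, dir = c(1, 0, 0))
    system_state(10, rbind(c(1, 1, 1), c(1, 1, 1) + r * dir),
                 matrix(0, 2, 3), c("E", "E"), c(1L, 1L),
                 c("DIM", "DIM"))
  at_rest <- bonded_forces(mk(0.28), dimer_ff)
  expect_equal(max(abs(at_rest$forces)), 0, tolerance = 1e-12)
  expect_equal(at_rest$energy, 0, tolerance = 1e-12)
  stretched <- bonded_forces(mk(0.38), dimer_ff)
  expect_equal(stretched$forces[1, 1], 125, tolerance = 1e-9)
  expect_equal(stretched$forces[2, 1], -125, tolerance = 1e-9)
  expect_equal(stretched$energy, 0.5 * 1250 * 0.01)
  # a bond whose minimum-image length exceeds L/2 is ambiguous
  expect_error(bonded_forces(mk(5, dir = c(1, 1, 1)), dimer_ff),
               "minimum image")
  # random chain vs finite differences
  set.seed(9)
  chain <- system_state(10, matrix(runif(15, 4, 6), 5, 3), matrix(0, 5, 3),
                        c("A", "E", "E", "E", "T"), rep(1L, 5),
                        rep("ADOH", 5))
  bf <- bonded_forces(chain, ff)
  delta <- 1e-5
  for (p in 1:5) for (d in 1:3) {
    cp <- chain; cp$positions[p, d] <- cp$positions[p, d] + delta
    cm <- chain; cm$positions[p, d] <- cm$positions[p, d] - delta
    f_fd <- -(bonded_forces(cp, ff)$energy -
                bonded_forces(cm, ff)$energy) / (2 * delta)
    expect_lt(abs(bf$forces[p, d] - f_fd) / max(abs(f_fd), 1), 1e-6)
  }
})

test_that("mesh electrostatics reproduce Coulomb far fields and symmetries", {
  ff <- default_adoh_forcefield("C", charged_tails = TRUE)
  pair_ff <- forcefield(ff$beads, ff$chi,
                        list(molecule_topology("PAIR", c("E", "E"),
                                               matrix(integer(0), 0, 2),
                                               numeric(0), numeric(0),
                                               charges = c(0.4, -0.4))),
                        epsilon_r = 5, tail_charges = TRUE)
  mk <- function(origin) {
    p <- rbind(origin, origin + c(3, 0, 0))
    system_state(20, p, matrix(0, 2, 3), c("E", "E"), c(1L, 1L),
                 c("PAIR", "PAIR"))
  }
  st <- mk(c(5.5, 10.5, 10.5))
  F <- electrostatic_forces(st, pair_ff, mesh_cells = 40)
  f_expect <- 138.935 * 0.4^2 / (5 * 3^2)
  expect_lt(abs(F[1, 1] - f_expect) / f_expect, 0.05)  # attraction, +x
  expect_lt(abs(F[2, 1] + f_expect) / f_expect, 0.05)
  expect_lt(max(abs(F[, 2:3])), 0.05 * f_expect)
  # translation by whole mesh cells: identical forces
  F2 <- electrostatic_forces(mk(c(5.5, 10.5, 10.5) + c(2, 1.5, -3)),
                             pair_ff, mesh_cells = 40)
  expect_equal(F2, F, tolerance = 1e-9)
  # zero charges: zero forces
  st0 <- random_state(20, 10, "W", seed = 1)
  st0$molecule_name <- rep("W", 20)
  expect_equal(max(abs(electrostatic_forces(st0,
                                            default_adoh_forcefield("W"),
                                            10))), 0)
  # net charge is rejected
  bad_ff <- pair_ff
  bad_ff$topologies[["PAIR"]]$charges <- c(0.4, 0)
  expect_error(electrostatic_forces(st, bad_ff, 20), "net charge")
})

test_that("free flight, equipartition and microcanonical energy conservation hold", {
  ffi <- ideal_gas_ff()
  # single free particle moves on a straight line
  st1 <- system_state(10, matrix(c(2, 2, 2), 1), matrix(c(0.1, -0.05, 0.2), 1),
                      "W", 1L, "W")
  cfg1 <- sim_config(n_steps = 100, dt = 0.03, thermostat = FALSE,
                     mesh_cells = 5, frame_stride = 100, seed = 1)
  tr1 <- run_hpf(st1, ffi, cfg1)
  expect_equal(tr1$frames[[2]][1, ],
               c(2, 2, 2) + c(0.1, -0.05, 0.2) * 3, tolerance = 1e-10)
  # thermostatted ideal gas converges to the target temperature from
  # deliberately cold initial velocities
  set.seed(4)
  n <- 1500
  stg <- system_state(8, matrix(runif(3 * n, 0, 8), n, 3),
                      matrix(0, n, 3), rep("W", n), seq_len(n),
                      rep("W", n))
  cfg <- sim_config(n_steps = 3000, seed = 5, mesh_cells = 8,
                    frame_stride = 100)
  tr <- run_hpf(stg, ffi, cfg)
  burn <- tr$log$step > 1000
  expect_lt(abs(mean(tr$log$kinetic_T[burn]) - 300) / 300, 0.03)
  # microcanonical chain fluid: total energy drift < 0.1%
  ff <- default_adoh_forcefield("W")
  ffb <- ideal_gas_ff()
  set.seed(6)
  chains <- 40
  res <- hpfmd:::build_positions_cpp(rep(1L, chains),
                                     list(c(0.33, 0.28, 0.28, 0.28)),
                                     8, 0.25, 500)
  stc <- system_state(8, res$positions,
                      matrix(rnorm(chains * 5 * 3,
                                   sd = sqrt(0.0083145 * 300 / 60)),
                             chains * 5, 3),
                      rep(c("A", "E", "E", "E", "T"), chains),
                      rep(seq_len(chains), each = 5),
                      rep("ADOH", chains * 5))
  cfgc <- sim_config(n_steps = 10000, dt = 0.001, thermostat = FALSE,
                     mesh_cells = 8, frame_stride = 500, seed = 7)
  trc <- run_hpf(stc, ffb, cfgc)
  n_at <- chains * 5
  etot <- 1.5 * n_at * 0.0083145 * trc$log$kinetic_T + trc$log$bonded_E
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 0.001)
})

test_that("runs are reproducible and emit frames at the configured stride", {
  ffi <- ideal_gas_ff()
  set.seed(8)
  n <- 100
  st <- system_state(5, matrix(runif(3 * n, 0, 5), n, 3),
                     matrix(rnorm(3 * n, sd = 0.2), n, 3), rep("W", n),
                     seq_len(n), rep("W", n))
  cfg <- sim_config(n_steps = 10000, seed = 9, mesh_cells = 5,
                    frame_stride = 100)
  tr <- run_hpf(st, ffi, cfg)
  expect_equal(n_frames(tr), 101)  # includes frame 0
  expect_equal(tr$times[2] - tr$times[1], 100 * 0.03)
  tr2 <- run_hpf(st, ffi, cfg)
  expect_identical(tr$frames[[101]], tr2$frames[[101]])
  expect_error(sim_config(n_steps = 100, collision_frequency = 40),
               "exceeds 1")
})
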