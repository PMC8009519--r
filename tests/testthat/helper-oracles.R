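# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths (plain-R
# union-find, direct-summation Fourier transforms, finite differences).

# Brute-force cluster partition: O(N^2) union over all inter-molecular
# bead pairs with a plain-R union-find.
brute_clusters <- function(state, cutoff, molecule = "ADOH") {
  sel <- state$molecule_name %in% molecule
  pos <- state$positions[sel, , drop = FALSE]
  mol <- state$molecule_id[sel]
  ids <- sort(unique(mol))
  parent <- seq_along(ids)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  L <- state$box_edge
  n <- nrow(pos)
  midx <- match(mol, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (midx[i] == midx[j]) next
      d <- abs(pos[i, ] - pos[j, ])
      d <- pmin(d, L - d)
      if (sum(d * d) < cutoff^2) {
        ri <- find_root(midx[i])
        rj <- find_root(midx[j])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(ids), find_root, 0L)
  # label each component by its smallest molecule id
  stats::setNames(vapply(roots, function(r) ids[min(which(roots == r))], 0),
                  ids)
}

# Partition equality up to label names: same grouping of molecule ids.
same_partition <- function(labels_a, labels_b) {
  ga <- split(names(labels_a), labels_a)
  gb <- split(names(labels_b), labels_b)
  setequal(lapply(ga, sort), lapply(gb, sort))
}

# Direct-summation Fourier transform of (g-1), trapezoid on the bins,
# written independently of saxs_from_rdf.
direct_saxs_oracle <- function(r, g, rho, Q) {
  sapply(Q, function(q) {
    f <- (g - 1) * r^2 * sin(q * r) / (q * r)
    s <- 0
    for (k in seq_len(length(r) - 1))
      s <- s + (r[k + 1] - r[k]) * (f[k] + f[k + 1]) / 2
    1 + 4 * pi * rho * s
  })
}

# Total discretized field energy of a configuration, for the
# finite-difference force oracle.
config_field_energy <- function(positions, state_template, chi, mesh) {
  st <- state_template
  st$positions <- hpfmd:::wrap_positions(positions, st$box_edge)
  fld <- assign_density(st, mesh, species_levels = chi$species)
  interaction_energy(fld, chi)
}

# Random multi-species test state (no topology constraints).
random_state <- function(n, box, species_pool = c("A", "W"), seed = 1) {
  set.seed(seed)
  system_state(box, matrix(runif(3 * n, 0, box), n, 3),
               matrix(0, n, 3),
               species = sample(species_pool, n, replace = TRUE),
               molecule_id = seq_len(n),
               molecule_name = rep("X", n))
}

# Ideal-gas force field: interactions switched off, single-bead
# topology per species plus the standard amphiphile chain.
ideal_gas_ff <- function(solvent = "W") {
  ff <- default_adoh_forcefield(solvent)
  ff$chi$values[] <- 0
  ff$chi$kappa_inv <- 0
  ff
}
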