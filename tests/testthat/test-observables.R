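test_that("cluster census matches the planted truth and its invariants", {
  st <- make_planted_clusters(c(7, 2, 2, 1, 1), 20, 0.4, seed = 1)
  rep <- find_clusters(st, 0.8)
  expect_equal(rep$histogram, c(`1` = 2L, `2` = 2L, `7` = 1L))
  expect_equal(rep$mean_size, 13 / 5)
  expect_equal(rep$monomer_fraction, 2 / 13)
  # conservation: sum(N * count) = number of surfactant molecules
  expect_equal(sum(as.integer(names(rep$histogram)) * rep$histogram), 13L)
  expect_gte(rep$mean_size, 1)
  # labels are the smallest molecule id of each cluster
  expect_true(all(vapply(split(as.integer(names(rep$labels)), rep$labels),
                         min, 0) == sort(unique(rep$labels))))
  expect_error(find_clusters(st, 0), "cutoff")
  expect_error(find_clusters(st, 11), "cutoff")
})

test_that("two molecules split exactly at the contact cutoff", {
  mk <- function(gap) {
    pos <- rbind(c(5, 5, 5), c(5 + gap, 5, 5))
    system_state(12, pos, matrix(0, 2, 3), c("A", "A"), c(1L, 2L),
                 c("ADOH", "ADOH"))
  }
  below <- find_clusters(mk(0.799), 0.8)
  above <- find_clusters(mk(0.801), 0.8)
  expect_equal(unname(below$histogram["2"]), 1L)
  expect_equal(unname(above$histogram["1"]), 2L)
  expect_equal(above$monomer_fraction, 1)
})

test_that("cluster detection agrees with the brute-force O(N^2) oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n_mol <- 25
    pos <- NULL
    for (i in seq_len(n_mol)) {
      com <- runif(3, 0, 6)
      pos <- rbind(pos, sweep(matrix(runif(9, -0.3, 0.3), 3, 3), 2, com,
                              `+`))
    }
    st <- system_state(6, pos, matrix(0, n_mol * 3, 3),
                       rep(c("A", "E", "T"), n_mol),
                       rep(seq_len(n_mol), each = 3),
                       rep("ADOH", n_mol * 3))
    for (cutoff in c(0.5, 0.9)) {
      rep <- find_clusters(st, cutoff)
      expect_true(same_partition(rep$labels, brute_clusters(st, cutoff)),
                  info = paste("seed", seed, "cutoff", cutoff))
    }
  }
})

test_that("cluster series aggregation pools correctly", {
  st <- make_planted_clusters(c(2, 1), 15, 0.4, seed = 3)
  r <- find_clusters(st, 0.8)
  agg <- aggregate_cluster_series(list(r, r, r))
  expect_equal(agg$series$mean_size, rep(r$mean_size, 3))
  expect_equal(agg$series$monomer_fraction, rep(r$monomer_fraction, 3))
  # alternating frames of ten monomers and five dimers: mean of means 1.5
  mk_rep <- function(hist, n_mol) {
    sizes <- rep(as.integer(names(hist)), hist)
    structure(list(time = 0, labels = NULL,
                   histogram = hist,
                   mean_size = mean(sizes),
                   monomer_fraction = sum(sizes == 1) / n_mol,
                   n_molecules = n_mol, cutoff = 0.8),
              class = "cluster_report")
  }
  series <- list(mk_rep(c(`1` = 10L), 10), mk_rep(c(`2` = 5L), 10))
  agg2 <- aggregate_cluster_series(series)
  expect_equal(agg2$mean_of_means, 1.5)
  expect_equal(sum(agg2$histogram$probability), 1)
  # bin width 5 groups sizes 1-5
  agg5 <- aggregate_cluster_series(series, bin_width = 5)
  expect_equal(agg5$histogram$probability[1], 1)
})

test_that("RDF is flat for an ideal gas and exact for a two-particle system", {
  set.seed(11)
  n <- 3000; L <- 10
  frames <- lapply(1:12, function(i) matrix(runif(3 * n, 0, L), n, 3))
  traj <- hpf_trajectory(L, rep("W", n), seq_len(n), rep("W", n),
                         seq_len(12), frames)
  sel <- selection(species = "W")
  rdf <- radial_distribution(traj, sel, sel, r_max = 4, bin_width = 0.1)
  keep <- rdf$table$r >= 1
  expect_lt(max(abs(rdf$table$g[keep] - 1)), 0.05)
  # two fixed particles: single occupied bin of height V / (2 * shell)
  d <- 2.02
  tp <- hpf_trajectory(L, c("W", "W"), 1:2, c("W", "W"), 0,
                       list(rbind(c(1, 1, 1), c(1 + d, 1, 1))))
  r2 <- radial_distribution(tp, sel, sel, r_max = 4, bin_width = 0.1)
  bin <- findInterval(d, seq(0, 4, by = 0.1))
  shell <- 4 / 3 * pi * ((bin * 0.1)^3 - ((bin - 1) * 0.1)^3)
  expect_equal(r2$table$g[bin], L^3 / shell, tolerance = 1e-10)
  # the single occupied bin also shows self pairs are excluded: no
  # zero-distance spike for an identical selection
  expect_equal(sum(r2$table$g > 0), 1)
  expect_equal(r2$table$g[1], 0)
  expect_error(radial_distribution(traj, sel, sel, r_max = 6), "box_edge/2")
  expect_error(radial_distribution(traj, selection(species = "Z"), sel, 4),
               "empty selection")
})

test_that("RDF supports center-of-mass selections and cross pairs", {
  # two rigid dimers with COMs 1.05 nm apart
  pos <- rbind(c(2, 2, 2), c(2.4, 2, 2), c(2, 3.05, 2), c(2.4, 3.05, 2))
  traj <- hpf_trajectory(8, rep(c("A", "T"), 2), rep(1:2, each = 2),
                         rep("ADOH", 4), 0, list(pos))
  sel <- selection(molecule = "ADOH", com = TRUE)
  rdf <- radial_distribution(traj, sel, sel, r_max = 2, bin_width = 0.1)
  expect_equal(rdf_peak(rdf), 1.05)
  # cross-species selection normalizes by the partner density
  selA <- selection(species = "A"); selT <- selection(species = "T")
  rx <- radial_distribution(traj, selA, selT, r_max = 2, bin_width = 0.1)
  expect_true(sum(rx$table$g > 0) >= 1)
})

test_that("MSD recovers planted diffusion and flags ballistic motion", {
  traj <- make_brownian_trajectory(300, 0.25, 600, 0.1, 40, seed = 6)
  msd <- mean_square_displacement(traj)
  expect_equal(msd$table$sigma2[1], 0)
  fit <- fit_diffusion(msd)
  expect_lt(abs(fit$D - 0.25) / 0.25, 0.05)
  expect_equal(fit$D_1e5_cm2_s, fit$D * 1000)
  expect_gt(fit$r_squared, 0.999)
  # ballistic: sigma^2 = v^2 t^2 exactly, and the linear fit is flagged
  v <- 0.2; nfr <- 200
  frames <- lapply(seq_len(nfr) - 1, function(i)
    matrix(rep(c(v * i * 0.1, 0, 0), each = 50), 50, 3) +
      matrix(seq_len(150), 50, 3))
  tb <- hpf_trajectory(1e3, rep("P", 50), 1:50, rep("P", 50),
                       (seq_len(nfr) - 1) * 0.1, frames)
  mb <- mean_square_displacement(tb)
  expect_equal(mb$table$sigma2, (v * mb$table$t)^2, tolerance = 1e-8)
  fb <- fit_diffusion(mb)
  expect_lt(fb$r_squared, 0.995)
  expect_error(fit_diffusion(msd, window = c(1e5, 2e5)), "fewer than 2")
})

test_that("selection mini-grammar parses species, molecule and com clauses", {
  s <- parse_selection("species=A,E & molecule=ADOH & com")
  expect_equal(s$species, c("A", "E"))
  expect_equal(s$molecule, "ADOH")
  expect_true(s$com)
  expect_error(parse_selection("bogus=1"), "cannot parse")
})
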