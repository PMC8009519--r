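# Structural and dynamic observables: cluster census (connected
# components of the inter-molecular contact graph), radial distribution
# functions, and mean-square displacement with Einstein-relation
# diffusion fits.

#' Bead selection
#'
#' Restrict an analysis to beads by species and/or molecule name,
#' optionally reduced to one center-of-mass point per molecule.
#' The equivalent mini-grammar (for [parse_selection()] and the command
#' line) is e.g. `"species=A & molecule=ADOH & com"`.
#'
#' @param species species labels to keep (NULL = all).
#' @param molecule molecule names to keep (NULL = all).
#' @param com reduce each selected molecule to its center of mass?
#' @return an object of class `bead_selection`.
#' @export
selection <- function(species = NULL, molecule = NULL, com = FALSE) {
  structure(list(species = species, molecule = molecule, com = com),
            class = "bead_selection")
}

#' @rdname selection
#' @param text selection string, clauses joined by `&`.
#' @export
parse_selection <- function(text) {
  cl <- trimws(strsplit(text, "&", fixed = TRUE)[[1]])
  sel <- selection()
  for (c0 in cl) {
    if (c0 == "com") sel$com <- TRUE
    else if (startsWith(c0, "species="))
      sel$species <- strsplit(sub("^species=", "", c0), ",")[[1]]
    else if (startsWith(c0, "molecule="))
      sel$molecule <- strsplit(sub("^molecule=", "", c0), ",")[[1]]
    else if (nzchar(c0)) stop("cannot parse selection clause '", c0, "'")
  }
  sel
}

# Apply a selection to per-particle metadata; returns bead indices.
selection_index <- function(species, molecule_name, sel) {
  keep <- rep(TRUE, length(species))
  if (!is.null(sel$species)) keep <- keep & species %in% sel$species
  if (!is.null(sel$molecule)) keep <- keep & molecule_name %in% sel$molecule
  which(keep)
}

# Coordinates for a selection in one frame (unwrapped input).  For COM
# selections, masses (named by species) weight the average when given.
selection_coords <- function(x, species, molecule_id, idx, sel,
                             masses = NULL) {
  if (!sel$com) return(x[idx, , drop = FALSE])
  mid <- molecule_id[idx]
  w <- if (is.null(masses)) rep(1, length(idx)) else masses[species[idx]]
  ord <- order(mid)
  idx <- idx[ord]; mid <- mid[ord]; w <- w[ord]
  xs <- x[idx, , drop = FALSE] * w
  num <- rowsum(xs, mid)
  den <- rowsum(w, mid)
  num / as.vector(den)
}

#' Cluster census of one frame
#'
#' Two surfactant molecules are connected iff any inter-molecular bead
#' pair lies within `cutoff` under the minimum image convention;
#' clusters are the connected components.  Cluster labels are
#' deterministic: each cluster is labeled by its smallest molecule id.
#'
#' @param state a [system_state()].
#' @param cutoff contact distance, nm; must lie in `(0, box_edge/2)`.
#'   The default 0.8 nm sits just past the ~0.75 nm first maximum of
#'   the surfactant-surfactant center-of-mass RDF; results are
#'   cutoff-sensitive, so expose this deliberately.
#' @param molecule molecule name(s) treated as surfactant.
#' @return an object of class `cluster_report`: `time`, per-molecule
#'   `labels` (named by molecule id), size `histogram`, `mean_size`,
#'   and `monomer_fraction` (fraction of surfactant molecules in
#'   clusters of size 1).
#' @export
find_clusters <- function(state, cutoff = 0.8, molecule = "ADOH") {
  if (cutoff <= 0 || cutoff >= state$box_edge / 2)
    stop("cutoff must lie in (0, box_edge/2)")
  sel <- state$molecule_name %in% molecule
  if (!any(sel)) stop("no surfactant molecules selected")
  pos <- state$positions[sel, , drop = FALSE]
  mol <- state$molecule_id[sel]
  mol_ids <- sort(unique(mol))
  midx <- match(mol, mol_ids)
  edges <- contact_edges_cpp(pos, midx, state$box_edge, cutoff)
  g <- igraph::make_empty_graph(n = length(mol_ids), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by the smallest molecule id in each component
  labels <- vapply(comp, function(cid) mol_ids[min(which(comp == cid))],
                   0)
  sizes <- as.vector(table(comp))
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  n_mol <- length(mol_ids)
  structure(list(time = state$time,
                 labels = stats::setNames(labels, mol_ids),
                 histogram = stats::setNames(as.integer(hist),
                                             names(hist)),
                 mean_size = mean(sizes),
                 monomer_fraction = sum(sizes == 1) / n_mol,
                 n_molecules = n_mol, cutoff = cutoff),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report at t =", x$time, "ps:", x$n_molecules,
      "molecules, mean size", signif(x$mean_size, 3),
      ", monomer fraction", signif(x$monomer_fraction, 3), "\n")
  invisible(x)
}

#' Aggregate a series of cluster reports
#'
#' Per-frame time series of mean cluster size and monomer fraction,
#' plus the pooled normalized cluster-size distribution with a
#' configurable bin width (width 1 resolves single sizes; width 5
#' reproduces the coarser presentation used for micellar systems).
#'
#' @param reports list of [find_clusters()] results.
#' @param bin_width size-histogram bin width (cluster-size units).
#' @return list with `series` (data frame: time, mean_size,
#'   monomer_fraction), `histogram` (data frame: size bin lower edge,
#'   probability; sums to 1) and `mean_of_means`.
#' @export
aggregate_cluster_series <- function(reports, bin_width = 1) {
  stopifnot(length(reports) >= 1)
  series <- data.frame(
    time = vapply(reports, `[[`, 0, "time"),
    mean_size = vapply(reports, `[[`, 0, "mean_size"),
    monomer_fraction = vapply(reports, `[[`, 0, "monomer_fraction"))
  sizes <- unlist(lapply(reports, function(r)
    rep(as.integer(names(r$histogram)), r$histogram)))
  edges <- seq(1, max(sizes) + bin_width, by = bin_width)
  bin <- findInterval(sizes, edges)
  tab <- table(factor(bin, levels = seq_along(edges)))
  hist <- data.frame(size = edges, probability = as.vector(tab) / sum(tab))
  hist <- hist[hist$probability > 0 | hist$size <= max(sizes), ]
  list(series = series, histogram = hist,
       mean_of_means = mean(series$mean_size))
}

#' Radial distribution function
#'
#' Standard minimum-image pair-count histogram normalized by the
#' ideal-gas expectation (shell volume times partner density per
#' center), averaged over frames.  Self-pairs are excluded when the two
#' selections are identical.  Supports per-molecule center-of-mass
#' selections (e.g. the surfactant-surfactant COM RDF).
#'
#' @param traj an [hpf_trajectory()].
#' @param sel_a,sel_b [selection()] objects (or strings for
#'   [parse_selection()]).
#' @param r_max histogram range, nm; at most half the box edge.
#' @param bin_width nm.
#' @param frames frame indices to average over (default: all).
#' @param masses optional named per-species masses for mass-weighted
#'   centers (defaults to geometric centers).
#' @return an object of class `rdf_result`: data frame `table` with
#'   bin centers `r` (nm) and `g`, plus the selection descriptors and
#'   the number of frames averaged.
#' @export
radial_distribution <- function(traj, sel_a, sel_b, r_max,
                                bin_width = 0.05, frames = NULL,
                                masses = NULL) {
  if (is.character(sel_a)) sel_a <- parse_selection(sel_a)
  if (is.character(sel_b)) sel_b <- parse_selection(sel_b)
  L <- traj$box_edge
  if (r_max > L / 2) stop("r_max must not exceed box_edge/2")
  ia <- selection_index(traj$species, traj$molecule_name, sel_a)
  ib <- selection_index(traj$species, traj$molecule_name, sel_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty selection")
  same <- identical(ia, ib) && identical(sel_a, sel_b)
  if (is.null(frames)) frames <- seq_along(traj$frames)
  nbins <- ceiling(r_max / bin_width)
  counts <- numeric(nbins)
  na <- nb <- 0
  for (fi in frames) {
    x <- traj$frames[[fi]]
    A <- wrap_positions(
      selection_coords(x, traj$species, traj$molecule_id, ia, sel_a, masses),
      L)
    B <- if (same) A else wrap_positions(
      selection_coords(x, traj$species, traj$molecule_id, ib, sel_b, masses),
      L)
    counts <- counts + pair_hist_cpp(A, B, same, L, r_max, nbins)
    na <- nrow(A); nb <- nrow(B)
  }
  edges <- seq(0, r_max, length.out = nbins + 1)
  shell <- 4 / 3 * pi * diff(edges^3)
  rho <- (if (same) nb - 1 else nb) / L^3
  g <- counts / (length(frames) * na * shell * rho)
  structure(list(table = data.frame(r = (edges[-1] + edges[-(nbins + 1)]) / 2,
                                    g = g),
                 sel_a = sel_a, sel_b = sel_b,
                 frames_averaged = length(frames), bin_width = bin_width),
            class = "rdf_result")
}

#' Position of the first maximum of an RDF
#' @param rdf an `rdf_result`.
#' @return bin center (nm) of the global maximum of g(r).
#' @export
rdf_peak <- function(rdf) rdf$table$r[which.max(rdf$table$g)]

#' Mean-square displacement
#'
#' \eqn{\sigma^2(t)} averaged over particles and multiple time origins
#' (origins spaced half a lag apart, a standard bias/variance
#' compromise).  Requires unwrapped coordinates, which engine and
#' fixture trajectories carry natively.
#'
#' @param traj an [hpf_trajectory()].
#' @param sel a [selection()] (or string); default all particles.
#' @param masses optional named species masses for COM selections.
#' @return an object of class `msd_result` with `table` (lag time ps,
#'   `sigma2` nm^2) including the zero lag.
#' @export
mean_square_displacement <- function(traj, sel = selection(),
                                     masses = NULL) {
  if (is.character(sel)) sel <- parse_selection(sel)
  idx <- selection_index(traj$species, traj$molecule_name, sel)
  if (length(idx) == 0) stop("empty selection")
  coords <- lapply(traj$frames, function(x)
    selection_coords(x, traj$species, traj$molecule_id, idx, sel, masses))
  nf <- length(coords)
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 0
  lags <- seq_len(nf - 1)
  sigma2 <- vapply(lags, function(l) {
    origins <- seq(1, nf - l, by = max(1L, l %/% 2L))
    mean(vapply(origins, function(o) {
      d <- coords[[o + l]] - coords[[o]]
      mean(rowSums(d * d))
    }, 0))
  }, 0)
  structure(list(table = data.frame(t = c(0, lags * dt),
                                    sigma2 = c(0, sigma2)),
                 n_particles = length(unique(traj$molecule_id[idx]))),
            class = "msd_result")
}

#' Einstein-relation diffusion fit
#'
#' Least-squares line \eqn{\sigma^2(t) = 6 D t + A} over the stated lag
#' window; the slope divided by 6 is the diffusion coefficient in
#' nm^2/ps (`D_1e5_cm2_s` converts to the conventional
#' \eqn{10^{-5}} cm^2/s).  The fit's \eqn{R^2} is reported as a
#' linearity diagnostic (ballistic motion, for instance, yields a
#' visibly poor value on a curved \eqn{\sigma^2 \propto t^2} law).
#'
#' @param msd an `msd_result`.
#' @param window lag-time interval `c(lo, hi)` in ps; defaults to
#'   10--50% of the maximum lag.
#' @return list with `D` (nm^2/ps), `A` (nm^2), `D_1e5_cm2_s`,
#'   `r_squared` and `window`.
#' @export
fit_diffusion <- function(msd, window = NULL) {
  tt <- msd$table$t
  if (is.null(window)) window <- c(0.1, 0.5) * max(tt)
  keep <- tt >= window[1] & tt <= window[2]
  if (sum(keep) < 2)
    stop("fit window [", window[1], ", ", window[2],
         "] ps contains fewer than 2 lags")
  fit <- lm(sigma2 ~ t, data = msd$table[keep, ])
  slope <- coef(fit)[["t"]]
  list(D = slope / 6, A = coef(fit)[["(Intercept)"]],
       D_1e5_cm2_s = slope / 6 * 1000,
       r_squared = summary(fit)$r.squared, window = window)
}
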