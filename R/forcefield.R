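# Coarse-grained chemical model: bead species, the Flory-Huggins-like
# interaction matrix driving the density-functional forces, molecular
# topologies, and optional partial charges on the amphiphile tail.

#' Bead species specification
#'
#' One coarse-grained bead type.  The default model uses five species:
#' `A` (adamantyl head, C10H15), `E` (one ethylene-glycol repeat of the
#' TEG tail), `T` (terminal hydroxyl), `C` (one cyclohexane molecule)
#' and `W` (a four-water bead).
#'
#' @param name single-character species label.
#' @param mass bead mass in amu; must be positive.
#' @param charge default partial charge in elementary charges.
#' @param mapping_note free-text description of the atoms represented.
#' @return an object of class `bead_spec`.
#' @export
bead_spec <- function(name, mass, charge = 0, mapping_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("bead mass must be a single positive number")
  structure(list(name = name, mass = mass, charge = charge,
                 mapping_note = mapping_note),
            class = "bead_spec")
}

#' Species interaction matrix
#'
#' Square, symmetric matrix of mean-field interaction parameters
#' \eqn{\tilde\chi_{ij}} (kJ/mol) between bead species, together with
#' the compressibility penalty prefactor \eqn{1/\kappa} (kJ/mol) that
#' suppresses deviations of the total density from its reference value.
#'
#' @param species character vector of species labels (matrix order).
#' @param values numeric square matrix of \eqn{\tilde\chi_{ij}} in
#'   kJ/mol, symmetric with zero diagonal.
#' @param kappa_inv compressibility prefactor in kJ/mol, `>= 0`.
#' @return an object of class `chi_matrix`.
#' @export
chi_matrix <- function(species, values, kappa_inv = 5.0) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(species), ncol(values) == length(species))
  dimnames(values) <- list(species, species)
  structure(list(species = species, values = values, kappa_inv = kappa_inv),
            class = "chi_matrix")
}

#' Molecule topology
#'
#' Ordered bead sequence with harmonic bonds.  The default amphiphile
#' (`ADOH`) is the linear chain A-E-E-E-T with four bonds.
#'
#' @param name molecule name.
#' @param beads character vector of species labels, chain order.
#' @param bonds integer matrix (n_bonds x 2) of 1-based bead indices.
#' @param kb per-bond force constants, kJ/mol/nm^2 (recycled).
#' @param r0 per-bond equilibrium lengths, nm (recycled).
#' @param charges optional per-bead partial charges (elementary units);
#'   defaults to zero.
#' @param angles optional list with `triples` (n x 3 indices), `ka`
#'   (kJ/mol/rad^2) and `theta0` (rad); unused by the default model.
#' @return an object of class `molecule_topology`.
#' @export
molecule_topology <- function(name, beads, bonds, kb, r0,
                              charges = NULL, angles = NULL) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(beads)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > n))
      stop("bond indices out of bead-sequence range in topology '", name, "'")
    if (any(bonds[, 1] == bonds[, 2]))
      stop("self-bond in topology '", name, "'")
  }
  if (is.null(charges)) charges <- rep(0, n)
  stopifnot(length(charges) == n)
  structure(list(name = name, beads = beads, bonds = bonds,
                 kb = rep_len(kb, nrow(bonds)), r0 = rep_len(r0, nrow(bonds)),
                 charges = charges, angles = angles),
            class = "molecule_topology")
}

#' Assemble a force field
#'
#' @param beads list of [bead_spec()] objects.
#' @param chi a [chi_matrix()].
#' @param topologies named list of [molecule_topology()] objects.
#' @param epsilon_r relative dielectric constant for mesh
#'   electrostatics.
#' @param tail_charges logical; whether tail partial charges are active.
#' @param solvent default solvent species label for system building.
#' @return an object of class `hpf_forcefield`.
#' @export
forcefield <- function(beads, chi, topologies, epsilon_r = 1,
                       tail_charges = FALSE, solvent = "W") {
  names(topologies) <- vapply(topologies, `[[`, "", "name")
  ff <- structure(list(beads = beads, chi = chi, topologies = topologies,
                       epsilon_r = epsilon_r, tail_charges = tail_charges,
                       solvent = solvent),
                  class = "hpf_forcefield")
  ff
}

#' @export
print.hpf_forcefield <- function(x, ...) {
  cat("hPF force field:", length(x$beads), "bead species,",
      length(x$topologies), "topologies\n")
  cat("  species:", paste(vapply(x$beads, `[[`, "", "name"), collapse = " "),
      "\n  kappa_inv:", x$chi$kappa_inv, "kJ/mol",
      "\n  tail charges:", x$tail_charges,
      if (x$tail_charges) paste0(" (epsilon_r = ", x$epsilon_r, ")"), "\n")
  invisible(x)
}

# Default bead masses (amu) from the mapped atoms: adamantyl C10H15,
# one C2H4O repeat, hydroxyl, cyclohexane, four waters.
bead_masses <- c(A = 135.2, E = 44.05, T = 17.01, C = 84.16, W = 72.06)

default_chi_values <- function() {
  sp <- c("A", "E", "T", "C", "W")
  v <- matrix(0, 5, 5, dimnames = list(sp, sp))
  pairs <- list(c("A", "E", 7.8), c("A", "T", 13.25), c("A", "C", 0),
                c("A", "W", 33.75), c("E", "T", 4.5), c("E", "C", 7.8),
                c("E", "W", 1.5), c("T", "C", 13.25), c("T", "W", 0),
                c("C", "W", 0))
  for (p in pairs) {
    v[p[1], p[2]] <- as.numeric(p[3])
    v[p[2], p[1]] <- as.numeric(p[3])
  }
  v
}

#' Default amphiphile force field
#'
#' The coarse-grained parameterization of the studied amphiphile
#' (adamantane head, three TEG repeats, hydroxyl terminal) in either
#' water or cyclohexane.  The interaction matrix (kJ/mol) has
#' \eqn{\tilde\chi(A,W) = 33.75}, \eqn{\tilde\chi(E,W) = 1.5},
#' \eqn{\tilde\chi(T,W) = 0}, \eqn{\tilde\chi(A,C) = 0},
#' \eqn{\tilde\chi(E,C) = 7.8}, \eqn{\tilde\chi(T,C) = 13.25},
#' \eqn{\tilde\chi(A,E) = 7.8}, \eqn{\tilde\chi(A,T) = 13.25} and
#' \eqn{\tilde\chi(E,T) = 4.5}, symmetric with zero diagonal.
#'
#' With `charged_tails` the tail beads carry alternating partial
#' charges (+0.4, -0.4, +0.4, -0.4 e on E1, E2, E3, T; the molecule is
#' neutral) and the relative dielectric constant is set to 5, the
#' configuration used to mimic the weak tail-tail electrostatics in the
#' apolar solvent.
#'
#' @param solvent `"W"` (water, 4:1 mapped) or `"C"` (cyclohexane, 1:1).
#' @param charged_tails logical; default `TRUE` for cyclohexane.
#' @param kappa_inv compressibility prefactor, kJ/mol.
#' @param kb,r0_head,r0_tail harmonic bond parameters: force constant
#'   (kJ/mol/nm^2) and equilibrium lengths for the head-tail (A-E) and
#'   intra-tail (E-E, E-T) bonds, nm.
#' @return an `hpf_forcefield`.
#' @examples
#' ff <- default_adoh_forcefield("W")
#' chi_value(ff, "A", "W")  # 33.75
#' @export
default_adoh_forcefield <- function(solvent = "W",
                                    charged_tails = identical(solvent, "C"),
                                    kappa_inv = 5.0, kb = 1250,
                                    r0_head = 0.33, r0_tail = 0.28) {
  if (!solvent %in% c("W", "C"))
    stop("unknown solvent label '", solvent, "': expected \"W\" or \"C\"")
  beads <- lapply(names(bead_masses), function(s)
    bead_spec(s, bead_masses[[s]],
              mapping_note = c(A = "adamantyl C10H15", E = "TEG repeat C2H4O",
                               T = "terminal OH", C = "cyclohexane C6H12",
                               W = "four H2O")[[s]]))
  chi <- chi_matrix(c("A", "E", "T", "C", "W"), default_chi_values(),
                    kappa_inv = kappa_inv)
  q <- if (charged_tails) c(0, 0.4, -0.4, 0.4, -0.4) else rep(0, 5)
  adoh <- molecule_topology("ADOH", c("A", "E", "E", "E", "T"),
                            bonds = cbind(1:4, 2:5), kb = kb,
                            r0 = c(r0_head, r0_tail, r0_tail, r0_tail),
                            charges = q)
  topo <- list(adoh,
               molecule_topology("W", "W", matrix(integer(0), 0, 2),
                                 numeric(0), numeric(0)),
               molecule_topology("C", "C", matrix(integer(0), 0, 2),
                                 numeric(0), numeric(0)))
  forcefield(beads, chi, topo,
             epsilon_r = if (charged_tails) 5 else 1,
             tail_charges = charged_tails, solvent = solvent)
}

#' Look up an interaction parameter
#'
#' @param ff an `hpf_forcefield`.
#' @param i,j species labels.
#' @return \eqn{\tilde\chi_{ij}} in kJ/mol.
#' @export
chi_value <- function(ff, i, j) ff$chi$values[i, j]

#' Validate a force field
#'
#' Checks every structural invariant and returns the violations as a
#' character vector (empty when the force field is valid): unique bead
#' names with positive masses, a symmetric interaction matrix with zero
#' diagonal and nonnegative compressibility prefactor, bond indices in
#' range, topologies referring only to declared species, and (when tail
#' charges are active) zero net charge per molecule.
#'
#' @param ff an `hpf_forcefield`.
#' @return character vector of violation messages.
#' @examples
#' validate_forcefield(default_adoh_forcefield("W"))  # character(0)
#' @export
validate_forcefield <- function(ff) {
  out <- character(0)
  nm <- vapply(ff$beads, `[[`, "", "name")
  if (anyDuplicated(nm)) out <- c(out, "duplicate bead species names")
  if (any(vapply(ff$beads, `[[`, 0, "mass") <= 0))
    out <- c(out, "nonpositive bead mass")
  v <- ff$chi$values
  sp <- ff$chi$species
  for (a in seq_along(sp))
    for (b in seq_len(a - 1))
      if (v[a, b] != v[b, a])
        out <- c(out, sprintf("asymmetric pair (%s,%s)", sp[b], sp[a]))
  if (any(diag(v) != 0)) out <- c(out, "nonzero chi diagonal")
  if (ff$chi$kappa_inv < 0) out <- c(out, "negative kappa_inv")
  for (tp in ff$topologies) {
    if (!all(tp$beads %in% nm))
      out <- c(out, sprintf("topology '%s' uses undeclared species", tp$name))
    if (nrow(tp$bonds) > 0 &&
        (any(tp$bonds < 1) || any(tp$bonds > length(tp$beads))))
      out <- c(out, sprintf("topology '%s' has out-of-range bonds", tp$name))
    if (ff$tail_charges && abs(sum(tp$charges)) > 1e-12)
      out <- c(out, "nonzero molecular charge")
  }
  out
}

num_fmt <- function(x) sprintf("%.17g", x)

#' Write a force field to a key-value text file
#'
#' Human-readable serialization (species, interaction matrix, topology
#' and option blocks).  [read_forcefield()] round-trips every
#' \eqn{\tilde\chi} value bit-exactly.
#'
#' @param ff an `hpf_forcefield`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  ln <- c("[beads]")
  for (b in ff$beads)
    ln <- c(ln, sprintf("%s mass=%s charge=%s note=%s", b$name,
                        num_fmt(b$mass), num_fmt(b$charge),
                        gsub(" ", "_", b$mapping_note)))
  ln <- c(ln, "[chi]",
          paste("species", paste(ff$chi$species, collapse = " ")),
          paste("kappa_inv", num_fmt(ff$chi$kappa_inv)))
  sp <- ff$chi$species
  for (a in seq_along(sp))
    for (b in seq_len(length(sp))[-seq_len(a)])
      ln <- c(ln, paste(sp[a], sp[b], num_fmt(ff$chi$values[a, b])))
  for (tp in ff$topologies) {
    ln <- c(ln, sprintf("[topology %s]", tp$name),
            paste("beads", paste(tp$beads, collapse = " ")),
            paste("charges", paste(num_fmt(tp$charges), collapse = " ")))
    for (k in seq_len(nrow(tp$bonds)))
      ln <- c(ln, paste("bond", tp$bonds[k, 1], tp$bonds[k, 2],
                        num_fmt(tp$kb[k]), num_fmt(tp$r0[k])))
  }
  ln <- c(ln, "[options]",
          paste("epsilon_r", num_fmt(ff$epsilon_r)),
          paste("tail_charges", if (ff$tail_charges) "true" else "false"),
          paste("solvent", ff$solvent))
  writeLines(ln, path)
  invisible(path)
}

#' Read a force field from a key-value text file
#'
#' @param path file written by [write_forcefield()].
#' @return an `hpf_forcefield`.
#' @export
read_forcefield <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  section <- ""
  beads <- list(); chi_sp <- NULL; kappa_inv <- 0; chi_pairs <- list()
  topo <- list(); cur <- NULL
  eps <- 1; tq <- FALSE; solv <- "W"
  flush_topo <- function() {
    if (!is.null(cur)) {
      b <- do.call(rbind, cur$bond_rows)
      topo[[length(topo) + 1L]] <<- molecule_topology(
        cur$name, cur$beads,
        if (is.null(b)) matrix(integer(0), 0, 2) else b[, 1:2, drop = FALSE],
        if (is.null(b)) numeric(0) else b[, 3],
        if (is.null(b)) numeric(0) else b[, 4],
        charges = cur$charges)
    }
    cur <<- NULL
  }
  for (l in ln) {
    if (startsWith(l, "[")) {
      flush_topo()
      inner <- gsub("\\[|\\]", "", l)
      if (startsWith(inner, "topology")) {
        section <- "topology"
        cur <- list(name = strsplit(inner, "\\s+")[[1]][2],
                    beads = character(0), charges = NULL, bond_rows = list())
      } else section <- inner
      next
    }
    tok <- strsplit(l, "\\s+")[[1]]
    if (section == "beads") {
      kv <- sub("^[^=]*=", "", tok[-1])
      beads[[length(beads) + 1L]] <-
        bead_spec(tok[1], as.numeric(kv[1]), as.numeric(kv[2]),
                  gsub("_", " ", kv[3]))
    } else if (section == "chi") {
      if (tok[1] == "species") chi_sp <- tok[-1]
      else if (tok[1] == "kappa_inv") kappa_inv <- as.numeric(tok[2])
      else chi_pairs[[length(chi_pairs) + 1L]] <- tok
    } else if (section == "topology") {
      if (tok[1] == "beads") cur$beads <- tok[-1]
      else if (tok[1] == "charges") cur$charges <- as.numeric(tok[-1])
      else if (tok[1] == "bond")
        cur$bond_rows[[length(cur$bond_rows) + 1L]] <- as.numeric(tok[-1])
    } else if (section == "options") {
      if (tok[1] == "epsilon_r") eps <- as.numeric(tok[2])
      else if (tok[1] == "tail_charges") tq <- identical(tok[2], "true")
      else if (tok[1] == "solvent") solv <- tok[2]
    }
  }
  flush_topo()
  v <- matrix(0, length(chi_sp), length(chi_sp),
              dimnames = list(chi_sp, chi_sp))
  for (p in chi_pairs) {
    v[p[1], p[2]] <- as.numeric(p[3])
    v[p[2], p[1]] <- as.numeric(p[3])
  }
  forcefield(beads, chi_matrix(chi_sp, v, kappa_inv), topo,
             epsilon_r = eps, tail_charges = tq, solvent = solv)
}
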