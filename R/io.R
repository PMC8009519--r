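# Readers/writers for the standard interchange formats: GRO for single
# configurations (fixed width, nm, optional velocities) and multi-frame
# XYZ for lightweight trajectories, plus JSON run manifests.

#' Write a configuration in GRO format
#'
#' Fixed-width GRO: title, atom count, one line per atom (residue
#' number/name, atom name, atom number, position in nm to 3 decimals,
#' velocity in nm/ps to 4 decimals), and the box vector line.
#' Molecules map to residues.
#'
#' @param state a [system_state()].
#' @param path output path.
#' @param title title line text.
#' @return `path`, invisibly.
#' @export
write_gro <- function(state, path, title = NULL) {
  n <- nrow(state$positions)
  if (is.null(title))
    title <- sprintf("hpfmd configuration, t= %g ps", state$time)
  lines <- c(title, sprintf("%5d", n))
  atom_in_mol <- stats::ave(seq_len(n), state$molecule_id,
                            FUN = seq_along)
  lines <- c(lines, sprintf(
    "%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
    state$molecule_id %% 100000L, substr(state$molecule_name, 1, 5),
    substr(paste0(state$species, atom_in_mol), 1, 5),
    seq_len(n) %% 100000L,
    state$positions[, 1], state$positions[, 2], state$positions[, 3],
    state$velocities[, 1], state$velocities[, 2], state$velocities[, 3]))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", state$box_edge,
                            state$box_edge, state$box_edge))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO configuration
#'
#' @param path GRO file with title, count, fixed-width atom lines and a
#'   box line.  Malformed lines are rejected with their line number.
#' @return a [system_state()].
#' @export
read_gro <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3) stop("GRO file too short: missing box line")
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n)) stop("malformed atom count at line 2")
  if (length(ln) < n + 3)
    stop("GRO file truncated: expected ", n + 3, " lines, found ",
         length(ln), " (missing box line?)")
  atoms <- ln[3:(n + 2)]
  parse_field <- function(txt, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(txt, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", what, " at line ", lineno[bad[1]])
    v
  }
  lineno <- 3:(n + 2)
  resid <- parse_field(atoms, 1, 5, "residue number", lineno)
  resname <- trimws(substr(atoms, 6, 10))
  atomname <- trimws(substr(atoms, 11, 15))
  pos <- cbind(parse_field(atoms, 21, 28, "x coordinate", lineno),
               parse_field(atoms, 29, 36, "y coordinate", lineno),
               parse_field(atoms, 37, 44, "z coordinate", lineno))
  has_vel <- all(nchar(atoms) >= 68)
  vel <- if (has_vel)
    cbind(parse_field(atoms, 45, 52, "x velocity", lineno),
          parse_field(atoms, 53, 60, "y velocity", lineno),
          parse_field(atoms, 61, 68, "z velocity", lineno))
  else matrix(0, n, 3)
  box <- suppressWarnings(as.numeric(strsplit(trimws(ln[n + 3]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box))
    stop("malformed box line at line ", n + 3)
  # renumber residues sequentially (GRO residue ids wrap at 99999)
  mol_id <- cumsum(c(1L, diff(resid) != 0))
  tm <- regmatches(ln[1], regexpr("t= *[-0-9.eE+]+", ln[1]))
  time <- if (length(tm)) as.numeric(sub("t= *", "", tm)) else 0
  system_state(box[1], pos, vel, species = gsub("[0-9]+$", "", atomname),
               molecule_id = mol_id, molecule_name = resname, time = time)
}

#' Write a trajectory in multi-frame XYZ
#'
#' Each frame: atom count, a comment line carrying the time stamp, box
#' edge and length unit, then `name x y z` records.  Coordinates are
#' the unwrapped ones (so displacement analyses round-trip).
#'
#' @param traj an [hpf_trajectory()].
#' @param path output path.
#' @param angstrom write coordinates in Angstrom instead of the default
#'   nm (the unit is recorded in the comment line either way).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, angstrom = FALSE) {
  scale <- if (angstrom) 10 else 1
  unit <- if (angstrom) "angstrom" else "nm"
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$frames[[1]])
  for (i in seq_along(traj$frames)) {
    x <- traj$frames[[i]] * scale
    writeLines(c(sprintf("%d", n),
                 sprintf("t= %.6f ps box= %.6f unit= %s", traj$times[i],
                         traj$box_edge * scale, unit),
                 sprintf("%-4s %14.6f %14.6f %14.6f", traj$species,
                         x[, 1], x[, 2], x[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file written by [write_xyz_trajectory()] (or any XYZ
#'   whose comment line carries `box=`; otherwise supply `box_edge`).
#' @param box_edge box edge in nm, if not recorded in the file.
#' @return an [hpf_trajectory()]; species come from the atom names,
#'   molecule ids default to one molecule per atom.
#' @export
read_xyz_trajectory <- function(path, box_edge = NULL) {
  ln <- readLines(path)
  if (length(ln) == 0) stop("empty XYZ file")
  i <- 1L
  frames <- list(); times <- numeric(0); species <- NULL
  n0 <- NA_integer_
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n)) stop("malformed atom count at line ", i)
    if (is.na(n0)) n0 <- n
    else if (n != n0)
      stop("inconsistent atom counts across frames (", n0, " vs ", n,
           " at line ", i, ")")
    if (i + 1 + n > length(ln)) stop("truncated frame at line ", i)
    comment <- ln[i + 1]
    tm <- regmatches(comment, regexpr("t= *[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm))
               else length(times))
    bx <- regmatches(comment, regexpr("box= *[-0-9.eE+]+", comment))
    un <- regmatches(comment, regexpr("unit= *\\w+", comment))
    scale <- if (length(un) && grepl("angstrom", un)) 0.1 else 1
    if (length(bx) && is.null(box_edge))
      box_edge <- as.numeric(sub("box= *", "", bx)) * scale
    rows <- strsplit(trimws(ln[(i + 2):(i + 1 + n)]), "\\s+")
    if (is.null(species)) species <- vapply(rows, `[[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed coordinates in frame at line ", i)
    frames[[length(frames) + 1L]] <- xyz * scale
    i <- i + 2L + n
  }
  if (is.null(box_edge))
    stop("box edge not found in file; supply box_edge=")
  hpf_trajectory(box_edge, species, seq_len(n0), species, times, frames)
}

#' Run manifest
#'
#' Provenance record emitted alongside every engine or analysis
#' output: configuration snapshot, seed, package version, input/output
#' file digests and a timestamp.
#'
#' @param config named list (configuration snapshot).
#' @param seed integer seed used.
#' @param inputs,outputs character vectors of file paths to digest.
#' @return named list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character(0),
                         outputs = character(0)) {
  digest <- function(p) {
    ex <- file.exists(p)
    d <- rep(NA_character_, length(p))
    d[ex] <- unname(tools::md5sum(p[ex]))
    stats::setNames(as.list(d), p)
  }
  structure(list(
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("hpfmd")),
    inputs = digest(inputs), outputs = digest(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
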