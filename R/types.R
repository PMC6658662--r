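#' @keywords internal
"_PACKAGE"

# Per-element lookup tables used when a topology does not carry explicit
# masses / van der Waals radii. Radii are in nm, masses in atomic mass units.
# Values can be overridden per atom via the topology columns.
.element_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  He = 4.0026, Ne = 20.180, Ar = 39.948, Mg = 24.305, Na = 22.990,
  Cl = 35.45, K = 39.098, Ca = 40.078
)

.element_vdw <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180, S = 0.180,
  He = 0.140, Ne = 0.154, Ar = 0.188, Mg = 0.173, Na = 0.227,
  Cl = 0.175, K = 0.275, Ca = 0.231
)

#' Infer an element symbol from an atom name
#'
#' Monatomic species whose atom name equals their residue name (e.g. helium
#' beads named "HE" in residue "HE") are matched against two-letter element
#' symbols first; otherwise the leading letter of the stripped atom name is
#' used, so "CA", "CB2" and "C17" are all carbon and "OD1"/"OW" oxygen.
#'
#' @param name character vector of atom names.
#' @param resname character vector of residue names (same length), used to
#'   disambiguate monatomic ions/gases.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name, resname = name) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  two <- paste0(substr(stripped, 1, 1), tolower(substr(stripped, 2, 2)))
  mono <- toupper(name) == toupper(resname) & two %in% names(.element_mass) &
    nchar(stripped) == 2
  out <- substr(stripped, 1, 1)
  out[mono] <- two[mono]
  out
}

#' Construct an atom topology table
#'
#' The topology is the per-atom metadata shared by every frame of a
#' trajectory: serial, atom name, residue name/number, chain identifier,
#' element, mass (amu) and van der Waals radius (nm). Element, mass and
#' radius are inferred from the atom name when not supplied; explicit values
#' always win.
#'
#' @param name,resname character vectors of atom and residue names.
#' @param resnum integer vector of residue numbers (positive).
#' @param chain character vector of chain identifiers ("" when unknown).
#' @param serial atom serials; defaults to 1..n. Must be unique.
#' @param element,mass,vdw optional per-atom overrides.
#' @return a `topology` data.frame.
#' @export
topology <- function(name, resname, resnum, chain = "",
                     serial = seq_along(name), element = NULL,
                     mass = NULL, vdw = NULL) {
  n <- length(name)
  resname <- rep_len(as.character(resname), n)
  resnum <- rep_len(as.integer(resnum), n)
  chain <- rep_len(as.character(chain), n)
  if (!is.null(mass)) mass <- rep_len(mass, n)
  if (!is.null(vdw)) vdw <- rep_len(vdw, n)
  if (!is.null(element)) element <- rep_len(element, n)
  serial <- as.integer(serial)
  if (anyDuplicated(serial)) stop("topology: atom serials must be unique")
  if (any(resnum < 1)) stop("topology: residue numbers must be positive")
  if (is.null(element)) element <- guess_element(name, resname)
  unknown <- !(element %in% names(.element_mass))
  if (any(unknown) && (is.null(mass) || is.null(vdw))) {
    warning("topology: element(s) ", paste(unique(element[unknown]), collapse = ", "),
            " not in the bundled table; using carbon-like mass/vdW defaults")
  }
  if (is.null(mass)) {
    mass <- unname(.element_mass[element])
    mass[unknown] <- 12.011
  }
  if (is.null(vdw)) {
    vdw <- unname(.element_vdw[element])
    vdw[unknown] <- 0.17
  }
  if (any(mass <= 0)) stop("topology: masses must be > 0")
  if (any(vdw <= 0)) stop("topology: vdW radii must be > 0")
  out <- data.frame(
    serial = serial, name = as.character(name),
    resname = as.character(resname), resnum = as.integer(resnum),
    chain = chain, element = element, mass = mass, vdw = vdw,
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology", "data.frame")
  out
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chains [%s]\n",
              nrow(x), length(unique(paste(x$chain, x$resnum))),
              paste(sort(unique(x$chain)), collapse = " ")))
  invisible(x)
}

#' Construct a single trajectory frame
#'
#' @param xyz numeric n x 3 matrix of coordinates in nm.
#' @param box numeric length-3 rectangular box edge lengths in nm.
#' @param time frame time in ps.
#' @return an `md_frame`.
#' @export
md_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("md_frame: xyz must be an n x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) {
    stop("md_frame: box must be three positive edge lengths (rectangular cell)")
  }
  structure(list(time = as.numeric(time), xyz = unname(xyz), box = box),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' An ordered sequence of frames sharing one topology. Frame times must be
#' strictly increasing and every frame must carry exactly one coordinate row
#' per topology atom.
#'
#' @param topology a [topology()] table.
#' @param frames list of [md_frame()] objects.
#' @return an `md_trajectory`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1)
  n <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "md_frame")) stop("trajectory: frames must be md_frame objects")
    if (nrow(f$xyz) != n) {
      stop(sprintf("trajectory: frame %d has %d atoms, topology has %d",
                   i, nrow(f$xyz), n))
    }
  }
  tt <- vapply(frames, `[[`, numeric(1), "time")
  if (length(tt) > 1 && any(diff(tt) <= 0)) {
    stop("trajectory: frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  tt <- frame_times(x)
  cat(sprintf("md_trajectory: %d atoms x %d frames, t = %g..%g ps, box %s nm\n",
              nrow(x$topology), length(x$frames), min(tt), max(tt),
              paste(signif(x$frames[[1]]$box, 4), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times (ps) of a trajectory
#' @param traj an `md_trajectory`.
#' @export
frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Restrict a trajectory to frames whose time lies in a closed interval
#'
#' @param traj an `md_trajectory`.
#' @param t_min,t_max interval bounds in ps (inclusive).
#' @export
subset_frames <- function(traj, t_min = -Inf, t_max = Inf) {
  tt <- frame_times(traj)
  keep <- tt >= t_min & tt <= t_max
  if (!any(keep)) stop("subset_frames: no frames in requested time window")
  trajectory(traj$topology, traj$frames[keep])
}

#' Construct an index group
#'
#' A named, ordered list of 1-based atom serials, the in-memory form of a
#' GROMACS NDX group. Serials are kept in the given order and must not repeat.
#'
#' @param name group name.
#' @param serials integer vector of atom serials (1-based).
#' @export
index_group <- function(name, serials) {
  serials <- as.integer(serials)
  if (anyNA(serials) || any(serials < 1)) {
    stop("index_group: serials must be positive integers")
  }
  if (anyDuplicated(serials)) stop("index_group: duplicate serials in group '", name, "'")
  structure(list(name = as.character(name), serials = serials),
            class = "index_group")
}

#' @export
print.index_group <- function(x, ...) {
  cat(sprintf("index_group '%s': %d atoms\n", x$name, length(x$serials)))
  invisible(x)
}

# Resolve an index group against a topology, returning 0-free row indices.
# Errors if any serial is absent from the topology.
.resolve_group <- function(group, topology) {
  if (inherits(group, "index_group")) serials <- group$serials
  else serials <- as.integer(group)
  idx <- match(serials, topology$serial)
  if (anyNA(idx)) {
    stop(sprintf("selection error: %d serial(s) not present in topology (first: %d)",
                 sum(is.na(idx)), serials[which(is.na(idx))[1]]))
  }
  idx
}

#' Construct a molecule map
#'
#' Assigns every atom to a molecule and records the intramolecular bond list
#' used by [make_whole()]. Each molecule's bond graph must be connected;
#' single-atom molecules need no bonds.
#'
#' @param molecule integer vector, molecule id per atom.
#' @param bonds two-column integer matrix of bonded atom indices (1-based
#'   topology rows). Both ends of a bond must belong to the same molecule.
#' @export
molecule_map <- function(molecule, bonds = matrix(integer(0), ncol = 2)) {
  molecule <- as.integer(molecule)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    same <- molecule[bonds[, 1]] == molecule[bonds[, 2]]
    if (!all(same)) {
      stop("molecule_map: bond(s) connect atoms of different molecules (first bond row ",
           which(!same)[1], ")")
    }
  }
  structure(list(molecule = molecule, bonds = bonds), class = "molecule_map")
}
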