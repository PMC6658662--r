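# Trajectory / index-group I/O.
#
# Internal unit is nm everywhere; Angstrom appears only at the PDB boundary
# (PDB stores Angstrom, GRO stores nm). Only rectangular boxes are supported:
# GRO box lines with nonzero triclinic components are rejected.

.parse_gro_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-+0-9.eE]+", title))
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("t=\\s*", "", m))
}

.num_or_stop <- function(s, line_no, what) {
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v)) {
    stop(sprintf("GRO parse error at line %d: malformed %s field", line_no, what))
  }
  v
}

#' Read a (multi-frame) GROMACS GRO file
#'
#' Frames are fixed-column GRO records concatenated in one file. Coordinates
#' are returned in nm exactly as stored (3-decimal precision). The box line's
#' first three fields are taken as rectangular edges; any further nonzero
#' (triclinic) components are rejected. Frame times are parsed from a
#' `t=` tag on the title line; when absent, the frame index (0, 1, ...) is
#' used so times are still strictly increasing.
#'
#' @param path file path.
#' @param topology optional [topology()] overriding the one reconstructed
#'   from the file (GRO stores no chain, element, mass or radius; the
#'   reconstructed topology infers element/mass/vdW from atom names and
#'   leaves chains empty).
#' @return an [trajectory()].
#' @export
read_gro <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("read_gro: file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  n_atoms_ref <- NA_integer_
  top <- topology
  frame_idx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    title <- lines[pos]
    n_at <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n_at) || n_at < 1) {
      stop(sprintf("GRO parse error at line %d: expected atom count", pos + 1L))
    }
    if (is.na(n_atoms_ref)) n_atoms_ref <- n_at
    else if (n_at != n_atoms_ref) {
      stop(sprintf("GRO structural error: frame starting at line %d has %d atoms, previous frames %d",
                   pos, n_at, n_atoms_ref))
    }
    at_lines <- lines[pos + 1L + seq_len(n_at)]
    bad <- which(nchar(at_lines) < 44L)
    if (length(bad)) {
      stop(sprintf("GRO parse error at line %d: atom record shorter than 44 columns",
                   pos + 1L + bad[1]))
    }
    ln0 <- pos + 1L
    x <- .num_or_stop(substr(at_lines, 21, 28), ln0 + 1L, "x")
    y <- .num_or_stop(substr(at_lines, 29, 36), ln0 + 1L, "y")
    z <- .num_or_stop(substr(at_lines, 37, 44), ln0 + 1L, "z")
    box_line <- trimws(lines[pos + 2L + n_at])
    box_fields <- suppressWarnings(as.numeric(strsplit(box_line, "\\s+")[[1]]))
    if (length(box_fields) < 3 || anyNA(box_fields[1:3])) {
      stop(sprintf("GRO parse error at line %d: malformed box line", pos + 2L + n_at))
    }
    if (length(box_fields) > 3 && any(abs(box_fields[-(1:3)]) > 1e-9)) {
      stop("read_gro: triclinic boxes are not supported (nonzero off-diagonal box fields)")
    }
    if (is.null(top)) {
      top <- topology(
        name = trimws(substr(at_lines, 11, 15)),
        resname = trimws(substr(at_lines, 6, 10)),
        resnum = as.integer(trimws(substr(at_lines, 1, 5))),
        serial = seq_len(n_at)
      )
    }
    tm <- .parse_gro_time(title)
    if (is.na(tm)) tm <- as.numeric(frame_idx)
    frames[[length(frames) + 1L]] <- md_frame(cbind(x, y, z), box_fields[1:3], tm)
    pos <- pos + 3L + n_at
    frame_idx <- frame_idx + 1L
  }
  if (length(frames) == 0) stop("read_gro: no frames in ", path)
  trajectory(top, frames)
}

#' Write a trajectory (or single frame) as a multi-frame GRO file
#'
#' @param traj an `md_trajectory` or a single `md_frame` (with `topology`).
#' @param path output path.
#' @param topology required when `traj` is a bare frame.
#' @export
write_gro <- function(traj, path, topology = NULL) {
  if (inherits(traj, "md_frame")) {
    stopifnot(!is.null(topology))
    traj <- trajectory(topology, list(traj))
  }
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("system t= %.5f", f$time), con)
    writeLines(sprintf("%5d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resnum %% 100000L, substr(top$resname, 1, 5),
                       substr(top$name, 1, 5), top$serial %% 100000L,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}

#' Read a GROMACS NDX index file
#'
#' Bracketed group names followed by whitespace-separated 1-based serials.
#' Groups are returned in file order; an empty group body is accepted with a
#' warning. Serials are validated against a topology only at resolution time
#' (see [select_atoms()] / internal resolution), not here.
#'
#' @param path file path.
#' @return a named list of [index_group()]s (names = group names).
#' @export
read_ndx <- function(path) {
  if (!file.exists(path)) stop("read_ndx: file not found: ", path)
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  hdr <- grepl("^\\s*\\[.*\\]\\s*$", lines)
  if (!any(hdr)) stop("read_ndx: no [ group ] headers found in ", path)
  starts <- which(hdr)
  ends <- c(starts[-1] - 1L, length(lines))
  groups <- list()
  for (k in seq_along(starts)) {
    nm <- trimws(gsub("\\[|\\]", "", lines[starts[k]]))
    body <- lines[(starts[k] + 1L):ends[k]]
    if (starts[k] + 1L > ends[k]) body <- character(0)
    toks <- unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+"))
    toks <- toks[nzchar(toks)]
    serials <- suppressWarnings(as.integer(toks))
    if (anyNA(serials)) stop("read_ndx: non-integer serial in group '", nm, "'")
    if (length(serials) == 0) {
      warning("read_ndx: group '", nm, "' is empty")
      groups[[nm]] <- structure(list(name = nm, serials = integer(0)),
                                class = "index_group")
    } else {
      groups[[nm]] <- index_group(nm, serials)
    }
  }
  groups
}

#' Write index groups as a GROMACS NDX file
#'
#' @param groups a list of [index_group()]s (or a single one).
#' @param path output path.
#' @export
write_ndx <- function(groups, path) {
  if (inherits(groups, "index_group")) groups <- list(groups)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in groups) {
    writeLines(sprintf("[ %s ]", g$name), con)
    s <- g$serials
    if (length(s)) {
      rows <- split(s, ceiling(seq_along(s) / 15))
      writeLines(vapply(rows, function(r) paste(sprintf("%d", r), collapse = " "),
                        character(1)), con)
    }
  }
  invisible(path)
}

#' Select atoms from a topology
#'
#' Conjunction of equality filters over atom name, residue name, residue
#' number and chain, optionally followed by a stride over the matches (every
#' `stride`-th matching atom, starting at the first match). The selection is
#' deterministic, order-preserving (topology order) and depends only on the
#' topology, never on coordinates. An empty result is an error, not a silent
#' empty group.
#'
#' @param topology a [topology()].
#' @param name,resname,chain optional character filters (vectors allowed;
#'   matching is `%in%`).
#' @param resnum optional integer filter.
#' @param stride optional positive integer stride over matches.
#' @param group_name name of the returned group (default auto-generated).
#' @return an [index_group()].
#' @export
select_atoms <- function(topology, name = NULL, resname = NULL, resnum = NULL,
                         chain = NULL, stride = NULL, group_name = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(name)) keep <- keep & topology$name %in% name
  if (!is.null(resname)) keep <- keep & topology$resname %in% resname
  if (!is.null(resnum)) keep <- keep & topology$resnum %in% resnum
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  idx <- which(keep)
  if (!is.null(stride)) {
    stopifnot(stride >= 1)
    idx <- idx[seq(1L, length(idx), by = as.integer(stride))]
  }
  if (length(idx) == 0) {
    stop("empty selection: no atoms match (name=", paste(name, collapse = ","),
         " resname=", paste(resname, collapse = ","),
         " resnum=", paste(resnum, collapse = ","),
         " chain=", paste(chain, collapse = ","), ")")
  }
  if (is.null(group_name)) {
    group_name <- paste(c(name, resname, resnum, chain,
                          if (!is.null(stride)) paste0("every", stride)),
                        collapse = "_")
  }
  index_group(group_name, topology$serial[idx])
}

#' Write one frame as a PDB file
#'
#' Coordinates are converted nm -> Angstrom. Chain identifiers are preserved.
#' Serials above PDB's 99999 (and residue numbers above 9999) are wrapped
#' modulo the field width, the conventional fallback for oversized systems;
#' residue names are truncated to the format's 3-character field.
#'
#' @param frame an `md_frame`.
#' @param topology matching [topology()].
#' @param path output path.
#' @export
write_pdb <- function(frame, topology, path) {
  stopifnot(inherits(frame, "md_frame"), nrow(frame$xyz) == nrow(topology))
  ch <- topology$chain
  ch[!nzchar(ch)] <- NA_character_
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(frame$xyz * 10)),
    resno = ((topology$resnum - 1L) %% 10000L) + 1L,
    resid = substr(topology$resname, 1, 3),
    eleno = ((topology$serial - 1L) %% 99999L) + 1L,
    elety = topology$name,
    chain = substr(ch, 1, 1),
    elesy = topology$element
  )
  invisible(path)
}

#' Read a PDB file as a single frame plus topology
#'
#' Thin wrapper around [bio3d::read.pdb()] used for fixtures and for
#' re-loading centroid frames; coordinates are converted Angstrom -> nm.
#' PDB carries no box, so one must be supplied.
#'
#' @param path file path.
#' @param box rectangular box edges in nm.
#' @return list with elements `frame` and `topology`.
#' @export
read_pdb_frame <- function(path, box) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  ch <- a$chain
  ch[is.na(ch)] <- ""
  top <- topology(name = a$elety, resname = a$resid, resnum = a$resno,
                  chain = ch, serial = seq_len(nrow(a)))
  xyz <- cbind(a$x, a$y, a$z) / 10
  list(frame = md_frame(xyz, box, 0), topology = top)
}
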