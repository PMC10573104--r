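# Core data model: a Structure is an ordered atom table plus one coordinate
# set; a Trajectory is a Structure topology plus an F x N x 3 frame stack.
# Conventions: coordinates in Angstrom throughout; atom indices are 0-free --
# everything user-facing is 1-based, matching R.

#' Construct a Structure
#'
#' An ordered atom table with one set of coordinates. Residues are implicit:
#' consecutive rows sharing `(chain, resid, resname)` form a residue, in file
#' order.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`, `chain`,
#'   and optionally `element`, `mass`, `charge`, `atype`. Missing elements are
#'   inferred from atom names, missing masses from elements.
#' @param xyz numeric N x 3 matrix, Angstrom.
#' @param title free-text title.
#' @return object of class `csg_structure` with components `atoms`, `xyz`,
#'   `title`.
#' @export
structure_model <- function(atoms, xyz, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "resname", "resid", "chain")
  if (!all(req %in% names(atoms))) {
    stop("atoms table must have columns: ", paste(req, collapse = ", "))
  }
  atoms$name <- trimws(as.character(atoms$name))
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element)) {
    atoms$element <- element_from_name(atoms$name, atoms$resname)
  }
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$atype)) atoms$atype <- NA_character_
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atoms)) {
    stop("xyz must be a numeric N x 3 matrix matching the atom table")
  }
  dimnames(xyz) <- NULL
  s <- base::structure(
    list(atoms = atoms, xyz = xyz, title = as.character(title)[1L]),
    class = "csg_structure"
  )
  validate_structure(s)
  s
}

#' Validate Structure invariants
#'
#' Checks that every `(chain, resid, name)` triple is unique, that masses are
#' positive, and that elements are consistent with atom names.
#'
#' @param s a `csg_structure`.
#' @return `s`, invisibly; errors on violation.
#' @export
validate_structure <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resid, a$name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- a[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate atom: chain ", d$chain, " resid ", d$resid, " name ", d$name)
  }
  if (any(!is.finite(a$mass)) || any(a$mass <= 0)) stop("non-positive atomic mass")
  if (nrow(a) == 0L) stop("empty structure")
  invisible(s)
}

#' @export
print.csg_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resid")]))
  cat("<csg_structure> ", nrow(a), " atoms, ", nres, " residues",
      if (nzchar(x$title)) paste0(' "', x$title, '"'), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory
#' @param x a `csg_structure` or `csg_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "csg_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Construct a Trajectory
#'
#' @param topology a `csg_structure` providing atom identities (its own `xyz`
#'   is frame 1 by convention but is not used by analyses).
#' @param frames numeric F x N x 3 array of coordinates, Angstrom.
#' @param frame_interval optional time between frames, ps.
#' @return object of class `csg_trajectory`.
#' @export
trajectory <- function(topology, frames, frame_interval = NULL) {
  stopifnot(inherits(topology, "csg_structure"))
  if (is.matrix(frames)) frames <- array(frames, c(1L, nrow(frames), 3L))
  if (length(dim(frames)) != 3L || dim(frames)[3L] != 3L) {
    stop("frames must be an F x N x 3 array")
  }
  if (dim(frames)[2L] != n_atoms(topology)) {
    stop("frame atom count (", dim(frames)[2L], ") does not match topology (",
         n_atoms(topology), ")")
  }
  if (dim(frames)[1L] < 1L) stop("trajectory needs at least one frame")
  base::structure(
    list(topology = topology, frames = frames, frame_interval = frame_interval),
    class = "csg_trajectory"
  )
}

#' @export
print.csg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat("<csg_trajectory> ", d[1L], " frames x ", d[2L], " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `csg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1L]

#' Extract one frame of a Trajectory as a Structure
#'
#' @param traj a `csg_trajectory`.
#' @param frame 1-based frame index.
#' @return a `csg_structure` whose coordinates are that frame.
#' @export
get_frame <- function(traj, frame = 1L) {
  stopifnot(inherits(traj, "csg_trajectory"))
  F <- n_frames(traj)
  if (frame < 1L || frame > F) stop("frame out of range 1..", F)
  s <- traj$topology
  s$xyz <- traj$frames[frame, , , drop = TRUE]
  dim(s$xyz) <- c(n_atoms(traj), 3L)
  s
}

#' Coerce a Structure to a single-frame Trajectory
#' @param s a `csg_structure`.
#' @return a `csg_trajectory` with F = 1.
#' @export
as_trajectory <- function(s) {
  if (inherits(s, "csg_trajectory")) return(s)
  trajectory(s, array(s$xyz, c(1L, nrow(s$xyz), 3L)))
}

# Subset a structure to atom indices (keeps order given).
.subset_structure <- function(s, idx) {
  base::structure(
    list(atoms = s$atoms[idx, , drop = FALSE],
         xyz = s$xyz[idx, , drop = FALSE],
         title = s$title),
    class = "csg_structure"
  )
}

# Row indices of a residue identified by (chain, resid).
.residue_indices <- function(s, chain, resid) {
  which(s$atoms$chain == chain & s$atoms$resid == as.integer(resid))
}

# Position of a named atom inside a residue; error if absent.
.atom_index <- function(s, chain, resid, name) {
  i <- which(s$atoms$chain == chain & s$atoms$resid == as.integer(resid) &
               s$atoms$name == name)
  if (length(i) != 1L) {
    stop("atom ", name, " not found in ", chain, ":", resid)
  }
  i
}

#' Remove crystallographic solvent and counter-ions
#'
#' Drops residues whose name is in the solvent/ion set (`WAT`, `HOH`, `NA`,
#' `NA+`, `SOD`, `CL`, `CL-`, `CLA`); everything else is untouched, in order.
#'
#' @param s a `csg_structure` or `csg_trajectory`.
#' @return the stripped object; warns if nothing is left.
#' @export
strip_solvent_ions <- function(s) {
  solvent <- c("WAT", "HOH", "TIP3", "NA", "NA+", "SOD", "CL", "CL-", "CLA")
  if (inherits(s, "csg_trajectory")) {
    keep <- !(s$topology$atoms$resname %in% solvent)
    if (!any(keep)) warning("all residues were solvent/ions; empty result")
    s$topology <- .subset_structure(s$topology, which(keep))
    s$frames <- s$frames[, keep, , drop = FALSE]
    return(s)
  }
  stopifnot(inherits(s, "csg_structure"))
  keep <- which(!(s$atoms$resname %in% solvent))
  if (length(keep) == 0L) {
    warning("all residues were solvent/ions; empty result")
    s$atoms <- s$atoms[keep, , drop = FALSE]
    s$xyz <- s$xyz[keep, , drop = FALSE]
    return(s)
  }
  .subset_structure(s, keep)
}
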