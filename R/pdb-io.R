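# PDB reading/writing. Parsing is delegated to bio3d::read.pdb /
# bio3d::write.pdb; this layer adds the checks and conventions the toolkit
# needs: per-model atom-count validation, occupancy-based altloc resolution,
# element/mass assignment, and multi-model (ensemble) handling.

.std_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "CYX", "GLN", "GLU", "GLY", "HIS",
  "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
  "THR", "TRP", "TYR", "VAL", "CSG"
)

#' Read a PDB file as a Trajectory
#'
#' One frame per `MODEL` block (a single frame if the file has none). Alternate
#' locations are resolved by keeping the highest-occupancy location, ties going
#' to the lexicographically first altloc identifier. Elements come from PDB
#' columns 77-78 when present, otherwise they are inferred from the atom name.
#'
#' @param path PDB file path.
#' @return a `csg_trajectory` (use [get_frame()] for a single Structure).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # model bookkeeping on the raw lines: consistent atom counts, parseable
  # coordinate fields (with line numbers, which bio3d does not report)
  model_id <- cumsum(rec == "MODEL ")
  if (any(model_id > 0L)) {
    counts <- table(model_id[is_atom & model_id > 0L])
    if (length(unique(as.integer(counts))) > 1L) {
      bad <- names(counts)[which(as.integer(counts) != as.integer(counts)[1L])[1L]]
      stop("inconsistent atom count across models: MODEL ", bad,
           " has ", counts[[bad]], " atoms, MODEL ", names(counts)[1L],
           " has ", counts[[1L]])
    }
  }
  coord_txt <- substr(lines[is_atom], 31L, 54L)
  xf <- suppressWarnings(cbind(
    as.numeric(substr(coord_txt, 1L, 8L)),
    as.numeric(substr(coord_txt, 9L, 16L)),
    as.numeric(substr(coord_txt, 17L, 24L))
  ))
  if (anyNA(xf)) {
    bad_line <- which(is_atom)[which(rowSums(is.na(xf)) > 0L)[1L]]
    stop("unparseable coordinate field at line ", bad_line, " of ", path)
  }

  p <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE,
                       hex = TRUE)
  a <- p$atom
  nmodel <- nrow(p$xyz)

  # altloc resolution: keep max occupancy, tie -> lexicographically first id
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- rep(TRUE, nrow(a))
  has_alt <- which(alt != "")
  if (length(has_alt) > 0L) {
    grp <- paste(a$chain[has_alt], a$resno[has_alt], a$insert[has_alt],
                 a$elety[has_alt], sep = "\r")
    for (g in split(has_alt, grp)) {
      if (length(g) == 1L) next
      best <- g[order(-occ[g], alt[g])][1L]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  ki <- which(keep)

  elem <- a$elesy[ki]
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- element_from_name(a$elety[ki][miss], a$resid[ki][miss])
  elem <- trimws(elem)
  chain <- ifelse(is.na(a$chain[ki]), " ", a$chain[ki])

  atoms <- data.frame(
    name = a$elety[ki], resname = a$resid[ki], resid = a$resno[ki],
    chain = chain, element = elem, mass = element_mass(elem),
    charge = NA_real_, atype = NA_character_, stringsAsFactors = FALSE
  )
  N <- length(ki)
  cols <- as.vector(rbind(3L * ki - 2L, 3L * ki - 1L, 3L * ki))
  frames <- array(NA_real_, c(nmodel, N, 3L))
  for (f in seq_len(nmodel)) {
    frames[f, , ] <- matrix(p$xyz[f, cols], ncol = 3L, byrow = TRUE)
  }
  topo <- structure_model(atoms, frames[1L, , , drop = TRUE],
                          title = basename(path))
  trajectory(topo, frames)
}

#' Write a Structure or Trajectory to a PDB file
#'
#' Multi-frame trajectories are written as `MODEL`/`ENDMDL` blocks. Standard
#' amino-acid residues (including CSG) become `ATOM` records, everything else
#' `HETATM`. Output is deterministic: re-writing a re-read file is byte-stable.
#'
#' @param x a `csg_structure` or `csg_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  traj <- as_trajectory(x)
  if (!all(is.finite(traj$frames))) stop("non-finite coordinates")
  if (any(abs(traj$frames) >= 10000)) {
    stop("coordinate magnitude >= 10000 Angstrom overflows the PDB field")
  }
  a <- traj$topology$atoms
  type <- ifelse(a$resname %in% .std_resnames, "ATOM", "HETATM")
  F <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = F, ncol = 3L * nrow(a))
  for (f in seq_len(F)) xyz[f, ] <- as.vector(t(traj$frames[f, , ]))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz, type = type, resno = a$resid,
    resid = a$resname, eleno = seq_len(nrow(a)), elety = a$name,
    chain = ifelse(a$chain == " ", "", a$chain),
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element, end = TRUE
  )
  invisible(path)
}
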