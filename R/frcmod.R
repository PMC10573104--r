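# AMBER parameter tables (frcmod/dat dialect) and coverage checking: does a
# parameter set contain every bond, angle, and proper dihedral term implied by
# a residue template's bond graph?

# canonical orientation of a type tuple: the lexicographically smaller of the
# forward and reversed hyphen-joined forms (forward = reverse collapse)
.canon_types <- function(types) {
  fw <- paste(types, collapse = "-")
  bw <- paste(rev(types), collapse = "-")
  if (fw <= bw) fw else bw
}

.canon_bond <- function(t1, t2) .canon_types(c(t1, t2))
.canon_angle <- function(t1, t2, t3) .canon_types(c(t1, t2, t3))
.canon_dihedral <- function(t1, t2, t3, t4) .canon_types(c(t1, t2, t3, t4))

#' Construct a parameter set
#'
#' Tables of bonded terms keyed by atom-type tuples, stored canonically
#' (forward and reverse orderings collapse to one key).
#'
#' @param bond data.frame with columns `t1`, `t2` (plus any constants).
#' @param angle data.frame with columns `t1`, `t2`, `t3`.
#' @param dihedral data.frame with columns `t1`..`t4`; type `X` is the
#'   frcmod wildcard.
#' @param improper data.frame with columns `t1`..`t4` (optional).
#' @param nonbonded data.frame with column `type` (optional).
#' @return object of class `csg_params`.
#' @export
parameter_set <- function(bond = NULL, angle = NULL, dihedral = NULL,
                          improper = NULL, nonbonded = NULL) {
  empty2 <- data.frame(t1 = character(), t2 = character(),
                       stringsAsFactors = FALSE)
  empty3 <- cbind(empty2, t3 = character(), stringsAsFactors = FALSE)
  empty4 <- cbind(empty3, t4 = character(), stringsAsFactors = FALSE)
  p <- list(
    bond = if (is.null(bond)) empty2 else bond,
    angle = if (is.null(angle)) empty3 else angle,
    dihedral = if (is.null(dihedral)) empty4 else dihedral,
    improper = if (is.null(improper)) empty4 else improper,
    nonbonded = if (is.null(nonbonded)) data.frame(type = character()) else nonbonded
  )
  row_keys <- function(tab, n) {
    if (nrow(tab) == 0L) return(character(0))
    vapply(seq_len(nrow(tab)), function(i) {
      .canon_types(as.character(unlist(tab[i, paste0("t", seq_len(n))])))
    }, character(1L))
  }
  p$bond_keys <- row_keys(p$bond, 2L)
  p$angle_keys <- row_keys(p$angle, 3L)
  p$dihedral_keys <- row_keys(p$dihedral, 4L)
  class(p) <- "csg_params"
  p
}

# split "CT-CT-S -S " style type fields on "-" with trimming
.split_types <- function(field, n) {
  parts <- trimws(strsplit(field, "-", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts) | seq_along(parts) <= n]
  if (length(parts) != n) return(NULL)
  parts
}

#' Read an AMBER frcmod-style parameter file
#'
#' Parses the `MASS`, `BOND`, `ANGLE`, `DIHE`, `IMPROPER` and `NONBON`
#' sections; only the atom-type tuples are retained (force constants are not
#' needed for coverage checking).
#'
#' @param path frcmod file path.
#' @return a `csg_params`.
#' @export
read_frcmod <- function(path) {
  ln <- readLines(path, warn = FALSE)
  section <- ""
  rows <- list(BOND = list(), ANGLE = list(), DIHE = list(),
               IMPROPER = list(), NONBON = list())
  headers <- c("MASS", "BOND", "ANGLE", "ANGL", "DIHE", "IMPROPER", "IMPR",
               "NONBON", "NONB")
  for (l in ln[-1L]) {  # first line is the title
    key <- toupper(trimws(l))
    if (key %in% headers) {
      section <- switch(key, ANGL = "ANGLE", IMPR = "IMPROPER",
                        NONB = "NONBON", key)
      next
    }
    if (!nzchar(trimws(l)) || section == "" || section == "MASS") next
    n <- switch(section, BOND = 2L, ANGLE = 3L, DIHE = 4L, IMPROPER = 4L,
                NONBON = 1L)
    if (section == "NONBON") {
      t <- strsplit(trimws(l), "\\s+")[[1L]][1L]
      rows$NONBON[[length(rows$NONBON) + 1L]] <- t
      next
    }
    field <- substr(l, 1L, 3L * n - 1L)
    types <- .split_types(field, n)
    if (is.null(types)) next
    rows[[section]][[length(rows[[section]]) + 1L]] <- types
  }
  tab <- function(sec, n) {
    if (length(rows[[sec]]) == 0L) return(NULL)
    m <- do.call(rbind, rows[[sec]])
    d <- as.data.frame(m, stringsAsFactors = FALSE)
    names(d) <- paste0("t", seq_len(n))
    d
  }
  parameter_set(
    bond = tab("BOND", 2L), angle = tab("ANGLE", 3L),
    dihedral = tab("DIHE", 4L), improper = tab("IMPROPER", 4L),
    nonbonded = if (length(rows$NONBON))
      data.frame(type = unlist(rows$NONBON), stringsAsFactors = FALSE) else NULL
  )
}

#' Write a minimal frcmod-style parameter file
#'
#' Writes the type tuples of a parameter set with placeholder constants --
#' enough for coverage bookkeeping and round-trip tests, not for simulation.
#'
#' @param params a `csg_params`.
#' @param path output path.
#' @param title first-line title.
#' @return `path`, invisibly.
#' @export
write_frcmod <- function(params, path, title = "csgkit parameter tuples") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_types <- function(types) paste(sprintf("%-2s", types), collapse = "-")
  writeLines(title, con)
  writeLines("BOND", con)
  if (nrow(params$bond)) {
    writeLines(sprintf("%s  300.0   1.500", apply(params$bond[, 1:2], 1L, fmt_types)), con)
  }
  writeLines("", con)
  writeLines("ANGLE", con)
  if (nrow(params$angle)) {
    writeLines(sprintf("%s   50.0  109.50", apply(params$angle[, 1:3], 1L, fmt_types)), con)
  }
  writeLines("", con)
  writeLines("DIHE", con)
  if (nrow(params$dihedral)) {
    writeLines(sprintf("%s   1    0.000       0.000           2.000",
                       apply(params$dihedral[, 1:4], 1L, fmt_types)), con)
  }
  writeLines("", con)
  invisible(path)
}

# enumerate unique bonded paths from a bond list (pairs of atom names)
.bond_graph_paths <- function(bonds) {
  adj <- list()
  adde <- function(a, b) adj[[a]] <<- union(adj[[a]], b)
  for (k in seq_len(nrow(bonds))) {
    adde(bonds[k, 1L], bonds[k, 2L]); adde(bonds[k, 2L], bonds[k, 1L])
  }
  angles <- list(); dihedrals <- list()
  for (b in names(adj)) {
    nb <- adj[[b]]
    if (length(nb) >= 2L) {
      for (i in seq_len(length(nb) - 1L)) for (j in seq(i + 1L, length(nb))) {
        angles[[length(angles) + 1L]] <- c(nb[i], b, nb[j])
      }
    }
  }
  for (k in seq_len(nrow(bonds))) {
    b <- bonds[k, 1L]; c_ <- bonds[k, 2L]
    for (a in setdiff(adj[[b]], c_)) for (d in setdiff(adj[[c_]], b)) {
      if (a == d) next  # three-membered ring path
      dihedrals[[length(dihedrals) + 1L]] <- c(a, b, c_, d)
    }
  }
  # deduplicate reversed duplicates
  dedup <- function(lst) {
    if (length(lst) == 0L) return(lst)
    keys <- vapply(lst, function(x) {
      r <- rev(x)
      if (paste(x, collapse = "-") <= paste(r, collapse = "-")) {
        paste(x, collapse = "-")
      } else paste(r, collapse = "-")
    }, character(1L))
    lst[!duplicated(keys)]
  }
  list(angles = dedup(angles), dihedrals = dedup(dihedrals))
}

#' Check parameter coverage of a residue template
#'
#' Enumerates every bond, angle (bonded path of length 2) and proper dihedral
#' (path of length 3) in the template's bond graph, maps atoms to their force
#' field types, canonicalizes each type tuple, and looks it up in the
#' parameter set -- dihedrals first exactly, then against the `X-B-C-X`
#' wildcard form. Returns the missing terms; an empty result means the
#' parameter set fully covers the residue.
#'
#' @param tmpl a `csg_template` (see [residue_template()]).
#' @param params a `csg_params`.
#' @return data.frame with columns `term` (`bond`/`angle`/`dihedral`) and
#'   `types` (hyphen-joined canonical tuple); zero rows = full coverage.
#' @export
check_parameter_coverage <- function(tmpl, params) {
  stopifnot(inherits(tmpl, "csg_template"), inherits(params, "csg_params"))
  at <- tmpl$atoms
  if (anyNA(at$atype) || any(!nzchar(at$atype))) {
    stop("template atom(s) without an atom type")
  }
  type_of <- stats::setNames(at$atype, at$name)
  bonds <- as.matrix(tmpl$bonds[, 1:2])
  missing <- list()
  # bonds
  for (k in seq_len(nrow(bonds))) {
    key <- .canon_bond(type_of[[bonds[k, 1L]]], type_of[[bonds[k, 2L]]])
    if (!(key %in% params$bond_keys)) {
      missing[[length(missing) + 1L]] <- c("bond", key)
    }
  }
  paths <- .bond_graph_paths(bonds)
  for (ang in paths$angles) {
    key <- .canon_angle(type_of[[ang[1L]]], type_of[[ang[2L]]],
                        type_of[[ang[3L]]])
    if (!(key %in% params$angle_keys)) {
      missing[[length(missing) + 1L]] <- c("angle", key)
    }
  }
  for (dh in paths$dihedrals) {
    t2 <- type_of[[dh[2L]]]; t3 <- type_of[[dh[3L]]]
    key <- .canon_dihedral(type_of[[dh[1L]]], t2, t3, type_of[[dh[4L]]])
    wkey <- .canon_dihedral("X", t2, t3, "X")
    if (!(key %in% params$dihedral_keys || wkey %in% params$dihedral_keys)) {
      missing[[length(missing) + 1L]] <- c("dihedral", key)
    }
  }
  if (length(missing) == 0L) {
    return(data.frame(term = character(), types = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, missing)
  out <- unique(data.frame(term = m[, 1L], types = m[, 2L],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
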