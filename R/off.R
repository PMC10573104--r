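# Residue templates and their file formats: the AMBER OFF (.lib) residue
# library dialect and TRIPOS mol2.

#' Construct a residue template
#'
#' The full definition of a force-field residue: atom names, types and
#' charges, connectivity, chain-link (head/tail) atoms, optionally ideal
#' coordinates and an internal-coordinate table used for grafting.
#'
#' @param name residue code (e.g. `"CSG"`).
#' @param atoms data.frame with columns `name`, `atype`, `charge`.
#' @param bonds data.frame (or 2-column matrix) of bonded atom-name pairs.
#' @param head chain-link atom on the N side (usually `"N"`).
#' @param tail chain-link atom on the C side (usually `"C"`).
#' @param xyz optional named ideal coordinates (N x 3, rownames = atom names).
#' @param zmatrix optional internal-coordinate table for grafting: columns
#'   `atom`, `ref1`, `ref2`, `ref3`, `bond` (Angstrom), `angle`, `dihedral`
#'   (degrees); each reference must be an anchor atom or a previously defined
#'   row.
#' @return object of class `csg_template`.
#' @export
residue_template <- function(name, atoms, bonds, head = "N", tail = "C",
                             xyz = NULL, zmatrix = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "atype", "charge") %in% names(atoms)))
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in template")
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  names(bonds)[1:2] <- c("a1", "a2")
  unknown <- setdiff(c(bonds$a1, bonds$a2), atoms$name)
  if (length(unknown) > 0L) {
    stop("bond references unknown atom(s): ", paste(unknown, collapse = ", "))
  }
  if (!(head %in% atoms$name) || !(tail %in% atoms$name)) {
    stop("head/tail must be template atoms")
  }
  # connectivity check
  reach <- atoms$name[1L]
  repeat {
    nb <- unique(c(bonds$a2[bonds$a1 %in% reach], bonds$a1[bonds$a2 %in% reach]))
    new <- setdiff(nb, reach)
    if (length(new) == 0L) break
    reach <- c(reach, new)
  }
  if (length(reach) < nrow(atoms)) {
    stop("template bond graph is disconnected (unreached: ",
         paste(setdiff(atoms$name, reach), collapse = ", "), ")")
  }
  if (!is.null(zmatrix)) {
    zmatrix <- as.data.frame(zmatrix, stringsAsFactors = FALSE)
    stopifnot(all(c("atom", "ref1", "ref2", "ref3", "bond", "angle",
                    "dihedral") %in% names(zmatrix)))
    defined <- c("N", "CA", "C", "CB", "SG")  # cysteine anchors
    for (k in seq_len(nrow(zmatrix))) {
      refs <- unlist(zmatrix[k, c("ref1", "ref2", "ref3")])
      if (!all(refs %in% defined)) {
        stop("z-matrix row ", k, " (", zmatrix$atom[k],
             ") references undefined atom(s): ",
             paste(setdiff(refs, defined), collapse = ", "))
      }
      defined <- c(defined, zmatrix$atom[k])
    }
  }
  base::structure(
    list(name = name, atoms = atoms, bonds = bonds[, c("a1", "a2")],
         head = head, tail = tail, xyz = xyz, zmatrix = zmatrix),
    class = "csg_template"
  )
}

#' @export
print.csg_template <- function(x, ...) {
  cat("<csg_template> ", x$name, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, total charge ",
      sprintf("%.4f", sum(x$atoms$charge)), " e\n", sep = "")
  invisible(x)
}

.atomic_number <- function(element) {
  z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, CL = 17,
         BR = 35, I = 53, NA. = 11, K = 19, MG = 12, CA. = 20, ZN = 30,
         FE = 26, SE = 34)
  unname(z[.element_key(element)])
}

#' Write a residue template as an AMBER OFF library file
#'
#' Emits the `.lib` dialect understood by AMBER's leap: the atoms table
#' (name, type, charge), connectivity, unit connect and residueconnect
#' entries naming the head/tail chain-link atoms, residue table and (when
#' available) positions. Output is deterministic: two writes of the same
#' template are byte-identical.
#'
#' @param tmpl a `csg_template`; its charges must sum to an integer (within
#'   1e-6), as force-field residues carry integer charge.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(tmpl, path) {
  stopifnot(inherits(tmpl, "csg_template"))
  total <- sum(tmpl$atoms$charge)
  if (abs(total - round(total)) > 1e-6) {
    stop("template charges sum to ", format(total),
         ", not an integer: refuse to write residue library")
  }
  a <- tmpl$atoms
  n <- nrow(a)
  elem <- element_from_name(a$name)
  seqn <- seq_len(n)
  head_i <- match(tmpl$head, a$name)
  tail_i <- match(tmpl$tail, a$name)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("!!index array str")
  w(' "', tmpl$name, '"')
  w("!entry.", tmpl$name,
    ".unit.atoms table  str name  str type  int typex  int resx  int flags  int seq  int elmnt  dbl chg")
  for (i in seqn) {
    w(sprintf(' "%s" "%s" 0 1 131072 %d %d %.6f', a$name[i], a$atype[i], i,
              .atomic_number(elem[i]), a$charge[i]))
  }
  w("!entry.", tmpl$name,
    ".unit.atomspertinfo table  str pname  str ptype  int ptypex  int pelmnt  dbl pchg")
  for (i in seqn) {
    w(sprintf(' "%s" "%s" 0 -1 0.0', a$name[i], a$atype[i]))
  }
  w("!entry.", tmpl$name, ".unit.boundbox array dbl")
  for (v in c(-1, 0, 0, 0, 0)) w(sprintf(" %.6f", v))
  w("!entry.", tmpl$name, ".unit.childsequence single int")
  w(" 2")
  w("!entry.", tmpl$name, ".unit.connect array int")
  w(sprintf(" %d", head_i))
  w(sprintf(" %d", tail_i))
  w("!entry.", tmpl$name,
    ".unit.connectivity table  int atom1x  int atom2x  int flags")
  b1 <- match(tmpl$bonds$a1, a$name)
  b2 <- match(tmpl$bonds$a2, a$name)
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  ord <- order(b1, b2)
  for (k in ord) w(sprintf(" %d %d 1", b1[k], b2[k]))
  w("!entry.", tmpl$name, ".unit.name single str")
  w(' "', tmpl$name, '"')
  if (!is.null(tmpl$xyz)) {
    w("!entry.", tmpl$name, ".unit.positions table  dbl x  dbl y  dbl z")
    xyz <- tmpl$xyz[a$name, , drop = FALSE]
    for (i in seqn) {
      w(sprintf(" %.6f %.6f %.6f", xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]))
    }
  }
  w("!entry.", tmpl$name,
    ".unit.residueconnect table  int c1x  int c2x  int c3x  int c4x  int c5x  int c6x")
  w(sprintf(" %d %d 0 0 0 0", head_i, tail_i))
  w("!entry.", tmpl$name,
    ".unit.residues table  str name  int seq  int childseq  int startatomx  str restype  int imagingx")
  w(sprintf(' "%s" 1 %d 1 "p" 0', tmpl$name, n + 1L))
  invisible(path)
}

#' Read an AMBER OFF library file back into a residue template
#'
#' Parses the atoms, connectivity, connect/residueconnect and positions
#' entries of a single-unit `.lib` file written by [write_library()] (or by
#' leap, for files following the same layout).
#'
#' @param path `.lib` file path.
#' @return a `csg_template` (without z-matrix, which the format does not
#'   carry).
#' @export
read_library <- function(path) {
  ln <- readLines(path, warn = FALSE)
  idx_line <- which(startsWith(ln, "!!index"))[1L]
  unit <- gsub('"', "", trimws(ln[idx_line + 1L]))
  section <- function(what) {
    tag <- paste0("!entry.", unit, ".unit.", what)
    st <- which(startsWith(ln, tag))
    if (length(st) == 0L) return(character(0))
    en <- st + 1L
    while (en <= length(ln) && !startsWith(ln[en], "!")) en <- en + 1L
    ln[seq(st + 1L, en - 1L)]
  }
  atom_rows <- section("atoms table")
  parse_q <- function(row) {
    qs <- regmatches(row, gregexpr('"[^"]*"', row))[[1L]]
    rest <- strsplit(trimws(gsub('"[^"]*"', "", row)), "\\s+")[[1L]]
    list(strings = gsub('"', "", qs), nums = as.numeric(rest))
  }
  atoms <- do.call(rbind, lapply(atom_rows, function(r) {
    p <- parse_q(r)
    data.frame(name = p$strings[1L], atype = p$strings[2L],
               charge = p$nums[length(p$nums)], stringsAsFactors = FALSE)
  }))
  conn_rows <- section("connectivity table")
  bonds <- do.call(rbind, lapply(conn_rows, function(r) {
    v <- as.integer(strsplit(trimws(r), "\\s+")[[1L]])
    data.frame(a1 = atoms$name[v[1L]], a2 = atoms$name[v[2L]],
               stringsAsFactors = FALSE)
  }))
  connect <- as.integer(trimws(section("connect array")))
  head <- atoms$name[connect[1L]]
  tail <- atoms$name[connect[2L]]
  pos_rows <- section("positions table")
  xyz <- NULL
  if (length(pos_rows) > 0L) {
    xyz <- do.call(rbind, lapply(pos_rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }))
    rownames(xyz) <- atoms$name
  }
  residue_template(unit, atoms, bonds, head = head, tail = tail, xyz = xyz)
}

#' Write a residue template as a TRIPOS mol2 file
#'
#' `@<TRIPOS>ATOM` records carry the template charges (to 1e-4, the format's
#' conventional precision) and `@<TRIPOS>BOND` the bond list.
#'
#' @param tmpl a `csg_template`.
#' @param path output path.
#' @param xyz optional coordinates (defaults to `tmpl$xyz`); required.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(tmpl, path, xyz = tmpl$xyz) {
  stopifnot(inherits(tmpl, "csg_template"))
  if (is.null(xyz)) stop("coordinates required for mol2 output")
  a <- tmpl$atoms
  xyz <- xyz[a$name, , drop = FALSE]
  if (anyNA(xyz)) stop("missing coordinates for some template atoms")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("@<TRIPOS>MOLECULE")
  w(tmpl$name)
  w(sprintf("%5d%6d%6d%6d%6d", nrow(a), nrow(tmpl$bonds), 1L, 0L, 0L))
  w("SMALL")
  w("USER_CHARGES")
  w("")
  w("@<TRIPOS>ATOM")
  elem <- element_from_name(a$name)
  for (i in seq_len(nrow(a))) {
    w(sprintf("%7d %-8s%10.4f%10.4f%10.4f %-8s%3d %-8s%10.4f",
              i, a$name[i], xyz[i, 1L], xyz[i, 2L], xyz[i, 3L],
              a$atype[i], 1L, tmpl$name, a$charge[i]))
  }
  w("@<TRIPOS>BOND")
  b1 <- match(tmpl$bonds$a1, a$name)
  b2 <- match(tmpl$bonds$a2, a$name)
  for (k in seq_len(nrow(tmpl$bonds))) {
    w(sprintf("%6d%6d%6d %s", k, b1[k], b2[k], "1"))
  }
  invisible(path)
}
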