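# The built-in CSG (S-glutathionylated cysteine) residue template.
#
# Atom names follow the glutathione (GSH) chemical-component naming so that
# grafted residues line up with experimental CSG entries: the gamma-glutamate
# arm is N1/CA1/C1/O11/O12/CB1/CG1/CD1/OE1, the glutathione cysteine is
# N2/CA2/C2/O2/CB2/SG2 and the glycine end is N3/CA3/C3/O31/O32; H2 and H4
# are the two amide hydrogens. Geometry is a synthetic ideal-coordinate set
# built from canonical bond lengths/angles (S-S 2.04 Angstrom, C-S-S 104
# degrees, trans amides); it is meant as a starting geometry that relaxes in
# any downstream minimization, and users can substitute their own template.
#
# The charge set is likewise synthetic: ff14SB cysteine backbone charges,
# analogy-based side-chain charges, run through normalize_charges() so the
# residue carries exactly -1 e (deprotonated termini of the glutathione
# moiety: +1 amino, two -1 carboxylates, net -1).

.csg_sidechain_raw <- c(
  CB = -0.0790, HB2 = 0.0880, HB3 = 0.0880, SG = -0.1950,
  SG2 = -0.1950, CB2 = -0.0540, HB22 = 0.0900, HB23 = 0.0900,
  CA2 = 0.0350, HA2 = 0.0850, N2 = -0.4630, H2 = 0.3000,
  C2 = 0.5970, O2 = -0.5680,
  CD1 = 0.5840, OE1 = -0.5400, CG1 = -0.0360, HG12 = 0.0430, HG13 = 0.0430,
  CB1 = -0.0340, HB12 = 0.0410, HB13 = 0.0410, CA1 = 0.0581, HA1 = 0.1141,
  N1 = -0.3821, H11 = 0.2850, H12 = 0.2850, H13 = 0.2850,
  C1 = 0.8031, O11 = -0.8190, O12 = -0.8190,
  N3 = -0.5163, H4 = 0.2936, CA3 = -0.0252, HA31 = 0.0698, HA32 = 0.0698,
  C3 = 0.8057, O31 = -0.8180, O32 = -0.8180
)

.csg_atypes <- c(
  N = "N", H = "H", CA = "CX", HA = "H1", C = "C", O = "O",
  CB = "2C", HB2 = "H1", HB3 = "H1", SG = "S",
  SG2 = "S", CB2 = "2C", HB22 = "H1", HB23 = "H1",
  CA2 = "CX", HA2 = "H1", N2 = "N", H2 = "H", C2 = "C", O2 = "O",
  CD1 = "C", OE1 = "O", CG1 = "2C", HG12 = "HC", HG13 = "HC",
  CB1 = "2C", HB12 = "HC", HB13 = "HC", CA1 = "CX", HA1 = "HP",
  N1 = "N3", H11 = "H", H12 = "H", H13 = "H",
  C1 = "CO", O11 = "O2", O12 = "O2",
  N3 = "N", H4 = "H", CA3 = "CX", HA31 = "H1", HA32 = "H1",
  C3 = "CO", O31 = "O2", O32 = "O2"
)

.csg_bonds <- matrix(c(
  "N", "H",    "N", "CA",   "CA", "HA",  "CA", "CB",  "CA", "C",
  "C", "O",    "CB", "HB2", "CB", "HB3", "CB", "SG",  "SG", "SG2",
  "SG2", "CB2", "CB2", "HB22", "CB2", "HB23", "CB2", "CA2",
  "CA2", "HA2", "CA2", "N2", "CA2", "C2", "C2", "O2", "C2", "N3",
  "N2", "H2", "N2", "CD1", "CD1", "OE1", "CD1", "CG1",
  "CG1", "HG12", "CG1", "HG13", "CG1", "CB1",
  "CB1", "HB12", "CB1", "HB13", "CB1", "CA1",
  "CA1", "HA1", "CA1", "N1", "CA1", "C1",
  "N1", "H11", "N1", "H12", "N1", "H13",
  "C1", "O11", "C1", "O12",
  "N3", "H4", "N3", "CA3", "CA3", "HA31", "CA3", "HA32",
  "CA3", "C3", "C3", "O31", "C3", "O32"
), ncol = 2L, byrow = TRUE)

# Internal-coordinate rows placing the glutathione moiety from the cysteine
# anchors (N, CA, C, CB, SG). bond Angstrom, angle/dihedral degrees. The SG2
# row's dihedral is chi2 (CA-CB-SG-SG2), the CB2 row's is chi_ss
# (CB-SG-SG2-CB2); both are override points for the grafting routine.
.csg_zmatrix_rows <- c(
  "SG2,SG,CB,CA,2.04,104.0,180",
  "CB2,SG2,SG,CB,1.81,104.0,90",
  "CA2,CB2,SG2,SG,1.53,110.5,180",
  "HB22,CB2,SG2,SG,1.09,109.5,60",
  "HB23,CB2,SG2,SG,1.09,109.5,-60",
  "N2,CA2,CB2,SG2,1.45,110.0,60",
  "C2,CA2,CB2,SG2,1.52,111.0,-60",
  "HA2,CA2,CB2,SG2,1.09,108.0,180",
  "N3,C2,CA2,N2,1.33,116.0,150",
  "O2,C2,CA2,N2,1.23,121.0,-30",
  "H4,N3,C2,CA2,1.01,119.0,0",
  "CA3,N3,C2,CA2,1.45,122.0,180",
  "C3,CA3,N3,C2,1.52,111.0,180",
  "HA31,CA3,N3,C2,1.09,109.5,60",
  "HA32,CA3,N3,C2,1.09,109.5,-60",
  "O31,C3,CA3,N3,1.25,117.0,0",
  "O32,C3,CA3,N3,1.25,117.0,180",
  "CD1,N2,CA2,CB2,1.33,122.0,-120",
  "H2,N2,CA2,CB2,1.01,118.0,60",
  "CG1,CD1,N2,CA2,1.51,116.0,180",
  "OE1,CD1,N2,CA2,1.23,123.0,0",
  "CB1,CG1,CD1,N2,1.53,112.0,180",
  "HG12,CG1,CD1,N2,1.09,109.0,60",
  "HG13,CG1,CD1,N2,1.09,109.0,-60",
  "CA1,CB1,CG1,CD1,1.53,112.0,180",
  "HB12,CB1,CG1,CD1,1.09,109.0,60",
  "HB13,CB1,CG1,CD1,1.09,109.0,-60",
  "N1,CA1,CB1,CG1,1.49,110.0,60",
  "C1,CA1,CB1,CG1,1.53,110.0,-60",
  "HA1,CA1,CB1,CG1,1.09,108.0,180",
  "H11,N1,CA1,CB1,1.03,109.5,60",
  "H12,N1,CA1,CB1,1.03,109.5,180",
  "H13,N1,CA1,CB1,1.03,109.5,-60",
  "O11,C1,CA1,N1,1.25,117.0,0",
  "O12,C1,CA1,N1,1.25,117.0,180"
)

.csg_zmatrix <- function() {
  parts <- strsplit(.csg_zmatrix_rows, ",", fixed = TRUE)
  data.frame(
    atom = vapply(parts, `[`, character(1L), 1L),
    ref1 = vapply(parts, `[`, character(1L), 2L),
    ref2 = vapply(parts, `[`, character(1L), 3L),
    ref3 = vapply(parts, `[`, character(1L), 4L),
    bond = as.numeric(vapply(parts, `[`, character(1L), 5L)),
    angle = as.numeric(vapply(parts, `[`, character(1L), 6L)),
    dihedral = as.numeric(vapply(parts, `[`, character(1L), 7L)),
    stringsAsFactors = FALSE
  )
}

# Run a z-matrix given a named coordinate environment; overrides is a named
# numeric vector replacing dihedral values of the named rows.
.apply_zmatrix <- function(pos, zmat, overrides = NULL) {
  for (k in seq_len(nrow(zmat))) {
    phi <- zmat$dihedral[k]
    if (!is.null(overrides) && zmat$atom[k] %in% names(overrides)) {
      phi <- overrides[[zmat$atom[k]]]
    }
    pos[[zmat$atom[k]]] <- .place_atom(
      pos[[zmat$ref1[k]]], pos[[zmat$ref2[k]]], pos[[zmat$ref3[k]]],
      zmat$bond[k], zmat$angle[k], phi
    )
  }
  pos
}

# Ideal cysteine fragment used as the template's own anchor frame.
.ideal_cys_anchor <- function() {
  pos <- list()
  pos$N <- c(0, 0, 0)
  pos$CA <- c(1.458, 0, 0)
  pos$C <- .place_atom(pos$CA, pos$N, pos$N + c(0, 0, 1), 1.52, 111.0, 60)
  pos$O <- .place_atom(pos$C, pos$CA, pos$N, 1.23, 121.0, -45)
  pos$H <- .place_atom(pos$N, pos$CA, pos$C, 1.01, 118.0, 180)
  pos$CB <- .place_atom(pos$CA, pos$C, pos$N, 1.53, 111.0, 122.5)
  pos$HA <- .place_atom(pos$CA, pos$C, pos$N, 1.09, 108.0, -119)
  pos$SG <- .place_atom(pos$CB, pos$CA, pos$N, 1.81, 108.6, -60)
  pos$HB2 <- .place_atom(pos$CB, pos$CA, pos$N, 1.09, 109.5, 60)
  pos$HB3 <- .place_atom(pos$CB, pos$CA, pos$N, 1.09, 109.5, 180)
  pos
}

#' The built-in CSG residue template
#'
#' A complete S-glutathionylated-cysteine residue definition: GSH-style atom
#' names, ff14SB-style atom types, a synthetic charge set normalized to a
#' total charge of -1 e (ff14SB cysteine backbone frozen, residual spread on
#' the side chain), full connectivity, chain-link atoms N/C, ideal-geometry
#' coordinates and the internal-coordinate table used by
#' [graft_glutathione()]. Replaceable by any user template with the same
#' shape.
#'
#' @param chi_ss ideal-geometry S-S dihedral (CB-SG-SG2-CB2), degrees.
#' @param chi2 ideal-geometry CA-CB-SG-SG2 dihedral, degrees.
#' @return a `csg_template`.
#' @examples
#' tmpl <- csg_template()
#' sum(tmpl$atoms$charge)  # -1
#' @export
csg_template <- function(chi_ss = 90, chi2 = 180) {
  sidechain <- names(.csg_sidechain_raw)
  backbone <- c("N", "H", "CA", "HA", "C", "O")
  raw <- c(stats::setNames(rep(0, length(backbone)), backbone),
           .csg_sidechain_raw)
  q <- normalize_charges(raw, ff14sb_cys_backbone(),
                         cap_atoms = character(0),
                         sidechain_atoms = sidechain, total_charge = -1L)
  atom_names <- c(backbone, sidechain)
  atoms <- data.frame(
    name = atom_names,
    atype = unname(.csg_atypes[atom_names]),
    charge = as.numeric(q[atom_names]),
    stringsAsFactors = FALSE
  )
  zmat <- .csg_zmatrix()
  pos <- .apply_zmatrix(.ideal_cys_anchor(), zmat,
                        overrides = c(CB2 = chi_ss, SG2 = chi2))
  xyz <- do.call(rbind, pos[atom_names])
  rownames(xyz) <- atom_names
  residue_template("CSG", atoms, .csg_bonds, head = "N", tail = "C",
                   xyz = xyz, zmatrix = zmat)
}

#' Stage-2 RESP refit set from a template
#'
#' The canonical two-stage RESP refit set: sp3 carbons bearing at least two
#' topologically equivalent hydrogens, plus those hydrogens. Equivalence here
#' means hydrogens bonded to the same carbon.
#'
#' @param tmpl a `csg_template`.
#' @return list with `refit` (atom names) and `equivalence_groups` (list of
#'   hydrogen-name vectors, one per qualifying carbon).
#' @export
stage2_set_from_template <- function(tmpl) {
  stopifnot(inherits(tmpl, "csg_template"))
  elem <- element_from_name(tmpl$atoms$name)
  nm <- tmpl$atoms$name
  bonds <- tmpl$bonds
  neigh <- function(x) c(bonds$a2[bonds$a1 == x], bonds$a1[bonds$a2 == x])
  refit <- character(0)
  groups <- list()
  for (cname in nm[elem == "C"]) {
    nb <- neigh(cname)
    if (length(nb) != 4L) next  # sp3 only
    hs <- nb[element_from_name(nb) == "H"]
    if (length(hs) >= 2L) {
      refit <- c(refit, cname, hs)
      groups[[length(groups) + 1L]] <- hs
    }
  }
  list(refit = refit, equivalence_groups = groups)
}
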