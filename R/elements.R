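# Element tables: IUPAC 2021 standard atomic weights (amu) and Bondi van der
# Waals radii (Angstrom). Keyed by element symbol in PDB upper-case form.

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA. = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)
# "NA"/"CA" clash with R's NA and the alpha-carbon name; stored with a dot and
# resolved through .element_key().

.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75, MG = 1.73, ZN = 1.39,
  SE = 1.90, CA. = 2.31
)

.element_key <- function(element) {
  el <- toupper(trimws(element))
  el[el == "NA"] <- "NA."
  el[el == "CA"] <- "CA."
  el
}

# Monatomic ion residue names whose atom name IS the element symbol.
.ion_resnames <- c("NA", "NA+", "SOD", "CL", "CL-", "CLA", "K", "K+", "MG",
                   "ZN", "CA", "CA2", "MN", "FE", "FE2")

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"NA"`).
#' @return numeric vector of masses in amu.
#' @examples
#' element_mass(c("C", "S"))
#' @export
element_mass <- function(element) {
  key <- .element_key(element)
  m <- unname(.element_masses[key])
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  m
}

#' Bondi van der Waals radius lookup
#'
#' @inheritParams element_mass
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  key <- .element_key(element)
  r <- unname(.bondi_radii[key])
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  r
}

#' Infer an element symbol from a PDB atom name
#'
#' Strips digits and primes, then takes the leading character; recognises
#' monatomic ions (where the atom name is the full element symbol, e.g. a
#' sodium ion named `NA` in residue `NA`) through the residue name.
#'
#' @param name atom name vector (PDB conventions).
#' @param resname residue names, same length (used only for ion recognition).
#' @return element symbol vector.
#' @export
element_from_name <- function(name, resname = rep("", length(name))) {
  stripped <- toupper(gsub("[0-9']", "", trimws(name)))
  el <- substr(stripped, 1L, 1L)
  ion <- toupper(trimws(resname)) %in% .ion_resnames & nchar(stripped) <= 2L
  el[ion] <- stripped[ion]
  # names like "1HB" strip to "HB" -> H; "SG2" -> "SG" -> S; fine either way
  bad <- !(.element_key(el) %in% names(.element_masses))
  if (any(bad)) {
    stop("cannot infer element from atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  }
  el
}
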