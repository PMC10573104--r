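# Small in-code PDB text fixtures.

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     record = "ATOM", alt = " ", occ = 1.0, elem = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resname, chain, resid, x, y, z, occ, 0,
          elem)
}

write_toy_pdb_file <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# three-atom, single-model toy file with exact coordinates
toy3_pdb <- function() {
  write_toy_pdb_file(c(
    pdb_line(1, "N", "ALA", "A", 1, 0.000, 0.000, 0.000, elem = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000, elem = "C"),
    pdb_line(3, "C", "ALA", "A", 1, 1.988, 1.425, 0.000, elem = "C")
  ))
}

two_model_pdb <- function() {
  m1 <- c(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, elem = "N"),
          pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, elem = "C"))
  m2 <- c(pdb_line(1, "N", "ALA", "A", 1, 0.5, 0, 0, elem = "N"),
          pdb_line(2, "CA", "ALA", "A", 1, 1.958, 0, 0, elem = "C"))
  write_toy_pdb_file(c("MODEL        1", m1, "ENDMDL",
                       "MODEL        2", m2, "ENDMDL"))
}

altloc_pdb <- function(occ_a = 0.6, occ_b = 0.4) {
  write_toy_pdb_file(c(
    pdb_line(1, "N", "CYS", "A", 1, 0, 0, 0, elem = "N"),
    pdb_line(2, "SG", "CYS", "A", 1, 1.0, 0, 0, alt = "A", occ = occ_a,
             elem = "S"),
    pdb_line(3, "SG", "CYS", "A", 1, 2.0, 0, 0, alt = "B", occ = occ_b,
             elem = "S"),
    pdb_line(4, "C", "CYS", "A", 1, 3.0, 0, 0, elem = "C")
  ))
}

solvated_pdb <- function() {
  prot <- c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0, elem = "N"),
            pdb_line(2, "CA", "GLY", "A", 1, 1.458, 0, 0, elem = "C"))
  wat <- unlist(lapply(1:3, function(i) {
    pdb_line(2 + i, "O", "HOH", "B", i, 10 + i, 0, 0, record = "HETATM",
             elem = "O")
  }))
  ion <- pdb_line(6, "NA", "NA", "B", 9, 20, 0, 0, record = "HETATM",
                  elem = "NA")
  write_toy_pdb_file(c(prot, wat, ion))
}
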