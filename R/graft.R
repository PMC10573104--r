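# In silico S-glutathionylation: build the glutathione moiety onto a target
# cysteine by internal-coordinate construction from a residue template, with
# control over the disulfide dihedral and rotamer enumeration, plus a steric
# clash scan.

#' Grafting specification
#'
#' @param chain chain id of the target cysteine.
#' @param resid residue number of the target cysteine.
#' @param chi_ss target S-S dihedral CB-SG-SG2-CB2, degrees in (-180, 180]
#'   (default +90, the value disulfides and experimental CSG sites cluster
#'   at).
#' @param chi2 CA-CB-SG-SG2 dihedral, degrees; `NULL` keeps the template
#'   value.
#' @param n_rotamers number of rotamers for [enumerate_rotamers()].
#' @param seed integer seed (reserved for stochastic placement strategies;
#'   the default builder is deterministic).
#' @return object of class `csg_graft_spec`.
#' @export
graft_spec <- function(chain, resid, chi_ss = 90, chi2 = NULL,
                       n_rotamers = 1L, seed = 1L) {
  if (!(chi_ss > -180 && chi_ss <= 180)) stop("chi_ss must be in (-180, 180]")
  if (!is.null(chi2) && !(chi2 > -180 && chi2 <= 180)) {
    stop("chi2 must be in (-180, 180]")
  }
  stopifnot(n_rotamers >= 1L)
  base::structure(
    list(chain = as.character(chain), resid = as.integer(resid),
         chi_ss = chi_ss, chi2 = chi2, n_rotamers = as.integer(n_rotamers),
         seed = as.integer(seed)),
    class = "csg_graft_spec"
  )
}

#' Graft glutathione onto a cysteine
#'
#' Renames the target cysteine to CSG, removes its thiol hydrogen (HG) when
#' present, and places every glutathione-moiety atom by running the
#' template's internal-coordinate table seeded from the cysteine anchors
#' (N, CA, C, CB, SG). The S-SG2 bond length and angles come from the
#' template; the CB-SG-SG2-CB2 dihedral is set to `spec$chi_ss` and
#' CA-CB-SG-SG2 to `spec$chi2` (template default when `NULL`). All
#' pre-existing atoms other than the removed HG keep bit-identical
#' coordinates.
#'
#' @param s a `csg_structure` containing the target cysteine.
#' @param spec a `csg_graft_spec`.
#' @param tmpl a `csg_template` with a z-matrix (default [csg_template()]).
#' @param clash_threshold heavy-heavy clash distance passed to
#'   [clash_scan()]; the report is attached as attribute `"clash"`.
#' @return the modified `csg_structure`.
#' @export
graft_glutathione <- function(s, spec, tmpl = csg_template(),
                              clash_threshold = 2.0) {
  stopifnot(inherits(s, "csg_structure"), inherits(spec, "csg_graft_spec"),
            inherits(tmpl, "csg_template"))
  if (is.null(tmpl$zmatrix)) stop("template has no z-matrix; cannot graft")
  res_i <- .residue_indices(s, spec$chain, spec$resid)
  if (length(res_i) == 0L) stop("no residue ", spec$chain, ":", spec$resid)
  resname <- unique(s$atoms$resname[res_i])
  if (!resname %in% c("CYS", "CYX")) {
    stop("target ", spec$chain, ":", spec$resid, " is ", resname, ", not CYS")
  }
  anchors <- c("N", "CA", "C", "CB", "SG")
  have <- s$atoms$name[res_i]
  if (!all(anchors %in% have)) {
    stop("missing anchor atom(s) in target cysteine: ",
         paste(setdiff(anchors, have), collapse = ", "))
  }
  pos <- list()
  for (a in anchors) pos[[a]] <- s$xyz[res_i[match(a, have)], ]

  overrides <- c(CB2 = spec$chi_ss)
  if (!is.null(spec$chi2)) overrides <- c(overrides, SG2 = spec$chi2)
  pos <- .apply_zmatrix(pos, tmpl$zmatrix, overrides = overrides)
  new_names <- tmpl$zmatrix$atom
  new_xyz <- do.call(rbind, pos[new_names])

  # drop HG, rename residue, append the new atoms after the residue
  keep <- setdiff(seq_len(nrow(s$atoms)), res_i[which(have == "HG")])
  atoms <- s$atoms[keep, , drop = FALSE]
  xyz <- s$xyz[keep, , drop = FALSE]
  in_res <- which(atoms$chain == spec$chain & atoms$resid == spec$resid)
  atoms$resname[in_res] <- "CSG"
  elem <- element_from_name(new_names)
  add <- data.frame(
    name = new_names, resname = "CSG", resid = spec$resid,
    chain = spec$chain, element = elem, mass = element_mass(elem),
    charge = tmpl$atoms$charge[match(new_names, tmpl$atoms$name)],
    atype = tmpl$atoms$atype[match(new_names, tmpl$atoms$name)],
    stringsAsFactors = FALSE
  )
  last <- max(in_res)
  n <- nrow(atoms)
  ord <- c(seq_len(last), seq_len(nrow(add)) + n, if (last < n) seq(last + 1L, n))
  atoms2 <- rbind(atoms, add)[ord, , drop = FALSE]
  xyz2 <- rbind(xyz, new_xyz)[ord, , drop = FALSE]
  rownames(atoms2) <- NULL
  out <- structure_model(atoms2, xyz2, title = s$title)
  new_idx <- which(out$atoms$name %in% new_names &
                     out$atoms$chain == spec$chain &
                     out$atoms$resid == spec$resid)
  attr(out, "clash") <- clash_scan(out, new_idx, threshold = clash_threshold,
                                   tmpl = tmpl)
  out
}

#' Scan for steric clashes around newly placed atoms
#'
#' Heavy-atom pairs between the new atoms and the rest of the structure
#' closer than `threshold`, excluding pairs separated by one or two bonds
#' (bond graph from the template plus the SG-SG2 attachment).
#'
#' @param s a `csg_structure`.
#' @param new_atom_indices indices of the newly placed atoms.
#' @param threshold clash distance, Angstrom (> 0; default 2.0).
#' @param tmpl template supplying the bond graph of the new atoms.
#' @return data.frame of class `csg_clash_report` with columns `atom_a`,
#'   `atom_b`, `distance`; each pair appears once.
#' @export
clash_scan <- function(s, new_atom_indices, threshold = 2.0,
                       tmpl = csg_template()) {
  stopifnot(threshold > 0)
  a <- s$atoms
  heavy <- toupper(a$element) != "H"
  new_i <- new_atom_indices[heavy[new_atom_indices]]
  other_i <- setdiff(which(heavy), new_atom_indices)
  # graph distance <= 2 exclusion: within the grafted residue, via template
  excl <- new.env()
  mark <- function(n1, n2) assign(paste(n1, n2, sep = "\r"), TRUE, envir = excl)
  bonds <- rbind(as.matrix(tmpl$bonds), c("SG", "SG2"))
  nb <- list()
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds[k, 1L]]] <- c(nb[[bonds[k, 1L]]], bonds[k, 2L])
    nb[[bonds[k, 2L]]] <- c(nb[[bonds[k, 2L]]], bonds[k, 1L])
  }
  for (x in names(nb)) {
    one <- nb[[x]]
    two <- unique(unlist(nb[one]))
    for (y in union(one, two)) { mark(x, y); mark(y, x) }
  }
  res_key <- paste(a$chain, a$resid)
  new_res <- unique(res_key[new_atom_indices])
  rows <- list()
  for (i in new_i) {
    d <- sqrt(rowSums(sweep(s$xyz[other_i, , drop = FALSE], 2L, s$xyz[i, ])^2))
    hit <- which(d < threshold)
    for (h in hit) {
      j <- other_i[h]
      if (res_key[j] %in% new_res &&
          !is.null(excl[[paste(a$name[i], a$name[j], sep = "\r")]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        atom_a = paste0(a$chain[i], ":", a$resid[i], ":", a$name[i]),
        atom_b = paste0(a$chain[j], ":", a$resid[j], ":", a$name[j]),
        distance = d[h], stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(atom_a = character(), atom_b = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("csg_clash_report", "data.frame")
  out
}

#' Enumerate grafting rotamers
#'
#' Builds `n_rotamers` grafted structures sampling `chi_ss` in `{+90, -90}`
#' (both disulfide wells, alternating) and, when more than two rotamers are
#' requested, `chi2` values spaced `360/k` apart starting from the template
#' value (`k = ceiling(n_rotamers / 2)`). Each structure carries its clash
#' report in attribute `"clash"`; the list is sorted by ascending clash count,
#' then by `(chi_ss, chi2)`.
#'
#' @param s a `csg_structure`.
#' @param spec a `csg_graft_spec` (`n_rotamers` used; its `chi_ss`/`chi2` are
#'   ignored in favor of the grid).
#' @param tmpl a `csg_template`.
#' @return list of `csg_structure`, each with attributes `"clash"`,
#'   `"chi_ss"`, `"chi2"`.
#' @export
enumerate_rotamers <- function(s, spec, tmpl = csg_template()) {
  n <- spec$n_rotamers
  k <- ceiling(n / 2)
  chi2_0 <- tmpl$zmatrix$dihedral[tmpl$zmatrix$atom == "SG2"]
  chi2_grid <- chi2_0 + 360 / k * (seq_len(k) - 1L)
  chi2_grid <- ((chi2_grid + 180) %% 360) - 180
  chi2_grid[chi2_grid == -180] <- 180
  combos <- data.frame(
    chi_ss = rep(c(90, -90), length.out = 2L * k),
    chi2 = rep(chi2_grid, each = 2L)
  )[seq_len(n), , drop = FALSE]
  out <- lapply(seq_len(n), function(r) {
    sp <- graft_spec(spec$chain, spec$resid, chi_ss = combos$chi_ss[r],
                     chi2 = combos$chi2[r], seed = spec$seed)
    g <- graft_glutathione(s, sp, tmpl)
    attr(g, "chi_ss") <- combos$chi_ss[r]
    attr(g, "chi2") <- combos$chi2[r]
    g
  })
  nclash <- vapply(out, function(g) nrow(attr(g, "clash")), integer(1L))
  out[order(nclash, combos$chi_ss, combos$chi2)]
}
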