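# Native-interaction identification and distance monitoring for the CSG side
# chain: hydrogen bonds of its amide/carboxylate/amino moieties with
# surrounding protein polar atoms, and the cation-pi contact of the free amino
# nitrogen with nearby aromatic rings.

# CSG side-chain polar moieties. Each monitored moiety maps to the heavy atom
# (or carboxylate oxygen pair) used for the distance, plus the donor H when
# the moiety donates.
.csg_moieties <- list(
  O2  = list(heavy = "O2",  kind = "acceptor"),
  OE1 = list(heavy = "OE1", kind = "acceptor"),
  H2  = list(heavy = "N2",  kind = "donor", hydrogen = "H2"),
  H4  = list(heavy = "N3",  kind = "donor", hydrogen = "H4"),
  C1  = list(heavy = c("O11", "O12"), kind = "carboxylate"),
  C3  = list(heavy = c("O31", "O32"), kind = "carboxylate"),
  N1  = list(heavy = "N1",  kind = "donor",
             hydrogen = c("H11", "H12", "H13"))
)

.aromatic_rings <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# distance used for a moiety: plain heavy-heavy, or min over the two
# carboxylate oxygens (crystallographic O naming is arbitrary).
.moiety_distance <- function(xyz, moiety_idx, partner_pos) {
  d <- apply(xyz[moiety_idx, , drop = FALSE], 1L,
             function(p) .vnorm(p - partner_pos))
  min(d)
}

#' Identify native CSG interactions in a reference structure
#'
#' Scans the polar moieties of the glutathione side chain (amide O2/OE1 and
#' H2/H4, the glycine-end carboxylate C3, the glutamate-end carboxylate C1 and
#' amino N1) for protein partners: any protein N/O heavy atom within `d_max`
#' (heavy-heavy; carboxylate distances are the minimum over the two oxygens).
#' When the donor hydrogen is present, candidate hydrogen bonds must also pass
#' a D-H...A angle >= 120 degrees filter. The free amino nitrogen N1 is
#' additionally tested for cation-pi contacts against TYR/PHE/TRP ring
#' centroids within `pi_max`.
#'
#' @param ref a `csg_structure` containing a CSG residue.
#' @param csg `c(chain, resid)` of the CSG residue.
#' @param d_max hydrogen-bond heavy-heavy cutoff (default 3.5 Angstrom).
#' @param pi_max cation-pi centroid cutoff (default 6.0 Angstrom).
#' @return data.frame of class `csg_interactions` with columns `kind`
#'   (`"hbond"`/`"cation_pi"`), `csg_atom`, `partner_chain`, `partner_resid`,
#'   `partner_atom` (`"ring"` for cation-pi), `ref_distance`.
#' @export
find_native_interactions <- function(ref, csg, d_max = 3.5, pi_max = 6.0) {
  stopifnot(inherits(ref, "csg_structure"))
  chain <- as.character(csg[1L]); resid <- as.integer(csg[2L])
  res_i <- .residue_indices(ref, chain, resid)
  if (length(res_i) == 0L) stop("no residue ", chain, ":", resid)
  a <- ref$atoms
  env_i <- setdiff(seq_len(nrow(a)), res_i)
  env_i <- env_i[!(a$resname[env_i] %in% c("WAT", "HOH"))]
  polar_i <- env_i[a$element[env_i] %in% c("N", "O")]

  res_names <- a$name[res_i]
  out <- list()
  for (mname in names(.csg_moieties)) {
    mo <- .csg_moieties[[mname]]
    heavy_i <- res_i[match(mo$heavy, res_names)]
    if (anyNA(heavy_i)) next  # moiety atoms absent (e.g. partial side chain)
    for (p in polar_i) {
      d <- .moiety_distance(ref$xyz, heavy_i, ref$xyz[p, ])
      if (d > d_max) next
      if (mo$kind == "donor") {
        hn <- mo$hydrogen[mo$hydrogen %in% res_names]
        if (length(hn) > 0L) {
          ok <- FALSE
          for (h in res_i[match(hn, res_names)]) {
            ang <- .bond_angle(ref$xyz[heavy_i[1L], ], ref$xyz[h, ], ref$xyz[p, ])
            if (ang >= 120) { ok <- TRUE; break }
          }
          if (!ok) next
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = "hbond", csg_atom = mname, partner_chain = a$chain[p],
        partner_resid = a$resid[p], partner_atom = a$name[p],
        ref_distance = d, stringsAsFactors = FALSE
      )
    }
  }

  # cation-pi: N1 against aromatic ring centroids
  n1 <- res_i[match("N1", res_names)]
  if (!is.na(n1)) {
    ar <- unique(a[a$resname %in% names(.aromatic_rings), c("chain", "resid", "resname")])
    ar <- ar[!(ar$chain == chain & ar$resid == resid), , drop = FALSE]
    if (nrow(ar) > 0L) for (k in seq_len(nrow(ar))) {
      ring_names <- .aromatic_rings[[ar$resname[k]]]
      ri <- .residue_indices(ref, ar$chain[k], ar$resid[k])
      ring_i <- ri[match(ring_names, a$name[ri])]
      if (anyNA(ring_i)) next
      ctr <- colMeans(ref$xyz[ring_i, , drop = FALSE])
      d <- .vnorm(ref$xyz[n1, ] - ctr)
      if (d <= pi_max) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "cation_pi", csg_atom = "N1", partner_chain = ar$chain[k],
          partner_resid = ar$resid[k], partner_atom = "ring",
          ref_distance = d, stringsAsFactors = FALSE
        )
      }
    }
  }

  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), csg_atom = character(),
               partner_chain = character(), partner_resid = integer(),
               partner_atom = character(), ref_distance = numeric(),
               stringsAsFactors = FALSE)
  class(res) <- c("csg_interactions", "data.frame")
  attr(res, "csg") <- c(chain = chain, resid = resid)
  res
}

#' Monitor native-interaction distances along an ensemble
#'
#' One distance series per interaction: heavy-heavy distance for hydrogen
#' bonds (minimum over the two oxygens for carboxylate moieties), centroid
#' distance for cation-pi entries, recomputed on every frame.
#'
#' @param traj a `csg_trajectory` whose topology contains the CSG residue and
#'   all partners.
#' @param interactions a `csg_interactions` table from
#'   [find_native_interactions()].
#' @return named list of `csg_series`, one per interaction row.
#' @export
interaction_distance_series <- function(traj, interactions) {
  stopifnot(inherits(traj, "csg_trajectory"),
            inherits(interactions, "csg_interactions"))
  top <- traj$topology
  a <- top$atoms
  csg <- attr(interactions, "csg")
  res_i <- .residue_indices(top, csg["chain"], as.integer(csg["resid"]))
  if (length(res_i) == 0L) stop("CSG residue not present in trajectory topology")
  res_names <- a$name[res_i]
  F <- n_frames(traj)

  out <- list()
  for (k in seq_len(nrow(interactions))) {
    row <- interactions[k, ]
    if (row$kind == "cation_pi") {
      ri <- .residue_indices(top, row$partner_chain, row$partner_resid)
      if (length(ri) == 0L) stop("unresolvable partner: ", row$partner_chain,
                                 ":", row$partner_resid)
      rn <- .aromatic_rings[[a$resname[ri[1L]]]]
      ring_i <- ri[match(rn, a$name[ri])]
      if (anyNA(ring_i)) stop("unresolvable aromatic ring for partner ",
                              row$partner_chain, ":", row$partner_resid)
      n1 <- res_i[match("N1", res_names)]
      vals <- vapply(seq_len(F), function(f) {
        xyz <- traj$frames[f, , , drop = TRUE]
        dim(xyz) <- c(n_atoms(traj), 3L)
        .vnorm(xyz[n1, ] - colMeans(xyz[ring_i, , drop = FALSE]))
      }, numeric(1L))
      nm <- paste0("N1...", row$partner_chain, ":", row$partner_resid, ":ring")
    } else {
      mo <- .csg_moieties[[row$csg_atom]]
      heavy_i <- res_i[match(mo$heavy, res_names)]
      if (anyNA(heavy_i)) stop("CSG moiety atoms missing: ", row$csg_atom)
      p <- which(a$chain == row$partner_chain & a$resid == row$partner_resid &
                   a$name == row$partner_atom)
      if (length(p) != 1L) stop("unresolvable partner: ", row$partner_chain,
                                ":", row$partner_resid, ":", row$partner_atom)
      vals <- vapply(seq_len(F), function(f) {
        xyz <- traj$frames[f, , , drop = TRUE]
        dim(xyz) <- c(n_atoms(traj), 3L)
        .moiety_distance(xyz, heavy_i, xyz[p, ])
      }, numeric(1L))
      nm <- paste0(row$csg_atom, "...", row$partner_chain, ":",
                   row$partner_resid, ":", row$partner_atom)
    }
    out[[nm]] <- descriptor_series(vals, name = nm)
  }
  out
}
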