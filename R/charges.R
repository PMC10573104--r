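# Charge sets and the charge-normalization scheme used to turn raw fitted
# charges for a capped model compound into a force-field residue with an
# exact integer total charge.

#' Construct a charge set
#'
#' @param charges named numeric vector, atom name -> charge (e).
#' @return object of class `csg_charges` (a named numeric vector).
#' @export
charge_set <- function(charges) {
  if (is.null(names(charges)) || any(!nzchar(names(charges)))) {
    stop("charges must be a fully named vector")
  }
  if (anyDuplicated(names(charges))) stop("duplicate atom names in charge set")
  base::structure(as.numeric(charges), names = names(charges),
                  class = "csg_charges")
}

#' @export
print.csg_charges <- function(x, ...) {
  cat("<csg_charges> ", length(x), " atoms, total ",
      sprintf("%.6f", sum(x)), " e\n", sep = "")
  invisible(x)
}

#' Normalize model-compound charges into a residue charge set
#'
#' The bookkeeping applied to raw fitted charges of a capped model compound:
#' cap atoms are dropped (their charge is discarded, not redistributed),
#' backbone atoms take the reference amino-acid charges exactly, and the
#' residual needed to reach the integer total charge is spread uniformly over
#' the side-chain atoms:
#' `delta = (total - sum(backbone_ref) - sum(raw side chain)) / n_sidechain`.
#'
#' @param raw `csg_charges` (or named vector) covering all atoms of the model
#'   compound.
#' @param backbone_ref reference charges for every backbone (non-cap,
#'   non-side-chain) atom, e.g. the ff14SB cysteine backbone.
#' @param cap_atoms names of the capping-group atoms to drop.
#' @param sidechain_atoms names of the side-chain atoms receiving the
#'   correction; must be non-empty.
#' @param total_charge integer target total charge (e).
#' @return `csg_charges` over backbone + side-chain atoms, summing to
#'   `total_charge` to 1e-9. The per-atom correction is stored in attribute
#'   `"delta"`.
#' @export
normalize_charges <- function(raw, backbone_ref, cap_atoms, sidechain_atoms,
                              total_charge) {
  raw <- charge_set(raw)
  backbone_ref <- charge_set(backbone_ref)
  if (length(sidechain_atoms) == 0L) stop("side-chain atom set is empty")
  cats <- c(cap_atoms, sidechain_atoms)
  if (anyDuplicated(cats)) {
    stop("atom in two categories: ",
         paste(unique(cats[duplicated(cats)]), collapse = ", "))
  }
  backbone_atoms <- setdiff(names(raw), c(cap_atoms, sidechain_atoms))
  if (any(backbone_atoms %in% sidechain_atoms)) stop("category overlap")
  missing_bb <- setdiff(backbone_atoms, names(backbone_ref))
  if (length(missing_bb) > 0L) {
    stop("backbone reference does not cover: ",
         paste(missing_bb, collapse = ", "))
  }
  missing_sc <- setdiff(sidechain_atoms, names(raw))
  if (length(missing_sc) > 0L) {
    stop("raw charges do not cover side-chain atoms: ",
         paste(missing_sc, collapse = ", "))
  }
  bb <- backbone_ref[backbone_atoms]
  sc_raw <- raw[sidechain_atoms]
  delta <- (total_charge - sum(bb) - sum(sc_raw)) / length(sidechain_atoms)
  out <- charge_set(c(stats::setNames(as.numeric(bb), backbone_atoms),
                      stats::setNames(as.numeric(sc_raw) + delta,
                                      sidechain_atoms)))
  stopifnot(abs(sum(out) - total_charge) < 1e-9)
  attr(out, "delta") <- delta
  out
}

#' Read a charge table (CSV: atom,charge)
#' @param path CSV path with columns `atom`, `charge`.
#' @return a `csg_charges`.
#' @export
read_charge_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  charge_set(stats::setNames(d$charge, d$atom))
}

#' Write a charge table (CSV: atom,charge)
#' @param charges a `csg_charges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charge_csv <- function(charges, path) {
  utils::write.csv(data.frame(atom = names(charges),
                              charge = as.numeric(charges)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' ff14SB cysteine backbone charges
#'
#' The backbone partial charges of the AMBER ff14SB cysteine residue, used as
#' the frozen backbone reference when normalizing CSG charges so the modified
#' residue splices cleanly into an ff14SB protein chain.
#'
#' @return a `csg_charges` for atoms N, H, CA, HA, C, O.
#' @export
ff14sb_cys_backbone <- function() {
  charge_set(c(N = -0.4157, H = 0.2719, CA = 0.0213, HA = 0.1124,
               C = 0.5973, O = -0.5679))
}
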