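# Two-stage RESP charge fitting. The fit minimizes
#
#   sum_i ( V_i - sum_j q_j / r_ij )^2  +  sum_j a_j ( sqrt(q_j^2 + b^2) - b )
#
# subject to a fixed total charge, frozen charges, and within-group charge
# equality, with everything in atomic units (Bohr, Hartree/e, elementary
# charge). The hyperbolic restraint is re-linearized each pass (its gradient
# contributes a_j / sqrt(q_j^2 + b^2) to the diagonal) and the constrained
# linear system is solved repeatedly until the charges stop moving.

.bohr_per_angstrom <- 1 / 0.529177210903

#' Construct an ESP grid
#'
#' Molecular geometry plus electrostatic-potential sample points, the input to
#' RESP fitting. Atomic units throughout (Bohr, Hartree/e).
#'
#' @param atom_positions M x 3 nuclear coordinates, Bohr.
#' @param atom_names M atom names.
#' @param points P x 3 sample-point coordinates, Bohr.
#' @param potentials P potential values, Hartree/e.
#' @return object of class `csg_esp_grid`.
#' @export
esp_grid <- function(atom_positions, atom_names, points, potentials) {
  atom_positions <- as.matrix(atom_positions)
  points <- as.matrix(points)
  stopifnot(ncol(atom_positions) == 3L, ncol(points) == 3L,
            nrow(points) == length(potentials),
            nrow(atom_positions) == length(atom_names))
  if (nrow(points) < nrow(atom_positions)) {
    stop("need at least as many sample points as atoms")
  }
  dmin <- min(apply(atom_positions, 1L, function(p) {
    sqrt(rowSums(sweep(points, 2L, p)^2))
  }))
  if (dmin <= 1) stop("sample point within 1 Bohr of a nucleus")
  base::structure(
    list(atom_positions = atom_positions, atom_names = as.character(atom_names),
         points = points, potentials = as.numeric(potentials)),
    class = "csg_esp_grid"
  )
}

#' @export
print.csg_esp_grid <- function(x, ...) {
  cat("<csg_esp_grid> ", nrow(x$atom_positions), " atoms, ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Read an ESP grid file (antechamber-style whitespace dialect)
#'
#' First line: atom count and point count; then one line per nucleus
#' (`x y z`, Bohr); then one line per sample point (`V x y z`, potential
#' first, atomic units).
#'
#' @param path file path.
#' @param atom_names optional atom names (defaults to `A1..AM`).
#' @return a `csg_esp_grid`.
#' @export
read_esp <- function(path, atom_names = NULL) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  hd <- as.integer(strsplit(trimws(ln[1L]), "\\s+")[[1L]])
  M <- hd[1L]; P <- hd[2L]
  num <- function(rows) {
    do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                          function(x) as.numeric(gsub("[Dd]", "e", x))))
  }
  at <- num(ln[2L:(1L + M)])
  pt <- num(ln[(2L + M):(1L + M + P)])
  if (is.null(atom_names)) atom_names <- paste0("A", seq_len(M))
  esp_grid(at[, 1:3, drop = FALSE], atom_names,
           pt[, 2:4, drop = FALSE], pt[, 1L])
}

#' Write an ESP grid file
#' @param grid a `csg_esp_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_esp <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d%5d", nrow(grid$atom_positions), nrow(grid$points)), con)
  writeLines(sprintf("%16.7E%16.7E%16.7E", grid$atom_positions[, 1L],
                     grid$atom_positions[, 2L], grid$atom_positions[, 3L]), con)
  writeLines(sprintf("%16.7E%16.7E%16.7E%16.7E", grid$potentials,
                     grid$points[, 1L], grid$points[, 2L], grid$points[, 3L]), con)
  invisible(path)
}

#' RESP fit configuration
#'
#' @param total_charge integer total molecular charge (e).
#' @param a1 stage-1 restraint strength (e^2 units, default 0.0005).
#' @param a2 stage-2 restraint strength (default 0.001).
#' @param b restraint width (e, default 0.1).
#' @param frozen named numeric vector: atom name -> fixed charge.
#' @param equivalence_groups list of atom-name vectors forced to share one
#'   charge.
#' @param stage2_refit_set atom names refit in stage 2 (canonically the sp3
#'   carbons bearing equivalent hydrogens plus those hydrogens; see
#'   [stage2_set_from_template()]). Empty -> single-stage fit.
#' @param max_iter maximum re-linearization passes (default 200).
#' @param tol convergence threshold on `max |dq|` (default 1e-8).
#' @return object of class `csg_resp_config`.
#' @export
resp_config <- function(total_charge, a1 = 0.0005, a2 = 0.001, b = 0.1,
                        frozen = NULL, equivalence_groups = list(),
                        stage2_refit_set = character(), max_iter = 200L,
                        tol = 1e-8) {
  stopifnot(a1 >= 0, a2 >= 0, b > 0)
  if (!is.null(frozen) && length(equivalence_groups) > 0L) {
    for (g in equivalence_groups) {
      if (any(g %in% names(frozen)) && !all(g %in% names(frozen))) {
        stop("equivalence group mixes frozen and free atoms: ",
             paste(g, collapse = ", "))
      }
    }
  }
  base::structure(
    list(total_charge = total_charge, a1 = a1, a2 = a2, b = b,
         frozen = frozen, equivalence_groups = equivalence_groups,
         stage2_refit_set = stage2_refit_set,
         max_iter = as.integer(max_iter), tol = tol),
    class = "csg_resp_config"
  )
}

# One constrained restrained fit. names: all atom names; A: P x M inverse
# distance matrix; V: potentials; a_vec: per-atom restraint strengths;
# frozen: named charges; groups: list of name vectors (free atoms only).
.resp_solve <- function(A, V, names, a_vec, b, total_charge, frozen, groups,
                        max_iter, tol, q_init = NULL) {
  M <- length(names)
  frozen_names <- names(frozen)
  free <- setdiff(names, frozen_names)
  if (length(free) == 0L) {
    q <- frozen[names]
    return(q)
  }
  # reduced variables: one per equivalence group + one per ungrouped free atom
  grp_of <- stats::setNames(rep(NA_integer_, M), names)
  gid <- 0L
  for (g in groups) {
    g <- intersect(g, free)
    if (length(g) == 0L) next
    gid <- gid + 1L
    grp_of[g] <- gid
  }
  for (nm in free) {
    if (is.na(grp_of[nm])) { gid <- gid + 1L; grp_of[nm] <- gid }
  }
  G <- gid
  E <- matrix(0, M, G)  # q_free = E %*% p (frozen rows stay 0)
  for (nm in free) E[match(nm, names), grp_of[nm]] <- 1
  Vadj <- V
  if (length(frozen_names) > 0L) {
    Vadj <- V - A[, match(frozen_names, names), drop = FALSE] %*%
      unname(frozen[frozen_names])
  }
  AE <- A %*% E
  B <- crossprod(AE)
  d <- crossprod(AE, Vadj)
  cvec <- colSums(E)  # group sizes
  Qfree <- total_charge - sum(frozen)

  p <- if (is.null(q_init)) rep(Qfree / sum(cvec), G) else {
    vapply(seq_len(G), function(g) mean(q_init[names[E[, g] > 0]]), numeric(1L))
  }
  for (it in seq_len(max_iter)) {
    q_all <- as.vector(E %*% p)
    # restraint diagonal: sum over member atoms of a_j / sqrt(q_j^2 + b^2)
    rdiag <- vapply(seq_len(G), function(g) {
      j <- which(E[, g] > 0)
      sum(a_vec[j] / sqrt(q_all[j]^2 + b^2))
    }, numeric(1L))
    K <- rbind(cbind(B + diag(rdiag, G), cvec),
               c(cvec, 0))
    rhs <- c(d, Qfree)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      stop("singular constrained RESP system: ", conditionMessage(e))
    })
    p_new <- sol[seq_len(G)]
    dq <- max(abs(p_new - p))
    p <- p_new
    if (dq < tol) {
      q <- stats::setNames(as.vector(E %*% p), names)
      q[frozen_names] <- frozen[frozen_names]
      return(q)
    }
  }
  stop("RESP did not converge after ", max_iter, " iterations (last max |dq| = ",
       format(dq), ")")
}

#' Fit RESP charges to an ESP grid
#'
#' Two-stage restrained electrostatic potential fit. Stage 1 restrains all
#' non-hydrogen atoms with strength `a1` (hydrogens are never restrained) and
#' fits every non-frozen atom. Stage 2, run only when `stage2_refit_set` is
#' non-empty, refits just that set with strength `a2` and the configured
#' equivalence groups, all other atoms frozen at their stage-1 values.
#'
#' @param grid a `csg_esp_grid`.
#' @param cfg a `csg_resp_config`.
#' @return named charge vector (class `csg_charges`) summing to
#'   `cfg$total_charge`.
#' @export
fit_resp <- function(grid, cfg) {
  stopifnot(inherits(grid, "csg_esp_grid"), inherits(cfg, "csg_resp_config"))
  names <- grid$atom_names
  M <- length(names)
  A <- 1 / .distance_matrix_pts(grid$points, grid$atom_positions)
  elem <- element_from_name(names)
  is_h <- toupper(elem) == "H"

  frozen1 <- if (is.null(cfg$frozen)) stats::setNames(numeric(0), character(0)) else cfg$frozen
  a_vec1 <- ifelse(is_h, 0, cfg$a1)
  refit <- intersect(cfg$stage2_refit_set, names)
  # canonical two-stage protocol: equivalencing is a stage-2 device; it only
  # constrains stage 1 when no second stage follows
  groups1 <- if (length(refit) > 0L) list() else cfg$equivalence_groups
  q1 <- .resp_solve(A, grid$potentials, names, a_vec1, cfg$b,
                    cfg$total_charge, frozen1, groups1,
                    cfg$max_iter, cfg$tol)

  if (length(refit) == 0L) {
    return(charge_set(q1))
  }
  frozen2_names <- setdiff(names, refit)
  frozen2 <- q1[frozen2_names]
  if (length(names(frozen1)) > 0L) frozen2[names(frozen1)] <- frozen1
  a_vec2 <- ifelse(is_h, 0, cfg$a2)
  groups2 <- lapply(cfg$equivalence_groups, intersect, y = refit)
  groups2 <- groups2[vapply(groups2, length, integer(1L)) > 1L]
  q2 <- .resp_solve(A, grid$potentials, names, a_vec2, cfg$b,
                    cfg$total_charge, frozen2, groups2,
                    cfg$max_iter, cfg$tol, q_init = q1)
  charge_set(q2[names])
}

# P x M matrix of distances between rows of pts and rows of at.
.distance_matrix_pts <- function(pts, at) {
  M <- nrow(at)
  out <- matrix(NA_real_, nrow(pts), M)
  for (j in seq_len(M)) {
    out[, j] <- sqrt(rowSums(sweep(pts, 2L, at[j, ])^2))
  }
  out
}
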