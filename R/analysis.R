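# Ensemble descriptor suite: Kabsch superposition and RMSD series, radius of
# gyration, torsion series with circular statistics, and the DescriptorSeries
# container shared by all per-frame analyses.

#' Per-frame descriptor series
#'
#' Container for a scalar descriptor measured on every frame of an ensemble.
#' For angular descriptors the mean/sd are circular (mean resultant vector),
#' so e.g. values +179 and -179 average to 180, not 0.
#'
#' @param values numeric vector, one value per frame (Angstrom or degrees).
#' @param name descriptor name.
#' @param frames frame indices (default `seq_along(values)`).
#' @param circular logical; treat values as angles in degrees.
#' @return object of class `csg_series` with fields `name`, `frames`,
#'   `values`, `mean`, `sd`, `circular`.
#' @export
descriptor_series <- function(values, name = "descriptor",
                              frames = seq_along(values), circular = FALSE) {
  stopifnot(length(values) == length(frames), length(values) >= 1L)
  if (circular) {
    th <- .deg2rad(values)
    S <- mean(sin(th)); C <- mean(cos(th))
    m <- .rad2deg(atan2(S, C))
    if (m <= -180) m <- m + 360
    Rbar <- min(1, sqrt(S^2 + C^2))
    sdv <- if (Rbar <= 0) Inf else .rad2deg(sqrt(max(0, -2 * log(Rbar))))
  } else {
    m <- mean(values)
    sdv <- if (length(values) > 1L) stats::sd(values) else 0
  }
  base::structure(
    list(name = name, frames = as.integer(frames), values = as.numeric(values),
         mean = m, sd = sdv, circular = circular),
    class = "csg_series"
  )
}

#' @export
print.csg_series <- function(x, ...) {
  cat("<csg_series> ", x$name, ": ", length(x$values), " frames, mean ",
      sprintf("%.3f", x$mean), " sd ", sprintf("%.3f", x$sd),
      if (x$circular) " (circular)", "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a descriptor series
#'
#' Mean, sd, median, quartiles and 1.5*IQR whiskers (the boxplot statistics
#' used for per-system descriptor panels).
#'
#' @param series a `csg_series`.
#' @return named list of statistics.
#' @export
series_summary <- function(series) {
  v <- series$values
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  list(
    name = series$name, n = length(v), mean = series$mean, sd = series$sd,
    median = q[2L], q1 = q[1L], q3 = q[3L],
    whisker_low = min(v[v >= q[1L] - 1.5 * iqr]),
    whisker_high = max(v[v <= q[3L] + 1.5 * iqr])
  )
}

#' Histogram of a descriptor series
#'
#' Fixed-width bins (default 0.1 Angstrom) for distance-distribution export.
#'
#' @param series a `csg_series`.
#' @param width bin width.
#' @return data.frame with `mid` (bin center) and `count`.
#' @export
series_histogram <- function(series, width = 0.1) {
  v <- series$values
  lo <- floor(min(v) / width) * width
  breaks <- seq(lo, max(v) + width, by = width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Write a descriptor series as CSV
#' @param series a `csg_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(data.frame(frame = series$frames, value = series$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Optimal weighted rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing the
#' weighted sum of squared distances between `R x_i + t` and `y_i`, and the
#' post-fit RMSD `sqrt(sum w_i |x_i' - y_i|^2 / sum w_i)`.
#'
#' @param mobile N x 3 coordinates to move.
#' @param ref N x 3 target coordinates.
#' @param weights optional non-negative weights (default uniform).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch_superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  N <- nrow(mobile)
  if (N < 3L || nrow(ref) != N) stop("need matching N x 3 matrices, N >= 3")
  w <- if (is.null(weights)) rep(1, N) else as.numeric(weights)
  if (length(w) != N || any(w < 0) || sum(w) <= 0) stop("bad weights")
  wn <- w / sum(w)
  cm <- colSums(mobile * wn)
  cr <- colSums(ref * wn)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(ref, 2L, cr)
  H <- t(X * wn) %*% Y
  sv <- svd(H)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300)) {
    stop("degenerate geometry: superposition target has rank < 2")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2L, t_vec, "+")
  rmsd <- sqrt(sum(wn * rowSums((moved - ref)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# Apply a superposition to an N x 3 matrix.
.apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Plain (unfitted) RMSD between two coordinate sets
#' @param a,b N x 3 matrices.
#' @param weights optional weights.
#' @return RMSD in Angstrom.
#' @export
rmsd_plain <- function(a, b, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  w <- if (is.null(weights)) rep(1, nrow(a)) else as.numeric(weights)
  sqrt(sum(w / sum(w) * rowSums((a - b)^2)))
}

# Map atoms of `traj` topology onto `ref` by (chain, resid, name); returns for
# each topology index the matching ref row, erroring on unmatched atoms.
.match_atoms <- function(top_atoms, ref_atoms, idx) {
  key <- function(a) paste(a$chain, a$resid, a$name, sep = "\r")
  m <- match(key(top_atoms)[idx], key(ref_atoms))
  if (anyNA(m)) {
    miss <- idx[is.na(m)]
    stop("atoms not found in reference: ",
         paste(paste0(top_atoms$chain[miss], ":", top_atoms$resid[miss], ":",
                      top_atoms$name[miss]), collapse = ", "))
  }
  m
}

#' Per-frame RMSD of an ensemble against a reference structure
#'
#' Each frame is first superposed on the reference over `fit_sel`, then the
#' RMSD is computed over `calc_sel` without refitting. With
#' `fit_sel == calc_sel` this is the classic best-fit RMSD. Atoms are matched
#' between trajectory and reference by `(chain, resid, name)`.
#'
#' @param traj a `csg_trajectory`.
#' @param ref a `csg_structure` reference.
#' @param fit_sel selection string for the superposition (default
#'   `"backbone"`).
#' @param calc_sel selection string for the RMSD (default = `fit_sel`).
#' @param mass_weighted use masses as fit weights (default FALSE).
#' @return a `csg_series` (Angstrom).
#' @export
rmsd_series <- function(traj, ref, fit_sel = "backbone", calc_sel = fit_sel,
                        mass_weighted = FALSE) {
  stopifnot(inherits(traj, "csg_trajectory"), inherits(ref, "csg_structure"))
  top <- traj$topology$atoms
  fit_i <- select_atoms(traj, fit_sel)
  calc_i <- select_atoms(traj, calc_sel)
  fit_r <- .match_atoms(top, ref$atoms, fit_i)
  calc_r <- .match_atoms(top, ref$atoms, calc_i)
  w <- if (mass_weighted) top$mass[fit_i] else NULL
  F <- n_frames(traj)
  vals <- numeric(F)
  for (f in seq_len(F)) {
    xyz <- traj$frames[f, , , drop = TRUE]
    dim(xyz) <- c(dim(traj$frames)[2L], 3L)
    fit <- kabsch_superpose(xyz[fit_i, , drop = FALSE],
                            ref$xyz[fit_r, , drop = FALSE], weights = w)
    moved <- .apply_fit(xyz[calc_i, , drop = FALSE], fit)
    vals[f] <- rmsd_plain(moved, ref$xyz[calc_r, , drop = FALSE])
  }
  descriptor_series(vals, name = paste0("rmsd[fit=", fit_sel, ",calc=",
                                        calc_sel, "]"))
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of atoms from their mass-weighted centroid:
#' `Rg = sqrt(sum m_i |x_i - xbar|^2 / sum m_i)`.
#'
#' @param coords N x 3 coordinates (Angstrom) or a `csg_structure`.
#' @param masses atomic masses; taken from the structure when omitted.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  if (inherits(coords, "csg_structure")) {
    if (is.null(masses)) masses <- coords$atoms$mass
    coords <- coords$xyz
  }
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) stop("non-positive mass")
  w <- masses / sum(masses)
  ctr <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2L, ctr)^2)))
}

#' Per-frame radius of gyration of an ensemble
#'
#' @param traj a `csg_trajectory`.
#' @param sel selection string (default `"all"`).
#' @return a `csg_series` (Angstrom).
#' @export
rg_series <- function(traj, sel = "all") {
  idx <- select_atoms(traj, sel)
  m <- traj$topology$atoms$mass[idx]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$frames[f, idx, , drop = TRUE]
    dim(xyz) <- c(length(idx), 3L)
    radius_of_gyration(xyz, m)
  }, numeric(1L))
  descriptor_series(vals, name = paste0("rg[", sel, "]"))
}

#' Per-frame S-S dihedral of a glutathionylated cysteine
#'
#' The torsion about the disulfide formed on glutathionylation,
#' CB-SG-SG2-CB2 (chi_ss), reported with circular mean/sd.
#'
#' @param traj a `csg_trajectory`.
#' @param csg `c(chain, resid)` of the CSG residue.
#' @return a `csg_series` in degrees, `circular = TRUE`.
#' @export
ss_dihedral_series <- function(traj, csg) {
  top <- traj$topology
  chain <- as.character(csg[1L]); resid <- as.integer(csg[2L])
  idx <- vapply(c("CB", "SG", "SG2", "CB2"),
                function(nm) .atom_index(top, chain, resid, nm), integer(1L))
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    p <- traj$frames[f, idx, , drop = TRUE]
    dim(p) <- c(4L, 3L)
    dihedral(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
  }, numeric(1L))
  descriptor_series(vals, name = "chi_ss", circular = TRUE)
}

#' Hydrogen-bond occupancy of a distance series
#'
#' Percentage of frames in which the monitored distance is at or below the
#' cutoff -- the operational meaning of an interaction being "observed" along
#' an ensemble.
#'
#' @param series a `csg_series` of distances (Angstrom).
#' @param d_cut cutoff distance (default 3.5 Angstrom, heavy-heavy).
#' @return occupancy percentage in \[0, 100\].
#' @export
hbond_occupancy <- function(series, d_cut = 3.5) {
  stopifnot(length(series$values) > 0L)
  100 * mean(series$values <= d_cut)
}
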