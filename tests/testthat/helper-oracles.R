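# Independent oracle implementations used to cross-check the package.
# Deliberately written along different algorithmic routes than the package
# code (quaternion eigen-solver instead of SVD Kabsch, naive loops instead of
# vectorized kernels) so agreement is evidence, not tautology.

# Horn's quaternion method for optimal superposition: returns rotation matrix
# and post-fit RMSD from the largest eigenvalue of the 4x4 key matrix.
oracle_quaternion_superpose <- function(mobile, ref) {
  N <- nrow(mobile)
  X <- scale(mobile, scale = FALSE)
  Y <- scale(ref, scale = FALSE)
  M <- t(X) %*% Y
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values[1]
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lambda) / N
  list(rotation = R, rmsd = sqrt(max(0, msd)))
}

# Naive per-frame RMSD recomputation: quaternion fit on fit indices, apply,
# plain loop RMSD over calc indices.
oracle_rmsd_series <- function(traj, ref_xyz, fit_i, calc_i) {
  vapply(seq_len(dim(traj$frames)[1]), function(f) {
    xyz <- traj$frames[f, , ]
    dim(xyz) <- c(dim(traj$frames)[2], 3)
    fit <- oracle_quaternion_superpose(xyz[fit_i, , drop = FALSE],
                                       ref_xyz[fit_i, , drop = FALSE])
    cm <- colMeans(xyz[fit_i, , drop = FALSE])
    cr <- colMeans(ref_xyz[fit_i, , drop = FALSE])
    moved <- sweep(sweep(xyz[calc_i, , drop = FALSE], 2, cm) %*% t(fit$rotation),
                   2, cr, "+")
    d2 <- 0
    for (k in seq_along(calc_i)) {
      d2 <- d2 + sum((moved[k, ] - ref_xyz[calc_i[k], ])^2)
    }
    sqrt(d2 / length(calc_i))
  }, numeric(1))
}

# Naive mass-weighted radius of gyration.
oracle_rg <- function(xyz, masses) {
  ctr <- c(sum(xyz[, 1] * masses), sum(xyz[, 2] * masses),
           sum(xyz[, 3] * masses)) / sum(masses)
  s <- 0
  for (i in seq_len(nrow(xyz))) s <- s + masses[i] * sum((xyz[i, ] - ctr)^2)
  sqrt(s / sum(masses))
}

# Analytic cross-product torsion (independent sign evaluation).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi))) * 180 / pi
  if (sum(cx(n1, n2) * b2) < 0) phi <- -phi
  phi
}

# Brute-force parameter-coverage oracle: adjacency-matrix path enumeration
# with direct forward/reverse (and wildcard) table lookups.
oracle_coverage <- function(atom_names, atypes, bond_pairs, params) {
  n <- length(atom_names)
  A <- matrix(FALSE, n, n, dimnames = list(atom_names, atom_names))
  for (k in seq_len(nrow(bond_pairs))) {
    A[bond_pairs[k, 1], bond_pairs[k, 2]] <- TRUE
    A[bond_pairs[k, 2], bond_pairs[k, 1]] <- TRUE
  }
  ty <- stats::setNames(atypes, atom_names)
  has_row <- function(tab, types) {
    if (nrow(tab) == 0) return(FALSE)
    fw <- rep(TRUE, nrow(tab)); bw <- rep(TRUE, nrow(tab))
    for (c in seq_along(types)) {
      fw <- fw & tab[[c]] == types[c]
      bw <- bw & tab[[c]] == rev(types)[c]
    }
    any(fw) || any(bw)
  }
  missing <- character(0)
  canon <- function(types) {
    r <- rev(types)
    if (paste(types, collapse = "-") <= paste(r, collapse = "-")) {
      paste(types, collapse = "-")
    } else paste(r, collapse = "-")
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && A[i, j] && !has_row(params$bond, ty[c(i, j)])) {
      missing <- c(missing, paste("bond", canon(ty[c(i, j)])))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i >= k || j == i || j == k || !A[i, j] || !A[j, k]) next
    if (!has_row(params$angle, ty[c(i, j, k)])) {
      missing <- c(missing, paste("angle", canon(ty[c(i, j, k)])))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (j >= k) next
      if (length(unique(c(i, j, k, l))) != 4) next
      if (!(A[i, j] && A[j, k] && A[k, l])) next
      tt <- ty[c(i, j, k, l)]
      if (has_row(params$dihedral, tt)) next
      if (has_row(params$dihedral, c("X", tt[2], tt[3], "X"))) next
      missing <- c(missing, paste("dihedral", canon(tt)))
    }
  }
  sort(unique(missing))
}

# Brute-force O(N^2) clash enumeration between a set of new atoms and the
# rest, with a bonded/1-3 exclusion list passed in explicitly.
oracle_clash <- function(s, new_idx, threshold, excluded_pairs) {
  heavy <- toupper(s$atoms$element) != "H"
  hits <- list()
  for (i in new_idx[heavy[new_idx]]) {
    for (j in setdiff(which(heavy), new_idx)) {
      d <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
      if (d >= threshold) next
      key <- paste(sort(c(s$atoms$name[i], s$atoms$name[j])), collapse = "-")
      if (key %in% excluded_pairs) next
      hits[[length(hits) + 1]] <- c(i, j, d)
    }
  }
  hits
}

# random rigid motion (proper rotation + translation), seeded by caller
random_rigid_motion <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, rt$t, "+")

# adjusted Rand index without external packages (used where mclust is absent)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}
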