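# Deterministic synthetic-fixture generators: toy peptides, seeded
# perturbation ("wobble") trajectories, two-state mixtures with known labels,
# and point-charge ESP grids. Every generator is a pure function of its
# arguments -- a fixed seed reproduces output bit for bit. These fixtures
# emulate the statistical structure the analyses consume, not force-field
# physics.

# run code under a fixed Mersenne-Twister seed, restoring the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

.toy_sidechains <- list(
  A = list(
    c("CB", "CA", "C", "N", 1.53, 111.0, 122.5),
    c("HB1", "CB", "CA", "N", 1.09, 109.5, 60),
    c("HB2", "CB", "CA", "N", 1.09, 109.5, 180),
    c("HB3", "CB", "CA", "N", 1.09, 109.5, -60)
  ),
  G = list(),
  C = list(
    c("CB", "CA", "C", "N", 1.53, 111.0, 122.5),
    c("SG", "CB", "CA", "N", 1.81, 108.6, -60),
    c("HB2", "CB", "CA", "N", 1.09, 109.5, 60),
    c("HB3", "CB", "CA", "N", 1.09, 109.5, 180),
    c("HG", "SG", "CB", "CA", 1.34, 96.0, 180)
  )
)
.toy_resnames <- c(A = "ALA", G = "GLY", C = "CYS")

#' Build a toy peptide structure
#'
#' Chemically complete extended-chain peptide (phi = -135, psi = 135, omega =
#' 180) from ideal internal coordinates, supporting alanine, glycine and
#' cysteine. Optionally S-glutathionylates one cysteine via
#' [graft_glutathione()], giving a complete CSG residue. Deterministic: the
#' same arguments always give bit-identical coordinates.
#'
#' @param sequence 1-letter string over `{A, G, C}`, e.g. `"ACA"`.
#' @param include_csg_at optional residue position to glutathionylate (must
#'   hold `C`).
#' @param chain chain identifier (default `"A"`).
#' @param chi_ss S-S dihedral passed to the graft when `include_csg_at` is
#'   set.
#' @return a `csg_structure`.
#' @examples
#' s <- make_toy_peptide("ACA", include_csg_at = 2)
#' unique(s$atoms$resname)
#' @export
make_toy_peptide <- function(sequence, include_csg_at = NULL, chain = "A",
                             chi_ss = 90) {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  if (length(letters1) == 0L) stop("empty sequence")
  bad <- setdiff(letters1, names(.toy_resnames))
  if (length(bad) > 0L) {
    stop("unsupported residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  if (!is.null(include_csg_at)) {
    p <- as.integer(include_csg_at)
    if (p < 1L || p > length(letters1) || letters1[p] != "C") {
      stop("include_csg_at must point at a C (cysteine) position")
    }
  }
  phi <- -135; psi <- 135; omega <- 180
  rows <- list()  # name, resid, xyz
  pos_prev <- NULL  # list(N, CA, C) of previous residue
  addr <- function(name, resid, p) {
    rows[[length(rows) + 1L]] <<- list(name = name, resid = resid, p = p)
  }
  for (i in seq_along(letters1)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- .place_atom(CA, N, N + c(0, 0, 1), 1.52, 111.0, 60)
    } else {
      N <- .place_atom(pos_prev$C, pos_prev$CA, pos_prev$N, 1.33, 116.0, psi)
      CA <- .place_atom(N, pos_prev$C, pos_prev$CA, 1.46, 122.0, omega)
      C <- .place_atom(CA, N, pos_prev$C, 1.52, 111.0, phi)
    }
    addr("N", i, N); addr("CA", i, CA); addr("C", i, C)
    O_t <- if (i < length(letters1)) psi - 180 else psi
    addr("O", i, .place_atom(C, CA, N, 1.23, 121.0, O_t))
    if (i == length(letters1)) {
      addr("OXT", i, .place_atom(C, CA, N, 1.25, 117.0, psi - 180))
    }
    if (i == 1L) {
      addr("H", i, .place_atom(N, CA, C, 1.01, 118.0, 60))
    } else {
      addr("H", i, .place_atom(N, pos_prev$C, pos_prev$CA, 1.01, 119.0, 0))
    }
    if (letters1[i] == "G") {
      addr("HA2", i, .place_atom(CA, C, N, 1.09, 109.5, 122.5))
      addr("HA3", i, .place_atom(CA, C, N, 1.09, 109.5, -119))
    } else {
      addr("HA", i, .place_atom(CA, C, N, 1.09, 108.0, -119))
    }
    pos_res <- list(N = N, CA = CA, C = C)
    for (sc in .toy_sidechains[[letters1[i]]]) {
      refs <- lapply(sc[2:4], function(r) {
        hit <- Filter(function(x) x$resid == i && x$name == r, rows)
        if (length(hit) > 0L) hit[[length(hit)]]$p else pos_res[[r]]
      })
      p <- .place_atom(refs[[1L]], refs[[2L]], refs[[3L]],
                       as.numeric(sc[5L]), as.numeric(sc[6L]),
                       as.numeric(sc[7L]))
      addr(sc[1L], i, p)
    }
    pos_prev <- pos_res
  }
  atoms <- data.frame(
    name = vapply(rows, `[[`, character(1L), "name"),
    resname = .toy_resnames[letters1[vapply(rows, `[[`, numeric(1L), "resid")]],
    resid = vapply(rows, `[[`, numeric(1L), "resid"),
    chain = chain, stringsAsFactors = FALSE
  )
  xyz <- do.call(rbind, lapply(rows, `[[`, "p"))
  s <- structure_model(atoms, xyz, title = paste0("toy peptide ", sequence))
  if (!is.null(include_csg_at)) {
    s <- graft_glutathione(s, graft_spec(chain, include_csg_at,
                                         chi_ss = chi_ss))
  }
  s
}

#' Seeded Gaussian "wobble" trajectory around a reference
#'
#' Every frame is the reference plus i.i.d. Gaussian noise of standard
#' deviation `sigma` on each coordinate, so the expected unfitted RMSD per
#' frame is `sigma * sqrt(3)`. A desk-scale stand-in for thermal fluctuation
#' around a well-defined conformation.
#'
#' @param ref a `csg_structure`.
#' @param sigma per-coordinate noise, Angstrom (>= 0).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a `csg_trajectory`.
#' @export
make_wobble_trajectory <- function(ref, sigma, n_frames, seed = 1L) {
  stopifnot(inherits(ref, "csg_structure"), sigma >= 0, n_frames >= 1L)
  N <- nrow(ref$xyz)
  frames <- .with_seed(seed, {
    arr <- array(NA_real_, c(n_frames, N, 3L))
    for (f in seq_len(n_frames)) {
      arr[f, , ] <- ref$xyz + matrix(stats::rnorm(3L * N, sd = sigma), N, 3L)
    }
    arr
  })
  trajectory(ref, frames)
}

#' Two-state mixture trajectory with known labels
#'
#' Frames drawn around two reference conformers with per-coordinate Gaussian
#' noise. The per-state frame counts are allocated deterministically
#' (`round(fraction * n_frames)`, remainder to the first state) and shuffled
#' by the seed; the generating labels are returned for oracle scoring of
#' clustering.
#'
#' @param ref_a,ref_b `csg_structure`s with identical topology.
#' @param fractions length-2 fractions summing to 1 (default `c(0.6, 0.4)`).
#' @param sigma per-coordinate noise, Angstrom.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return list with `trajectory` (a `csg_trajectory`) and `labels`
#'   (per-frame 1/2).
#' @export
make_two_state_trajectory <- function(ref_a, ref_b, fractions = c(0.6, 0.4),
                                      sigma = 0.1, n_frames = 100L,
                                      seed = 1L) {
  stopifnot(inherits(ref_a, "csg_structure"), inherits(ref_b, "csg_structure"))
  if (!identical(dim(ref_a$xyz), dim(ref_b$xyz)) ||
      !identical(ref_a$atoms$name, ref_b$atoms$name)) {
    stop("ref_a and ref_b topologies differ")
  }
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 2L) {
    stop("fractions must be two values summing to 1")
  }
  n_a <- round(fractions[1L] * n_frames)
  labels0 <- rep(c(1L, 2L), times = c(n_a, n_frames - n_a))
  N <- nrow(ref_a$xyz)
  refs <- list(ref_a$xyz, ref_b$xyz)
  out <- .with_seed(seed, {
    perm <- sample.int(n_frames)
    labels <- labels0[perm]
    arr <- array(NA_real_, c(n_frames, N, 3L))
    for (f in seq_len(n_frames)) {
      arr[f, , ] <- refs[[labels[f]]] +
        matrix(stats::rnorm(3L * N, sd = sigma), N, 3L)
    }
    list(arr = arr, labels = labels)
  })
  list(trajectory = trajectory(ref_a, out$arr), labels = out$labels)
}

# deterministic quasi-uniform points on a unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  if (n < 1L) return(matrix(numeric(0), 0L, 3L))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Synthetic ESP grid from known point charges
#'
#' Builds a Merz-Singh-Kollman-style shell grid around the atoms
#' (quasi-uniform points on scaled van der Waals spheres, points falling
#' inside any other atom's same-scale shell removed) and evaluates the exact
#' Coulomb potential of the given charges at every point. The generating
#' charges are the natural oracle for RESP recovery tests.
#'
#' @param charges `csg_charges` (or named vector), elementary charge.
#' @param positions M x 3 atom coordinates, Angstrom, rownames optional.
#' @param shells shell scale factors (default `c(1.4, 1.6, 1.8, 2.0)` x vdW).
#' @param density surface point density, points per Angstrom^2 (default 1).
#' @param seed integer seed for the random orientation of each shell lattice.
#' @param elements element symbols (default inferred from charge names).
#' @return a `csg_esp_grid` (atomic units).
#' @export
make_esp_grid <- function(charges, positions, shells = c(1.4, 1.6, 1.8, 2.0),
                          density = 1.0, seed = 1L, elements = NULL) {
  charges <- charge_set(charges)
  positions <- as.matrix(positions)
  M <- length(charges)
  stopifnot(nrow(positions) == M)
  if (is.null(elements)) elements <- element_from_name(names(charges))
  rad <- vdw_radius(elements)
  pts <- .with_seed(seed, {
    acc <- list()
    for (srow in shells) {
      # one random rotation per shell scale, shared by all atoms
      ax <- stats::rnorm(3L); ax <- ax / .vnorm(ax)
      ang <- stats::runif(1L, 0, 2 * pi)
      K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L], -ax[2L], ax[1L], 0),
                  3L, 3L, byrow = TRUE)
      R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      for (j in seq_len(M)) {
        r <- srow * rad[j]
        n <- max(4L, round(density * 4 * pi * r^2))
        sph <- .fibonacci_sphere(n) %*% t(R) * r
        p <- sweep(sph, 2L, positions[j, ], "+")
        # drop points inside any other atom's shell at the same scale
        keep <- rep(TRUE, nrow(p))
        for (k in seq_len(M)) {
          if (k == j) next
          d <- sqrt(rowSums(sweep(p, 2L, positions[k, ])^2))
          keep <- keep & d >= srow * rad[k]
        }
        acc[[length(acc) + 1L]] <- p[keep, , drop = FALSE]
      }
    }
    do.call(rbind, acc)
  })
  if (nrow(pts) < M) stop("grid construction produced too few points")
  pts_bohr <- pts * .bohr_per_angstrom
  pos_bohr <- positions * .bohr_per_angstrom
  V <- rep(0, nrow(pts_bohr))
  for (j in seq_len(M)) {
    V <- V + charges[j] / sqrt(rowSums(sweep(pts_bohr, 2L, pos_bohr[j, ])^2))
  }
  esp_grid(pos_bohr, names(charges), pts_bohr, V)
}
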