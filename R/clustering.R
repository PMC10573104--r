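# Conformational clustering of trajectory ensembles: all-vs-all best-fit RMSD
# matrix, average-linkage agglomerative clustering (stats::hclust) with an
# epsilon or k termination, occupancy percentages and representative frames.

#' All-vs-all best-fit RMSD matrix
#'
#' Entry (i, j) is the Kabsch best-fit RMSD between frames i and j over the
#' selection. Symmetric with a zero diagonal.
#'
#' @param traj a `csg_trajectory` with at least 2 frames.
#' @param sel selection string (default `"backbone"`).
#' @param stride keep every `stride`-th frame (default 1 = all frames).
#' @return F x F numeric matrix (Angstrom); attribute `"frames"` holds the
#'   original frame indices when `stride > 1`.
#' @export
pairwise_rmsd_matrix <- function(traj, sel = "backbone", stride = 1L) {
  stopifnot(inherits(traj, "csg_trajectory"))
  keep <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (length(keep) < 2L) stop("need at least 2 frames")
  idx <- select_atoms(traj, sel)
  F <- length(keep)
  coords <- lapply(keep, function(f) {
    xyz <- traj$frames[f, idx, , drop = TRUE]
    dim(xyz) <- c(length(idx), 3L)
    xyz
  })
  # best-fit RMSD from the covariance singular values:
  # rmsd^2 = (tr(X'X) + tr(Y'Y) - 2 (s1 + s2 +/- s3)) / N, the sign of s3
  # following det(H) (proper-rotation correction)
  N <- length(idx)
  centered <- lapply(coords, function(x) sweep(x, 2L, colMeans(x)))
  tra <- vapply(centered, function(x) sum(x * x), numeric(1L))
  D <- matrix(0, F, F)
  for (i in seq_len(F - 1L)) {
    Xi <- centered[[i]]
    for (j in seq(i + 1L, F)) {
      H <- crossprod(Xi, centered[[j]])
      s <- svd(H, nu = 0L, nv = 0L)$d
      if (det(H) < 0) s[3L] <- -s[3L]
      msd <- (tra[i] + tra[j] - 2 * sum(s)) / N
      r <- sqrt(max(0, msd))
      if (r < 1e-3) {
        # the trace difference cancels catastrophically near zero; redo the
        # few near-identical pairs through the explicit superposition
        r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
      }
      D[i, j] <- D[j, i] <- r
    }
  }
  attr(D, "frames") <- keep
  D
}

#' Cluster frames from a distance matrix
#'
#' Average-linkage agglomerative clustering. Merging stops when the smallest
#' inter-cluster (average-linkage) distance exceeds `eps`, or when `k`
#' clusters remain; give exactly one of the two. Clusters are numbered by
#' descending occupancy (ties broken by the lowest member frame index); each
#' cluster's representative is the member frame minimizing the mean distance
#' to its co-members.
#'
#' @param dist F x F symmetric distance matrix (Angstrom).
#' @param eps distance cutoff (Angstrom); default 2.0 when `k` is absent.
#' @param k target number of clusters (overrides `eps`).
#' @return object of class `csg_clusters`: `labels` (per-frame id),
#'   `occupancy` (per-cluster %, descending), `representative` (per-cluster
#'   frame index), `n_clusters`.
#' @export
cluster_frames <- function(dist, eps = NULL, k = NULL) {
  dist <- as.matrix(dist)
  F <- nrow(dist)
  if (F < 2L) stop("need at least 2 frames to cluster")
  if (!is.null(eps) && !is.null(k)) stop("give exactly one of eps / k")
  if (is.null(eps) && is.null(k)) eps <- 2.0
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  # average linkage is monotone up to floating-point noise; enforce it so
  # cutree accepts near-degenerate (e.g. all-zero) distance matrices
  hc$height <- cummax(hc$height)
  raw <- if (!is.null(k)) {
    stats::cutree(hc, k = min(k, F))
  } else {
    stats::cutree(hc, h = eps)
  }
  sizes <- tabulate(raw)
  first_member <- vapply(seq_along(sizes), function(c) which(raw == c)[1L],
                         integer(1L))
  ord <- order(-sizes, first_member)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  labels <- relabel[raw]
  nc <- length(sizes)
  occupancy <- 100 * sizes[ord] / F
  representative <- vapply(seq_len(nc), function(c) {
    mem <- which(labels == c)
    if (length(mem) == 1L) return(mem)
    mem[which.min(rowMeans(dist[mem, mem, drop = FALSE]))]
  }, integer(1L))
  frames_attr <- attr(dist, "frames")
  if (!is.null(frames_attr)) representative <- frames_attr[representative]
  base::structure(
    list(labels = labels, occupancy = occupancy,
         representative = representative, n_clusters = nc),
    class = "csg_clusters"
  )
}

#' @export
print.csg_clusters <- function(x, ...) {
  cat("<csg_clusters> ", x$n_clusters, " clusters; occupancy ",
      paste(sprintf("%.1f%%", x$occupancy), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract cluster-representative structures
#'
#' @param traj the clustered `csg_trajectory`.
#' @param result a `csg_clusters` from [cluster_frames()].
#' @return list of `csg_structure`, one per cluster, ordered by descending
#'   occupancy; coordinates are bit-equal to the representative frames.
#' @export
extract_representatives <- function(traj, result) {
  stopifnot(inherits(result, "csg_clusters"))
  lapply(result$representative, function(f) get_frame(traj, f))
}
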