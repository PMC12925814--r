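# Periodic-boundary geometry shared by all trajectory metrics.
# Orthorhombic boxes only; distances in nm.

#' Minimum-image displacement vectors
#'
#' @param a,b numeric matrices (n x 3) or length-3 vectors, positions in nm.
#' @param box orthorhombic box edges (length 3, nm) or `NULL` for open
#'   boundaries.
#' @return n x 3 matrix of displacements b - a mapped to the nearest image
#' @export
min_image_displacement <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- b - a
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

#' Minimum-image distance between two positions
#'
#' With a periodic box this is the Euclidean distance to the nearest
#' periodic image (never larger than the open-boundary distance); without
#' a box it is the plain Euclidean distance.
#'
#' @inheritParams min_image_displacement
#' @return numeric distance(s) in nm
#' @export
min_image_distance <- function(a, b, box = NULL) {
  d <- min_image_displacement(a, b, box)
  sqrt(rowSums(d * d))
}

# All pairwise squared distances between row sets A (n x 3) and B (m x 3)
# under the minimum-image convention. Returns n x m matrix.
cross_dist2 <- function(A, B, box = NULL) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

#' Particle pairs within a distance cutoff
#'
#' Finds all pairs between two selections whose minimum-image distance is
#' less than or equal to `cutoff` (inclusive boundary). When the two
#' selections are identical each unordered pair is reported once
#' (`id_a < id_b`), and pairs within one molecule can be excluded.
#'
#' @param frame an [md_frame()]
#' @param system the owning [molecular_system()]
#' @param selection_a,selection_b integer row indices into the particle
#'   table (see [select_particles()]).
#' @param cutoff distance cutoff in nm.
#' @param exclude_same_molecule drop pairs whose particles share a
#'   molecule (applies when the selections are identical, and also
#'   filters cross-selection pairs when requested).
#' @return data.frame with columns `id_a`, `id_b` (particle ids) and
#'   `dist` (nm); zero rows when a selection is empty.
#' @export
neighbor_pairs <- function(frame, system, selection_a, selection_b,
                           cutoff, exclude_same_molecule = FALSE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  empty <- data.frame(id_a = integer(), id_b = integer(), dist = numeric())
  if (!length(selection_a) || !length(selection_b)) return(empty)
  p <- system$particles
  X <- frame$coords
  identical_sel <- length(selection_a) == length(selection_b) &&
    all(selection_a == selection_b)
  d2 <- cross_dist2(X[selection_a, , drop = FALSE],
                    X[selection_b, , drop = FALSE], frame$box)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ia <- selection_a[hit[, 1]]
  ib <- selection_b[hit[, 2]]
  keep <- rep(TRUE, length(ia))
  if (identical_sel) keep <- ia < ib          # unordered, no self pairs
  if (exclude_same_molecule)
    keep <- keep & p$molecule_id[ia] != p$molecule_id[ib]
  if (!any(keep)) return(empty)
  data.frame(id_a = p$particle_id[ia[keep]],
             id_b = p$particle_id[ib[keep]],
             dist = sqrt(d2[hit][keep]))
}

# angle in degrees between two vectors
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# centroid and best-fit plane normal of >= 3 ring sites;
# normal = direction of least coordinate variance
ring_geometry <- function(coords) {
  if (nrow(coords) < 3L) stop("ring needs at least 3 sites")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-12)
    stop("ring sites are collinear; plane normal undefined")
  list(centroid = ctr, normal = ev$vectors[, 3])
}
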