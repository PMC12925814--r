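# Receptor-peptide interface metrics: Kabsch least-squares superposition
# and RMSD series, residue contact maps against named chemical groups,
# geometric interaction detectors (cation-pi, pi-stacking, hydrogen
# bond, salt bridge) with occupancy statistics, and Spearman correlation
# between contact profiles.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation that minimise
#' the squared deviation of `mobile[fit_subset, ]` from
#' `reference[fit_subset, ]`, then reports the RMSD over
#' `measure_subset` after applying the transform to the mobile set.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm) indexed
#'   identically.
#' @param fit_subset row indices used to fit the transform (>= 3
#'   non-collinear points).
#' @param measure_subset row indices over which RMSD is evaluated
#'   (default: the fit subset).
#' @return list with `rotation` (3 x 3), `translation` (length 3, applied
#'   after rotation), `rmsd` (nm) and `transformed` (the full mobile set
#'   after superposition).
#' @export
kabsch_fit <- function(mobile, reference,
                       fit_subset = seq_len(nrow(mobile)),
                       measure_subset = fit_subset) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have equal particle counts")
  if (length(fit_subset) < 3L)
    stop("fit subset needs at least 3 points")
  P <- mobile[fit_subset, , drop = FALSE]
  Q <- reference[fit_subset, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("degenerate (collinear) fit set; rotation underdetermined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)           # y = R x + t
  tvec <- cq - as.vector(R %*% cp)
  transformed <- t(R %*% t(mobile)) + rep(tvec, each = nrow(mobile))
  dev <- transformed[measure_subset, , drop = FALSE] -
    reference[measure_subset, , drop = FALSE]
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums(dev * dev))),
       transformed = transformed)
}

#' RMSD time series after least-squares fitting
#'
#' Each frame is superposed on the reference frame using the fit
#' selection (e.g. the receptor backbone) and the RMSD is measured over
#' the measure selection (e.g. the whole peptide).
#'
#' @param traj a [trajectory()]
#' @param fit_selection,measure_selection particle-row indices
#' @param reference_frame index of the reference frame (default 1)
#' @return data.frame of class `rmsd_series` with columns `frame`,
#'   `time`, `rmsd` (nm)
#' @export
rmsd_series <- function(traj, fit_selection, measure_selection,
                        reference_frame = 1L) {
  ref <- traj$frames[[reference_frame]]$coords
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    kabsch_fit(traj$frames[[i]]$coords, ref,
               fit_subset = fit_selection,
               measure_subset = measure_selection)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(nf), time = frame_times(traj),
                    rmsd = vals)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Receptor-residue contact map against a chemical group
#'
#' Counts contacts between a peptide chemical group (e.g. the
#' guanidinium beads of the N-terminal arginine) and receptor particles
#' over all frames, attributed to the receptor residue, and normalised
#' to percentages summing to 100. Raw counts are retained.
#'
#' @param traj a [trajectory()]
#' @param group particle-row indices of the probing group (non-empty)
#' @param receptor particle-row indices of the receptor
#' @param cutoff contact cutoff in nm
#' @param mode `"events"` (default) or `"frames"`
#' @return data.frame of class `residue_contact_map` with columns
#'   `residue_index`, `residue_name`, `residue`, `count`,
#'   `contact_percentage`, sorted by residue index
#' @export
residue_group_contact_map <- function(traj, group, receptor, cutoff = 0.6,
                                      mode = c("events", "frames")) {
  mode <- match.arg(mode)
  if (!length(group)) stop("empty probing group")
  if (!length(receptor)) stop("empty receptor selection")
  p <- traj$system$particles
  key <- paste0(p$residue_name[receptor], p$residue_index[receptor])
  counts <- numeric(0)
  for (i in seq_len(n_frames(traj))) {
    pairs <- neighbor_pairs(traj$frames[[i]], traj$system, group,
                            receptor, cutoff)
    if (!nrow(pairs)) next
    rec_rows <- match(pairs$id_b, p$particle_id)
    kk <- paste0(p$residue_name[rec_rows], p$residue_index[rec_rows])
    if (mode == "frames") kk <- unique(kk)
    tab <- table(kk)
    for (nm in names(tab))
      counts[nm] <- if (nm %in% names(counts)) counts[nm] + tab[[nm]]
                    else tab[[nm]]
  }
  all_res <- !duplicated(key)
  out <- data.frame(residue_index = p$residue_index[receptor][all_res],
                    residue_name = p$residue_name[receptor][all_res],
                    residue = key[all_res])
  out$count <- ifelse(out$residue %in% names(counts),
                      counts[out$residue], 0)
  total <- sum(out$count)
  out$contact_percentage <- if (total > 0) 100 * out$count / total
                            else out$count
  out <- out[order(out$residue_index), ]
  rownames(out) <- NULL
  attr(out, "no_contacts") <- total == 0
  class(out) <- c("residue_contact_map", "data.frame")
  out
}

#' Top contacting receptor residues
#'
#' @param map a `residue_contact_map`
#' @param k number of residues to report
#' @return the k rows with the highest contact percentage
#' @export
top_contacts <- function(map, k = 5L) {
  map <- map[order(-map$contact_percentage, map$residue_index), ]
  utils::head(map, k)
}

#' Detect a cation-pi interaction in one frame
#'
#' True when the distance between the cation-group centroid and the ring
#' centroid is within the cutoff and the angle between the ring normal
#' and the centroid-to-cation vector is within `max_angle` (the cation
#' sits over the ring face, not in its plane).
#'
#' @param frame an [md_frame()]
#' @param cation particle-row indices of the cation group (centroid used)
#' @param ring particle-row indices of the aromatic ring (>= 3)
#' @param cutoff centroid distance cutoff in nm
#' @param max_angle maximal face angle in degrees
#' @return list(`present`, `distance` nm, `angle` degrees)
#' @export
detect_cation_pi <- function(frame, cation, ring, cutoff = 0.6,
                             max_angle = 45) {
  if (!length(cation)) stop("empty cation group")
  rg <- ring_geometry(frame$coords[ring, , drop = FALSE])
  cat_ctr <- colMeans(frame$coords[cation, , drop = FALSE])
  v <- cat_ctr - rg$centroid
  dist <- sqrt(sum(v * v))
  ang <- vec_angle(v, rg$normal)
  ang <- min(ang, 180 - ang)            # normal orientation is arbitrary
  list(present = dist <= cutoff && ang <= max_angle,
       distance = dist, angle = ang)
}

#' Detect parallel pi-stacking between two rings in one frame
#'
#' True when the ring centroids are within the cutoff and the angle
#' between the two ring planes is within `max_angle` (parallel mode).
#'
#' @param frame an [md_frame()]
#' @param ring_a,ring_b particle-row indices of the rings (>= 3 each)
#' @param cutoff centroid distance cutoff in nm
#' @param max_angle maximal inter-plane angle in degrees
#' @return list(`present`, `distance` nm, `angle` degrees)
#' @export
detect_pi_stacking <- function(frame, ring_a, ring_b, cutoff = 0.55,
                               max_angle = 30) {
  ga <- ring_geometry(frame$coords[ring_a, , drop = FALSE])
  gb <- ring_geometry(frame$coords[ring_b, , drop = FALSE])
  v <- gb$centroid - ga$centroid
  dist <- sqrt(sum(v * v))
  ang <- vec_angle(ga$normal, gb$normal)
  ang <- min(ang, 180 - ang)
  list(present = dist <= cutoff && ang <= max_angle,
       distance = dist, angle = ang)
}

#' Detect a hydrogen bond in one frame
#'
#' With an explicit hydrogen: donor-acceptor distance within the cutoff
#' and donor-hydrogen-acceptor angle at least `min_angle`. Without a
#' hydrogen (coarse-grained mode) the distance criterion alone is used
#' and the result is flagged `distance_only`.
#'
#' @param frame an [md_frame()]
#' @param donor,acceptor single particle-row indices (must differ)
#' @param hydrogen single particle-row index or `NULL`
#' @param cutoff donor-acceptor cutoff in nm
#' @param min_angle minimal D-H-A angle in degrees
#' @return list(`present`, `distance` nm, `angle` (degrees or `NA`),
#'   `distance_only`)
#' @export
detect_hbond <- function(frame, donor, acceptor, hydrogen = NULL,
                         cutoff = 0.35, min_angle = 120) {
  if (donor == acceptor) stop("donor and acceptor must differ")
  X <- frame$coords
  dist <- sqrt(sum((X[donor, ] - X[acceptor, ])^2))
  if (is.null(hydrogen)) {
    return(list(present = dist <= cutoff, distance = dist,
                angle = NA_real_, distance_only = TRUE))
  }
  ang <- vec_angle(X[donor, ] - X[hydrogen, ], X[acceptor, ] - X[hydrogen, ])
  list(present = dist <= cutoff && ang >= min_angle,
       distance = dist, angle = ang, distance_only = FALSE)
}

#' Detect a salt bridge (charged-group distance criterion)
#'
#' @param frame an [md_frame()]
#' @param group_a,group_b particle-row indices of the two charged groups
#' @param cutoff centroid distance cutoff in nm
#' @return list(`present`, `distance` nm)
#' @export
detect_salt_bridge <- function(frame, group_a, group_b, cutoff = 0.45) {
  ca <- colMeans(frame$coords[group_a, , drop = FALSE])
  cb <- colMeans(frame$coords[group_b, , drop = FALSE])
  dist <- sqrt(sum((ca - cb)^2))
  list(present = dist <= cutoff, distance = dist)
}

#' Specify a geometric interaction for occupancy analysis
#'
#' @param kind one of `"cation_pi"`, `"pi_stacking"`, `"hbond"`,
#'   `"salt_bridge"`
#' @param a,b particle-row index sets for the two partners (cation/ring,
#'   ring/ring, donor/acceptor, group/group)
#' @param hydrogen optional hydrogen row index (hbond only)
#' @param label human-readable partner label (e.g. "R1:W45")
#' @param ... criteria overrides passed to the detector
#'   (`cutoff`, `max_angle`, `min_angle`)
#' @return object of class `interaction_spec`
#' @export
interaction_spec <- function(kind = c("cation_pi", "pi_stacking",
                                      "hbond", "salt_bridge"),
                             a, b, hydrogen = NULL, label = "", ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, a = a, b = b, hydrogen = hydrogen,
                 label = label, criteria = list(...)),
            class = "interaction_spec")
}

#' Occupancy of a geometric interaction over a trajectory
#'
#' Applies the detector named by the spec to every frame and summarises
#' the boolean series: occupancy (fraction of frames present), mean
#' distance, and the longest uninterrupted event length in frames.
#'
#' @param traj a [trajectory()]
#' @param spec an [interaction_spec()]
#' @return object of class `interaction_occupancy`: list with `kind`,
#'   `label`, `series` (logical per frame), `distances` (nm per frame),
#'   `occupancy`, `mean_distance`, `longest_event` and the `criteria`
#'   used.
#' @export
occupancy_series <- function(traj, spec) {
  stopifnot(inherits(spec, "interaction_spec"))
  nf <- n_frames(traj)
  present <- logical(nf); dists <- numeric(nf)
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    res <- switch(spec$kind,
      cation_pi = do.call(detect_cation_pi,
                          c(list(f, spec$a, spec$b), spec$criteria)),
      pi_stacking = do.call(detect_pi_stacking,
                            c(list(f, spec$a, spec$b), spec$criteria)),
      hbond = do.call(detect_hbond,
                      c(list(f, spec$a, spec$b, spec$hydrogen),
                        spec$criteria)),
      salt_bridge = do.call(detect_salt_bridge,
                            c(list(f, spec$a, spec$b), spec$criteria)))
    present[i] <- res$present
    dists[i] <- res$distance
  }
  runs <- rle(present)
  longest <- if (any(present)) max(runs$lengths[runs$values]) else 0L
  structure(list(kind = spec$kind, label = spec$label,
                 series = present, distances = dists,
                 occupancy = mean(present),
                 mean_distance = mean(dists),
                 longest_event = as.integer(longest),
                 criteria = spec$criteria),
            class = "interaction_occupancy")
}

#' @export
print.interaction_occupancy <- function(x, ...) {
  cat(sprintf("%s %s: occupancy %.3f over %d frames (longest event %d)\n",
              x$kind, x$label, x$occupancy, length(x$series),
              x$longest_event))
  invisible(x)
}

#' Spearman correlation between two residue contact profiles
#'
#' Joins the two maps on the union of receptor residues (absent entries
#' contribute 0%) and computes the Spearman rank correlation with
#' fractional (mid) ranks for ties.
#'
#' @param map_a,map_b `residue_contact_map` objects (or data.frames with
#'   `residue` and `contact_percentage` columns)
#' @return list with `rho` and `n` (joint residues)
#' @export
profile_spearman <- function(map_a, map_b) {
  keys <- union(map_a$residue, map_b$residue)
  if (length(keys) < 3L)
    stop("fewer than 3 joint receptor residues; correlation undefined")
  va <- map_a$contact_percentage[match(keys, map_a$residue)]
  vb <- map_b$contact_percentage[match(keys, map_b$residue)]
  va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
  list(rho = stats::cor(va, vb, method = "spearman"), n = length(keys))
}
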