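# Peptide-lipid aggregate metrics: per-residue head-group/tail contact
# profiles, Shrake-Rupley solvent-accessible surface area with a
# deterministic golden-spiral quadrature, and divalent-ion binding /
# displacement series.

#' Per-residue peptide-lipid contact profile
#'
#' Counts contact events (pairs within the cutoff, minimum image,
#' inclusive) between peptide particles and lipid particles carrying the
#' target group tag, over all frames. Events are attributed to the
#' peptide residue index and normalised to percentages summing to 100.
#'
#' @param traj a [trajectory()] with peptide and lipid molecules
#' @param target `"headgroup"` or `"tail"`
#' @param cutoff contact cutoff in nm
#' @param mode `"events"` (default) or `"frames"` (per residue: frames
#'   in contact).
#' @return data.frame of class `contact_profile` with columns
#'   `residue_index`, `residue_name`, `count`, `contact_percentage`;
#'   attributes `"target"` and `"no_contacts"`.
#' @export
residue_lipid_contacts <- function(traj, target = c("headgroup", "tail"),
                                   cutoff = 0.6,
                                   mode = c("events", "frames")) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  system <- traj$system
  p <- system$particles
  pep <- select_particles(system, kind = "peptide")
  lip <- select_particles(system, kind = "lipid", tag = target)
  if (!length(pep)) stop("system contains no peptide molecules")
  if (!length(lip))
    stop("no lipid particles tagged '", target,
         "'; run classify_groups() first")
  n_res <- max(p$residue_index[pep])
  counts <- numeric(n_res)
  for (i in seq_len(n_frames(traj))) {
    pairs <- neighbor_pairs(traj$frames[[i]], system, pep, lip, cutoff)
    if (!nrow(pairs)) next
    res <- p$residue_index[match(pairs$id_a, p$particle_id)]
    if (mode == "events") counts <- counts + tabulate(res, nbins = n_res)
    else counts <- counts + tabulate(unique(res), nbins = n_res)
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts
  resnames <- p$residue_name[pep][match(seq_len(n_res),
                                        p$residue_index[pep])]
  out <- data.frame(residue_index = seq_len(n_res),
                    residue_name = resnames,
                    count = counts,
                    contact_percentage = pct)
  attr(out, "target") <- target
  attr(out, "no_contacts") <- total == 0
  class(out) <- c("contact_profile", "data.frame")
  out
}

# deterministic golden-spiral points on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' Deterministic golden-spiral quadrature: for each selected particle,
#' the fraction of points on its solvent-expanded sphere (radius
#' `r_i + probe`) that are not strictly inside any occluder's expanded
#' sphere, times `4 pi (r_i + probe)^2`. A point exactly on an occluding
#' sphere counts as exposed. Occluders default to every non-solvent
#' particle in the system (solvent never occludes: the probe represents
#' it).
#'
#' @param frame an [md_frame()]
#' @param system the owning [molecular_system()]; selected particles and
#'   occluders must have radii (see [assign_default_radii()]).
#' @param selection integer particle-row indices to measure
#' @param probe probe radius in nm
#' @param n_points quadrature points per sphere (>= 16)
#' @param occluders particle-row indices that can bury surface; default
#'   all particles whose residue name is not a known solvent name.
#' @return total SASA of the selection in nm^2
#' @export
shrake_rupley_sasa <- function(frame, system, selection, probe = 0.26,
                               n_points = 96L, occluders = NULL) {
  if (n_points < 16L) stop("n_points must be >= 16")
  if (probe <= 0) stop("probe radius must be > 0")
  p <- system$particles
  if (is.null(occluders))
    occluders <- which(!p$residue_name %in% SOLVENT_NAMES)
  need <- union(selection, occluders)
  nr <- need[is.na(p$radius[need])]
  if (length(nr))
    stop("missing radius for particle(s): ",
         paste(utils::head(p$particle_id[nr], 10L), collapse = ", "),
         if (length(nr) > 10L) " ..." else "")
  X <- frame$coords
  box <- frame$box
  pts <- golden_spiral_points(n_points)
  total <- 0
  rad <- p$radius
  occ_r <- rad[occluders] + probe
  max_occ <- max(occ_r)
  for (i in selection) {
    ri <- rad[i] + probe
    # occluders close enough to possibly bury points of sphere i
    d2 <- cross_dist2(X[i, , drop = FALSE],
                      X[occluders, , drop = FALSE], box)[1, ]
    near <- occluders[occluders != i & d2 < (ri + max_occ)^2]
    if (!length(near)) {
      total <- total + 4 * pi * ri^2
      next
    }
    sphere <- sweep(pts * ri, 2, X[i, ], "+")
    dd <- cross_dist2(sphere, X[near, , drop = FALSE], box)
    r2 <- (rad[near] + probe)^2
    buried <- rowSums(sweep(dd, 2, r2, "<")) > 0   # strictly inside
    total <- total + 4 * pi * ri^2 * mean(!buried)
  }
  total
}

#' SASA time series over a trajectory
#'
#' @inheritParams shrake_rupley_sasa
#' @param traj a [trajectory()]
#' @param label selection label recorded in the result
#' @return data.frame of class `sasa_series` with columns `frame`,
#'   `time`, `sasa` (nm^2); attributes `probe_radius`, `n_points`,
#'   `label`.
#' @export
sasa_series <- function(traj, selection, probe = 0.26, n_points = 96L,
                        occluders = NULL, label = "selection") {
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i)
    shrake_rupley_sasa(traj$frames[[i]], traj$system, selection,
                       probe, n_points, occluders), numeric(1))
  out <- data.frame(frame = seq_len(nf), time = frame_times(traj),
                    sasa = vals)
  attr(out, "probe_radius") <- probe
  attr(out, "n_points") <- as.integer(n_points)
  attr(out, "label") <- label
  class(out) <- c("sasa_series", "data.frame")
  out
}

#' Ion binding and displacement series
#'
#' An ion is bound in a frame when it lies within the cutoff of any
#' anchor-tagged particle (default: phosphate). The displaced count is
#' measured relative to the first frame's bound count and floored at 0;
#' the full bound-count series is returned so alternative definitions
#' can be derived.
#'
#' @param traj a [trajectory()]
#' @param ions particle-row indices of the ions (default: all particles
#'   of molecule kind `ion`).
#' @param anchor_tag group tag of the binding partners
#' @param cutoff binding distance cutoff in nm
#' @return data.frame of class `ion_binding_series` with columns
#'   `frame`, `time`, `bound_count`, `displaced_count`
#' @export
ion_binding_series <- function(traj, ions = NULL,
                               anchor_tag = "phosphate", cutoff = 0.6) {
  system <- traj$system
  if (is.null(ions)) ions <- select_particles(system, kind = "ion")
  if (!length(ions)) stop("no ions in the system")
  anchors <- select_particles(system, tag = anchor_tag)
  if (!length(anchors))
    stop("no particles tagged '", anchor_tag, "'")
  nf <- n_frames(traj)
  bound <- integer(nf)
  for (i in seq_len(nf)) {
    d2 <- cross_dist2(traj$frames[[i]]$coords[ions, , drop = FALSE],
                      traj$frames[[i]]$coords[anchors, , drop = FALSE],
                      traj$frames[[i]]$box)
    bound[i] <- sum(apply(d2 <= cutoff^2, 1, any))
  }
  out <- data.frame(frame = seq_len(nf), time = frame_times(traj),
                    bound_count = bound,
                    displaced_count = pmax(0L, bound[1] - bound))
  class(out) <- c("ion_binding_series", "data.frame")
  out
}
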