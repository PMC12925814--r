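# Synthetic-data generators with planted ground truth. Structure is
# planted geometrically/combinatorially, not via force fields: the
# analyses, not the dynamics, are under test. Every generator is
# seed-deterministic and returns its ground truth alongside the data.

SHVF18_SEQ <- "HVFRLKKWIXKVIXQFGE"

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

# rigid bead-rod peptide: beads on a line, 0.35 nm spacing
rod_coords <- function(origin, direction, n_beads, spacing = 0.35) {
  sweep(outer(seq_len(n_beads) - 1, direction * spacing), 2, origin, "+")
}

wrap_box <- function(X, box) {
  for (k in 1:3) X[, k] <- X[, k] %% box[k]
  X
}

#' Generate a multi-peptide solution trajectory (aggregation study)
#'
#' Rigid bead-rod peptides performing random-walk moves in a periodic
#' box. With `sticky > 0`, peptide bodies drift toward their nearest
#' neighbour at `0.2 * sticky` nm per frame and merge irreversibly into
#' co-moving bodies when any bead pair comes within the capture radius
#' (default 0.6 nm, the contact cutoff, so a detected contact is always
#' an irreversible merge; the merging body is snapped so the closest
#' bead pair sits at 0.4
#' nm); with `sticky = 0` the peptides are independent walkers. The
#' defaults emulate a solution self-assembly study: 10 peptide copies of
#' 18 residues in a 15 nm cubic box.
#'
#' @param n_peptides number of peptide molecules (>= 2)
#' @param beads_per_peptide beads (residues) per peptide
#' @param sticky aggregation strength (>= 0; 0 disables merging)
#' @param n_frames frames to generate
#' @param box cubic box edges in nm
#' @param step random-walk step standard deviation, nm/frame
#' @param capture merge capture radius in nm
#' @param seed RNG seed
#' @param sequence one-letter sequence for the residue template
#' @return list with `trajectory` and `truth` (final largest cluster
#'   size, merge log, parameters)
#' @export
gen_aggregation <- function(n_peptides = 10L, beads_per_peptide = 18L,
                            sticky = 1, n_frames = 300L,
                            box = c(15, 15, 15), step = 0.15,
                            capture = 0.6, seed = 1L,
                            sequence = SHVF18_SEQ) {
  if (n_peptides < 2L) stop("need at least 2 peptides")
  if (nchar(sequence) != beads_per_peptide)
    sequence <- paste(rep("A", beads_per_peptide), collapse = "")
  with_seed(seed, {
    rod_len <- (beads_per_peptide - 1) * 0.35
    if (min(box) < rod_len + 2)
      stop("box too small to place peptides without overlap")
    # place rod origins with >= 2 nm separation (up to 2000 attempts)
    origins <- matrix(NA_real_, n_peptides, 3)
    placed <- 0L; attempts <- 0L
    while (placed < n_peptides) {
      attempts <- attempts + 1L
      if (attempts > 2000L)
        stop("box too small to place peptides without overlap")
      cand <- stats::runif(3) * box
      if (placed == 0L ||
          min(min_image_distance(origins[seq_len(placed), , drop = FALSE],
                                 matrix(cand, placed, 3, byrow = TRUE),
                                 box)) >= 2) {
        placed <- placed + 1L
        origins[placed, ] <- cand
      }
    }
    beads <- lapply(seq_len(n_peptides), function(m)
      rod_coords(origins[m, ], random_unit_vector(), beads_per_peptide))
    particles <- do.call(rbind, lapply(seq_len(n_peptides), function(m)
      peptide_template(sequence, molecule_id = m,
                       first_particle_id = (m - 1L) * beads_per_peptide + 1L)))
    system <- molecular_system(particles)
    body <- seq_len(n_peptides)       # co-moving body id per peptide
    merges <- list()
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      for (b in unique(body)) {
        members <- which(body == b)
        shift <- stats::rnorm(3, sd = step)
        if (sticky > 0 && length(unique(body)) > 1L) {
          ctr <- colMeans(do.call(rbind, beads[members]))
          others <- which(body != b)
          octr <- t(vapply(others, function(m) colMeans(beads[[m]]),
                           numeric(3)))
          d <- min_image_distance(matrix(ctr, nrow(octr), 3, byrow = TRUE),
                                  octr, box)
          target <- octr[which.min(d), ]
          dir <- min_image_displacement(ctr, target, box)[1, ]
          nrm <- sqrt(sum(dir * dir))
          if (nrm > 1e-9) shift <- shift + 0.2 * sticky * dir / nrm
        }
        for (m in members)
          beads[[m]] <- sweep(beads[[m]], 2, shift, "+")
      }
      if (sticky > 0) {
        repeat {
          merged_any <- FALSE
          bids <- unique(body)
          for (bi in bids) for (bj in bids) {
            if (bj <= bi || !(bi %in% body) || !(bj %in% body)) next
            A <- do.call(rbind, beads[which(body == bi)])
            B <- do.call(rbind, beads[which(body == bj)])
            d2 <- cross_dist2(A, B, box)
            if (min(d2) <= capture^2) {
              # snap body bj so the closest bead pair sits at 0.4 nm,
              # collapsing any periodic-image offset so the merged body
              # is contiguous in unwrapped coordinates
              idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
              disp <- min_image_displacement(A[idx[1], ], B[idx[2], ],
                                             box)[1, ]
              dmin <- sqrt(sum(disp * disp))
              u <- if (dmin > 1e-9) disp / dmin else c(1, 0, 0)
              pull <- (B[idx[2], ] - A[idx[1], ]) - 0.4 * u
              for (m in which(body == bj))
                beads[[m]] <- sweep(beads[[m]], 2, pull, "-")
              body[body == bj] <- bi
              merges[[length(merges) + 1L]] <-
                list(frame = t, bodies = c(bi, bj))
              merged_any <- TRUE
            }
          }
          if (!merged_any) break
        }
      }
      coords <- wrap_box(do.call(rbind, beads), box)
      frames[[t]] <- md_frame(coords, box = box, time = t - 1)
    }
    truth <- list(kind = "aggregation", sticky = sticky,
                  n_peptides = n_peptides,
                  final_largest_cluster = max(table(body)),
                  n_bodies_final = length(unique(body)),
                  merge_frames = vapply(merges, `[[`, numeric(1), "frame"),
                  seed = seed)
    list(trajectory = trajectory(system, frames), truth = truth)
  })
}

#' Generate a peptide-adsorbed lipid aggregate trajectory
#'
#' A spherical lipid aggregate (tail beads in the core, head-group and
#' phosphate beads on the surface) with peptides adsorbed above the
#' surface. Each frame, each peptide residue independently contacts the
#' head-group shell with probability proportional to the planted
#' per-residue weights (the contacting bead is placed 0.45 nm radially
#' above one head bead, guaranteeing a single contact event); otherwise
#' the residue sits >= 1.2 nm above the surface, out of contact.
#' Divalent ions start bound to distinct phosphate beads; `released_k`
#' of them are displaced to 3 nm above the surface from frame
#' `released_at` onward. Defaults emulate a small lipid-A aggregate
#' (61 lipids) with 30 adsorbed peptide copies.
#'
#' @param n_lipids lipids in the aggregate
#' @param n_peptides adsorbed peptides
#' @param residue_contact_weights non-negative planted per-residue
#'   head-group contact weights (default: uniform over 18 residues)
#' @param contact_scale probability of the most contact-prone residue
#'   being in contact in a frame
#' @param n_ions bound divalent ions
#' @param released_at frame index from which ions are displaced
#'   (`NULL`: never)
#' @param released_k ions displaced
#' @param n_frames frames
#' @param seed RNG seed
#' @param sequence peptide sequence (letters; length fixes residues per
#'   peptide)
#' @return list with `trajectory` (group tags already assigned) and
#'   `truth` (weights, expected contact probabilities, ion release)
#' @export
gen_lipid_interface <- function(n_lipids = 61L, n_peptides = 30L,
                                residue_contact_weights = NULL,
                                contact_scale = 0.6,
                                n_ions = 20L, released_at = NULL,
                                released_k = 0L, n_frames = 100L,
                                seed = 1L, sequence = SHVF18_SEQ) {
  n_res <- nchar(sequence)
  if (is.null(residue_contact_weights))
    residue_contact_weights <- rep(1, n_res)
  if (length(residue_contact_weights) != n_res)
    stop("need one contact weight per residue")
  if (any(residue_contact_weights < 0) ||
      all(residue_contact_weights == 0))
    stop("contact weights must be non-negative and not all zero")
  with_seed(seed, {
    R <- 3.0                              # aggregate surface radius, nm
    surf <- golden_spiral_points(n_lipids)
    # lipid: 1 head + 1 phosphate at the surface, 3 tail beads inside
    lipid_particles <- list(); lipid_coords <- list()
    pid <- 0L
    for (m in seq_len(n_lipids)) {
      u <- surf[m, ]
      sites <- c("HD", "PO", "TA1", "TA2", "TA3")
      radial <- c(1.0, 0.93, 0.75, 0.55, 0.35) * R
      lipid_particles[[m]] <- data.frame(
        particle_id = pid + seq_along(sites), molecule_id = m,
        molecule_kind = "lipid", residue_index = 1L,
        residue_name = "LIP", site_name = sites,
        group_tag = c("headgroup", "phosphate", "tail", "tail", "tail"),
        radius = 0.23)
      lipid_coords[[m]] <- outer(radial, u)
      pid <- pid + length(sites)
    }
    head_rows <- which(do.call(rbind, lipid_particles)$group_tag ==
                         "headgroup")
    head_xyz <- do.call(rbind, lipid_coords)[head_rows, , drop = FALSE]
    pep_particles <- lapply(seq_len(n_peptides), function(k)
      transform(peptide_template(sequence,
                                 molecule_id = n_lipids + k,
                                 first_particle_id = pid +
                                   (k - 1L) * n_res + 1L),
                radius = 0.23))
    pid2 <- pid + n_peptides * n_res
    ion_particles <- if (n_ions > 0)
      data.frame(particle_id = pid2 + seq_len(n_ions),
                 molecule_id = n_lipids + n_peptides + seq_len(n_ions),
                 molecule_kind = "ion", residue_index = 1L,
                 residue_name = "CA", site_name = "CA",
                 group_tag = "none", radius = 0.23)
      else NULL
    particles <- rbind(do.call(rbind, lipid_particles),
                       do.call(rbind, pep_particles), ion_particles)
    system <- molecular_system(particles)
    w <- residue_contact_weights
    p_contact <- contact_scale * w / max(w)
    # each peptide anchored near a home direction on the sphere
    home <- golden_spiral_points(n_peptides + 2)[-(1:2), , drop = FALSE]
    phosph_rows <- which(particles$group_tag == "phosphate")
    ion_home <- sample(phosph_rows, min(n_ions, length(phosph_rows)))
    lipid_xyz <- do.call(rbind, lipid_coords)
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      pep_xyz <- matrix(NA_real_, n_peptides * n_res, 3)
      row <- 0L
      for (k in seq_len(n_peptides)) {
        # candidate head beads near the peptide's home direction
        hd <- head_xyz %*% home[k, ]
        near_heads <- order(-hd)[1:5]
        for (r in seq_len(n_res)) {
          row <- row + 1L
          if (stats::runif(1) < p_contact[r]) {
            hb <- head_xyz[sample(near_heads, 1L), ]
            u <- hb / sqrt(sum(hb * hb))
            pep_xyz[row, ] <- hb + 0.45 * u
          } else {
            u <- home[k, ] + stats::rnorm(3, sd = 0.2)
            u <- u / sqrt(sum(u * u))
            pep_xyz[row, ] <- u * (R + 1.2 + stats::runif(1, 0, 0.6))
          }
        }
      }
      ion_xyz <- NULL
      if (n_ions > 0) {
        ion_xyz <- matrix(NA_real_, n_ions, 3)
        released <- !is.null(released_at) && t >= released_at
        for (i in seq_len(n_ions)) {
          anchor <- lipid_xyz[ion_home[i], ]
          u <- anchor / sqrt(sum(anchor * anchor))
          if (released && i <= released_k) {
            ion_xyz[i, ] <- u * (R + 3.0)
          } else {
            ion_xyz[i, ] <- anchor + 0.3 * u
          }
        }
      }
      frames[[t]] <- md_frame(rbind(lipid_xyz, pep_xyz, ion_xyz),
                              box = NULL, time = t - 1)
    }
    truth <- list(kind = "lipid_interface",
                  residue_contact_weights = w,
                  contact_probability = p_contact,
                  n_frames = n_frames, n_peptides = n_peptides,
                  released_at = released_at, released_k = released_k,
                  surface_radius = R, seed = seed)
    list(trajectory = trajectory(system, frames), truth = truth)
  })
}

# hexagonal ring of 6 beads, radius 0.14 nm, in the plane normal to `normal`
ring_beads <- function(center, normal, radius = 0.14) {
  normal <- normal / sqrt(sum(normal * normal))
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  t(vapply(ang, function(th)
    center + radius * (cos(th) * e1 + sin(th) * e2), numeric(3)))
}

#' Generate a receptor-peptide complex trajectory with planted
#' interactions
#'
#' A static receptor of one-bead residues on a coarse grid (>= 1.5 nm
#' spacing), with ring residues (six-bead hexagons) at positions named
#' in the interaction specs. Each planted interaction is geometrically
#' satisfied in exactly `round(p * n_frames)` frames (the satisfying
#' frames are spread evenly over the trajectory): a cation-pi spec
#' places the peptide cation bead 0.4 nm above the ring face in
#' satisfying frames and 1.0 nm away in the ring plane otherwise; an
#' hbond spec places donor at 0.30 nm (satisfying) or 0.8 nm from the
#' acceptor. Optionally the whole peptide drifts by `drift * (t-1)` nm
#' per frame (a planted, strictly increasing RMSD), and a planted
#' contact mixture over receptor residues can be sampled by
#' `contact_weights`.
#'
#' @param receptor_residues number of receptor residues
#' @param specs list of planted interactions; each a list with `kind`
#'   (`"cation_pi"` or `"hbond"`), `receptor_residue` (index), and
#'   occupancy `p` in `[0, 1]`
#' @param ring_residues receptor residue indices built as rings (rings
#'   are added automatically for cation-pi specs); named residues get
#'   residue_name TRP/PHE/TYR cyclically
#' @param contact_weights optional named numeric vector over receptor
#'   residue indices: each frame the peptide probe bead is placed in
#'   contact with one receptor residue sampled by these weights
#' @param drift peptide drift per frame in nm (0 = none)
#' @param n_frames frames
#' @param seed RNG seed
#' @param sequence peptide sequence
#' @return list with `trajectory` (tags assigned), `truth` (per-spec
#'   planted occupancy and frames, contact weights, drift) and `specs`
#'   resolved to [interaction_spec()] objects
#' @export
gen_complex <- function(receptor_residues = 30L, specs = list(),
                        ring_residues = integer(), contact_weights = NULL,
                        drift = 0, n_frames = 100L, seed = 1L,
                        sequence = SHVF18_SEQ) {
  for (s in specs) {
    if (!s$kind %in% c("cation_pi", "hbond"))
      stop("unsupported planted interaction kind: ", s$kind)
    if (s$p < 0 || s$p > 1) stop("occupancy p must be in [0, 1]")
  }
  spec_res <- vapply(specs, function(s) as.integer(s$receptor_residue),
                     integer(1))
  if (anyDuplicated(spec_res))
    stop("conflicting specs: one receptor residue in two specs")
  ring_residues <- sort(union(ring_residues, spec_res[
    vapply(specs, function(s) s$kind == "cation_pi", logical(1))]))
  with_seed(seed, {
    # receptor residues on a planar grid, 1.5 nm spacing, z = 0
    side <- ceiling(sqrt(receptor_residues))
    gx <- ((seq_len(receptor_residues) - 1) %% side) * 1.5
    gy <- ((seq_len(receptor_residues) - 1) %/% side) * 1.5
    rec_centers <- cbind(gx, gy, 0)
    aromatic_names <- c("TRP", "PHE", "TYR")
    rec_particles <- list(); rec_coords <- list()
    pid <- 0L
    for (r in seq_len(receptor_residues)) {
      if (r %in% ring_residues) {
        nm <- aromatic_names[(match(r, ring_residues) - 1L) %% 3L + 1L]
        rec_particles[[r]] <- data.frame(
          particle_id = pid + 1:6, molecule_id = 1L,
          molecule_kind = "receptor", residue_index = r,
          residue_name = nm, site_name = paste0("R", 1:6),
          group_tag = "aromatic_ring", radius = 0.17)
        rec_coords[[r]] <- ring_beads(rec_centers[r, ], c(0, 0, 1))
        pid <- pid + 6L
      } else {
        rec_particles[[r]] <- data.frame(
          particle_id = pid + 1L, molecule_id = 1L,
          molecule_kind = "receptor", residue_index = r,
          residue_name = "GLY", site_name = "BB",
          group_tag = "backbone", radius = 0.23)
        rec_coords[[r]] <- matrix(rec_centers[r, ], 1, 3)
        pid <- pid + 1L
      }
    }
    rec_xyz <- do.call(rbind, rec_coords)
    n_rec <- nrow(rec_xyz)
    # peptide: backbone rod parked 3 nm above the grid, plus one probe
    # bead per planted spec (cation bead SCP or donor bead DON) and an
    # optional contact-mixture probe bead PRB
    n_res <- nchar(sequence)
    pep <- peptide_template(sequence, molecule_id = 2L,
                            first_particle_id = pid + 1L)
    pep$radius <- 0.23
    extra <- list()
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      extra[[length(extra) + 1L]] <- data.frame(
        particle_id = pid + n_res + length(extra) + 1L,
        molecule_id = 2L, molecule_kind = "peptide",
        residue_index = 1L, residue_name = substr(sequence, 1, 1),
        site_name = if (s$kind == "cation_pi") paste0("SCP", si)
                    else paste0("DON", si),
        group_tag = if (s$kind == "cation_pi") "cation_group" else "none",
        radius = 0.23)
    }
    if (!is.null(contact_weights)) {
      extra[[length(extra) + 1L]] <- data.frame(
        particle_id = pid + n_res + length(extra) + 1L,
        molecule_id = 2L, molecule_kind = "peptide",
        residue_index = 1L, residue_name = substr(sequence, 1, 1),
        site_name = "PRB", group_tag = "cation_group", radius = 0.23)
    }
    particles <- rbind(do.call(rbind, rec_particles), pep,
                       do.call(rbind, extra))
    system <- molecular_system(particles)
    pep_rows <- which(particles$molecule_kind == "peptide" &
                        particles$site_name == "BB")
    # zig-zag backbone (non-collinear, so the peptide can serve as a
    # fit selection itself)
    pep_base <- cbind(0.35 * (seq_len(n_res) - 1),
                      -2 + 0.1 * (seq_len(n_res) %% 2), 3)
    # frames in which spec si is satisfied: evenly spread
    sat <- lapply(specs, function(s) {
      k <- round(s$p * n_frames)
      if (k == 0L) integer(0)
      else round(seq(1, n_frames, length.out = k))
    })
    mix_choice <- NULL
    if (!is.null(contact_weights)) {
      widx <- as.integer(names(contact_weights))
      if (is.null(names(contact_weights)))
        stop("contact_weights must be named by receptor residue index")
      mix_choice <- sample(widx, n_frames, replace = TRUE,
                           prob = contact_weights / sum(contact_weights))
    }
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      X <- matrix(NA_real_, nrow(particles), 3)
      X[seq_len(n_rec), ] <- rec_xyz
      X[pep_rows, ] <- sweep(pep_base, 2, c(drift * (t - 1), 0, 0), "+")
      erow <- n_rec + n_res
      for (si in seq_along(specs)) {
        s <- specs[[si]]
        erow <- erow + 1L
        ctr <- rec_centers[s$receptor_residue, ]
        if (t %in% sat[[si]]) {
          X[erow, ] <- if (s$kind == "cation_pi") ctr + c(0, 0, 0.4)
                       else ctr + c(0, 0, 0.30)
        } else {
          X[erow, ] <- if (s$kind == "cation_pi") ctr + c(1.0, 0, 0)
                       else ctr + c(0.8, 0, 0)
        }
      }
      if (!is.null(mix_choice)) {
        erow <- erow + 1L
        X[erow, ] <- rec_centers[mix_choice[t], ] + c(0, 0, 0.45)
      }
      frames[[t]] <- md_frame(X, box = NULL, time = t - 1)
    }
    resolved <- lapply(seq_along(specs), function(si) {
      s <- specs[[si]]
      probe_row <- which(particles$site_name ==
        if (s$kind == "cation_pi") paste0("SCP", si) else paste0("DON", si))
      target_rows <- which(particles$molecule_kind == "receptor" &
                             particles$residue_index == s$receptor_residue)
      if (s$kind == "cation_pi")
        interaction_spec("cation_pi", a = probe_row, b = target_rows,
                         label = paste0("R1:", s$receptor_residue))
      else
        interaction_spec("hbond", a = probe_row, b = target_rows[1],
                         label = paste0("R1:", s$receptor_residue))
    })
    truth <- list(kind = "complex",
                  planted_occupancy = vapply(specs, `[[`, numeric(1), "p"),
                  satisfied_frames = sat,
                  contact_weights = contact_weights,
                  mixture_choice = mix_choice,
                  drift = drift, n_frames = n_frames, seed = seed)
    list(trajectory = trajectory(system, frames), truth = truth,
         specs = resolved)
  })
}

#' Generate a multiple sequence alignment with planted column profiles
#'
#' Rows are sampled independently per column from the given residue
#' distributions. The `"conserved_his"` preset plants an invariant
#' histidine column flanked by variable columns, emulating a universally
#' conserved position inside an otherwise variable region; the
#' reference row is the first sequence.
#'
#' @param n_seqs sequences
#' @param length columns (ignored when `column_profiles` given)
#' @param column_profiles list of named probability vectors over
#'   residues (and `-`), one per column; `NULL` draws uniform-variable
#'   columns
#' @param preset `"none"` or `"conserved_his"`
#' @param conserved_column column index of the invariant histidine in
#'   the preset
#' @param seed RNG seed
#' @return list with `msa`, `truth` (planted majority residue and
#'   per-column profiles, preset info)
#' @export
gen_msa <- function(n_seqs = 12L, length = 20L, column_profiles = NULL,
                    preset = c("none", "conserved_his"),
                    conserved_column = 10L, seed = 1L) {
  preset <- match.arg(preset)
  with_seed(seed, {
    if (is.null(column_profiles)) {
      column_profiles <- lapply(seq_len(length), function(j) {
        k <- sample(3:8, 1)
        res <- sample(AA20, k)
        p <- stats::runif(k); p <- p / sum(p)
        stats::setNames(p, res)
      })
      if (preset == "conserved_his")
        column_profiles[[conserved_column]] <- c(H = 1)
    }
    ncol_ <- length(column_profiles)
    seqs <- matrix("-", n_seqs, ncol_)
    for (j in seq_len(ncol_)) {
      pr <- column_profiles[[j]]
      seqs[, j] <- sample(names(pr), n_seqs, replace = TRUE, prob = pr)
    }
    ids <- c("reference", paste0("taxon", seq_len(n_seqs - 1L)))
    msa <- msa_from_strings(apply(seqs, 1, paste, collapse = ""), ids)
    truth <- list(kind = "msa",
                  planted_majority = vapply(column_profiles, function(p)
                    names(p)[which.max(p)], character(1)),
                  column_profiles = column_profiles,
                  preset = preset,
                  conserved_column = if (preset == "conserved_his")
                    conserved_column else NA_integer_,
                  seed = seed)
    list(msa = msa, truth = truth)
  })
}

#' Generate a codon alignment evolved under a chosen dN/dS
#'
#' Star-tree evolution from a random stop-free ancestor: each tip
#' receives `round(mutation_rate * n_codons)` proposed single-nucleotide
#' changes at random positions; a proposal creating a stop codon is
#' rejected, a synonymous proposal is accepted with probability 1 (or
#' `1/omega` when `omega > 1`), and a nonsynonymous proposal with
#' probability `omega` (capped at 1). Realised accepted substitution
#' counts per codon are recorded as ground truth.
#'
#' @param n_seqs tip sequences
#' @param n_codons codons per sequence
#' @param omega planted dN/dS acceptance ratio (> 0)
#' @param mutation_rate proposed changes per codon per tip
#' @param seed RNG seed
#' @return list with `msa` (nucleotide rows), `truth` (per-codon
#'   realised synonymous/nonsynonymous substitution counts, omega)
#' @export
gen_codon_msa <- function(n_seqs = 6L, n_codons = 60L, omega = 0.5,
                          mutation_rate = 0.5, seed = 1L) {
  if (omega < 0) stop("omega must be >= 0")
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  with_seed(seed, {
    anc <- sample(sense, n_codons, replace = TRUE)
    p_syn <- if (omega > 1) 1 / omega else 1
    p_non <- if (omega > 1) 1 else omega
    syn_count <- numeric(n_codons); non_count <- numeric(n_codons)
    tips <- matrix("", n_seqs, n_codons)
    n_prop <- round(mutation_rate * n_codons)
    for (s in seq_len(n_seqs)) {
      cur <- anc
      for (it in seq_len(n_prop)) {
        k <- sample.int(n_codons, 1)
        pos <- sample.int(3L, 1)
        chars <- strsplit(cur[k], "")[[1]]
        nt <- sample(setdiff(NUCS, chars[pos]), 1)
        mut <- chars; mut[pos] <- nt
        mutc <- paste(mut, collapse = "")
        if (code[[mutc]] == "*") next
        synonymous <- code[[mutc]] == code[[cur[k]]]
        p_acc <- if (synonymous) p_syn else p_non
        if (stats::runif(1) < p_acc) {
          cur[k] <- mutc
          if (synonymous) syn_count[k] <- syn_count[k] + 1
          else non_count[k] <- non_count[k] + 1
        }
      }
      tips[s, ] <- cur
    }
    seqs <- apply(tips, 1, paste, collapse = "")
    msa <- msa_from_strings(seqs, paste0("tip", seq_len(n_seqs)))
    truth <- list(kind = "codon_msa", omega = omega,
                  ancestor = paste(anc, collapse = ""),
                  realized_synonymous = syn_count,
                  realized_nonsynonymous = non_count,
                  mutation_rate = mutation_rate, seed = seed)
    list(msa = msa, truth = truth)
  })
}

#' Generate a noisy dose-response or binding curve
#'
#' Log-spaced concentrations over the assay range (default
#' 0.015-500 uM) with Gaussian noise around a four-parameter logistic
#' or 1:1 binding isotherm.
#'
#' @param model `"fourpl"` or `"isotherm"`
#' @param params named list: for `fourpl` `bottom`, `top`, `ic50`,
#'   `hill`; for `isotherm` `baseline`, `amplitude`, `kd`
#' @param n_points concentrations
#' @param noise_sd Gaussian noise standard deviation (response units)
#' @param conc_range concentration range in uM
#' @param seed RNG seed
#' @return list with `data` (a [dose_response()]) and `truth`
#' @export
gen_dose_response <- function(model = c("fourpl", "isotherm"),
                              params = NULL, n_points = 12L,
                              noise_sd = 0, conc_range = c(0.015, 500),
                              seed = 1L) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "fourpl")
      list(bottom = 0, top = 100, ic50 = 1, hill = 1.5)
    else list(baseline = 0, amplitude = 1, kd = 2.45)
  with_seed(seed, {
    x <- exp(seq(log(conc_range[1]), log(conc_range[2]),
                 length.out = n_points))
    y <- if (model == "fourpl")
      fourpl(x, params$bottom, params$top, params$ic50, params$hill)
    else params$baseline + params$amplitude * x / (params$kd + x)
    y <- y + stats::rnorm(n_points, sd = noise_sd)
    list(data = dose_response(x, y),
         truth = c(list(kind = model, noise_sd = noise_sd, seed = seed),
                   params))
  })
}
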