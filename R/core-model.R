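#' @keywords internal
"_PACKAGE"

MOLECULE_KINDS <- c("peptide", "lipid", "ion", "receptor", "other")
GROUP_TAGS <- c("headgroup", "phosphate", "tail", "backbone", "sidechain",
                "cation_group", "aromatic_ring", "none")

#' Construct a molecular system from a particle table
#'
#' A `molecular_system` is the particle-level description shared by all
#' trajectory analyses: one row per particle (atom or coarse-grained bead)
#' with its molecule membership, residue numbering, site name, chemical
#' group tag and an optional radius used for surface-area calculations.
#'
#' @param particles data.frame with columns `particle_id`, `molecule_id`,
#'   `molecule_kind` (one of peptide/lipid/ion/receptor/other),
#'   `residue_index` (1-based within the molecule), `residue_name`,
#'   `site_name`, and optionally `group_tag` (defaults to `"none"`) and
#'   `radius` (nm; defaults to `NA`).
#' @return object of class `molecular_system`
#' @export
molecular_system <- function(particles) {
  stopifnot(is.data.frame(particles))
  required <- c("particle_id", "molecule_id", "molecule_kind",
                "residue_index", "residue_name", "site_name")
  missing <- setdiff(required, names(particles))
  if (length(missing))
    stop("particle table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"group_tag" %in% names(particles)) particles$group_tag <- "none"
  if (!"radius" %in% names(particles)) particles$radius <- NA_real_
  particles$particle_id <- as.integer(particles$particle_id)
  particles$molecule_id <- as.integer(particles$molecule_id)
  particles$residue_index <- as.integer(particles$residue_index)
  if (anyDuplicated(particles$particle_id))
    stop("particle_id values must be unique")
  if (any(particles$residue_index < 1L))
    stop("residue_index must be >= 1")
  bad_kind <- setdiff(unique(particles$molecule_kind), MOLECULE_KINDS)
  if (length(bad_kind))
    stop("unknown molecule_kind: ", paste(bad_kind, collapse = ", "))
  bad_tag <- setdiff(unique(particles$group_tag), GROUP_TAGS)
  if (length(bad_tag))
    stop("unknown group_tag: ", paste(bad_tag, collapse = ", "))
  if (any(!is.na(particles$radius) & particles$radius <= 0))
    stop("particle radii must be > 0 when given")
  rownames(particles) <- NULL
  structure(list(particles = particles), class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  p <- x$particles
  cat("molecular_system:", nrow(p), "particles,",
      length(unique(p$molecule_id)), "molecules\n")
  kinds <- table(p$molecule_kind[!duplicated(p$molecule_id)])
  cat("  molecules by kind:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_particles <- function(system) nrow(system$particles)

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix (n x 3) of particle positions in nm,
#'   ordered as the particle table of the owning system.
#' @param box optional orthorhombic box edge lengths in nm (length 3);
#'   `NULL` means open (non-periodic) boundaries.
#' @param time frame time in ns.
#' @return object of class `md_frame`
#' @export
md_frame <- function(coords, box = NULL, time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z in nm)")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive edge lengths in nm (orthorhombic only)")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory from a system and a list of frames
#'
#' @param system a [molecular_system()]
#' @param frames list of [md_frame()] objects with matching particle counts;
#'   frames with missing/duplicate times are assigned 0, 1, 2, ... ns.
#' @return object of class `trajectory`
#' @export
trajectory <- function(system, frames) {
  stopifnot(inherits(system, "molecular_system"), is.list(frames))
  if (!length(frames)) stop("a trajectory needs at least one frame")
  np <- n_particles(system)
  counts <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (any(counts != np))
    stop("frame particle count differs from system (",
         paste(unique(counts), collapse = ","), " vs ", np, ")")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times) || any(diff(times) <= 0)) {
    # missing or non-increasing stamps: renumber 0, 1, 2, ... ns
    for (i in seq_along(frames)) frames[[i]]$time <- i - 1
  }
  structure(list(system = system, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      n_particles(x$system), "particles, t = [",
      x$frames[[1]]$time, ",", x$frames[[length(x$frames)]]$time, "] ns\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) vapply(traj$frames, function(f) f$time, numeric(1))

#' Analysis configuration
#'
#' Bundles the geometric cutoffs and quadrature settings used across the
#' analyses. Defaults follow the conventions of the coarse-grained
#' peptide-lipid literature: a 0.6 nm contact cutoff and a 0.26 nm SASA
#' probe radius (the radius of a coarse-grained water particle).
#'
#' @param contact_cutoff contact distance cutoff in nm (inclusive).
#' @param probe_radius SASA probe radius in nm.
#' @param cation_pi_cutoff cation-centroid to ring-centroid cutoff in nm.
#' @param cation_pi_angle maximal angle (degrees) between the ring normal
#'   and the centroid-to-cation vector.
#' @param stacking_cutoff ring-ring centroid cutoff in nm.
#' @param stacking_angle maximal inter-plane angle (degrees) for parallel
#'   stacking.
#' @param hbond_cutoff donor-acceptor distance cutoff in nm.
#' @param hbond_angle minimal donor-hydrogen-acceptor angle (degrees).
#' @param salt_bridge_cutoff charged-group distance cutoff in nm.
#' @param sasa_points quadrature points per sphere (>= 16).
#' @param rng_seed integer seed recorded with analysis runs.
#' @return object of class `analysis_config` (a named list)
#' @export
analysis_config <- function(contact_cutoff = 0.6,
                            probe_radius = 0.26,
                            cation_pi_cutoff = 0.6,
                            cation_pi_angle = 45,
                            stacking_cutoff = 0.55,
                            stacking_angle = 30,
                            hbond_cutoff = 0.35,
                            hbond_angle = 120,
                            salt_bridge_cutoff = 0.45,
                            sasa_points = 96L,
                            rng_seed = 1L) {
  cuts <- c(contact_cutoff, probe_radius, cation_pi_cutoff, stacking_cutoff,
            hbond_cutoff, salt_bridge_cutoff)
  if (any(cuts <= 0)) stop("all cutoffs and radii must be > 0")
  if (sasa_points < 16L) stop("sasa_points must be >= 16")
  structure(list(contact_cutoff = contact_cutoff,
                 probe_radius = probe_radius,
                 cation_pi_cutoff = cation_pi_cutoff,
                 cation_pi_angle = cation_pi_angle,
                 stacking_cutoff = stacking_cutoff,
                 stacking_angle = stacking_angle,
                 hbond_cutoff = hbond_cutoff,
                 hbond_angle = hbond_angle,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 sasa_points = as.integer(sasa_points),
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Default group-classification rules
#'
#' Ordered pattern rules mapping (residue name, site name) to chemical
#' group tags. Covers the coarse-grained bead naming used by the built-in
#' generators (BB backbone, HD/PO/TA lipid beads, SCP cation beads,
#' R1..R6 ring beads) and standard atomistic side-chain atoms (arginine
#' guanidinium NH1/NH2/CZ, lysine ammonium NZ, aromatic ring carbons).
#' Patterns containing `*` are globs; otherwise they are `|`-separated
#' exact alternatives. First matching rule wins.
#'
#' @return data.frame with columns `residue`, `site`, `tag`
#' @export
default_group_rules <- function() {
  rbind(
    data.frame(residue = "ARG", site = "NH1|NH2|CZ", tag = "cation_group"),
    data.frame(residue = "LYS", site = "NZ", tag = "cation_group"),
    data.frame(residue = "*",   site = "SCP", tag = "cation_group"),
    data.frame(residue = "PHE|TYR", site = "CG|CD1|CD2|CE1|CE2|CZ",
               tag = "aromatic_ring"),
    data.frame(residue = "HIS", site = "CG|ND1|CD2|CE1|NE2",
               tag = "aromatic_ring"),
    data.frame(residue = "TRP",
               site = "CG|CD1|CD2|NE1|CE2|CE3|CZ2|CZ3|CH2",
               tag = "aromatic_ring"),
    data.frame(residue = "*",   site = "R1|R2|R3|R4|R5|R6",
               tag = "aromatic_ring"),
    data.frame(residue = "*",   site = "PO*", tag = "phosphate"),
    data.frame(residue = "*",   site = "HD*", tag = "headgroup"),
    data.frame(residue = "*",   site = "TA*", tag = "tail"),
    data.frame(residue = "*",   site = "BB|N|CA|C|O", tag = "backbone")
  )
}

rule_regex <- function(pattern) {
  if (grepl("*", pattern, fixed = TRUE)) {
    utils::glob2rx(pattern)
  } else {
    paste0("^(", pattern, ")$")
  }
}

#' Assign chemical group tags by ordered pattern rules
#'
#' Applies rules in listed order; the first rule whose residue and site
#' patterns both match a particle assigns its tag. Unmatched particles
#' keep their current tag. Matching an empty set of particles is not an
#' error (a warning is emitted when no rule matched anything).
#'
#' @param system a [molecular_system()]
#' @param rules data.frame with columns `residue`, `site`, `tag`
#'   (see [default_group_rules()]).
#' @return the system with updated `group_tag`
#' @export
classify_groups <- function(system, rules = default_group_rules()) {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.data.frame(rules) || !nrow(rules))
    stop("rules must be a non-empty data.frame")
  bad <- setdiff(unique(rules$tag), GROUP_TAGS)
  if (length(bad))
    stop("rule references unknown group_tag: ", paste(bad, collapse = ", "))
  p <- system$particles
  assigned <- rep(FALSE, nrow(p))
  for (k in seq_len(nrow(rules))) {
    hit <- !assigned &
      grepl(rule_regex(rules$residue[k]), p$residue_name) &
      grepl(rule_regex(rules$site[k]), p$site_name)
    if (any(hit)) {
      p$group_tag[hit] <- rules$tag[k]
      assigned <- assigned | hit
    }
  }
  if (!any(assigned))
    warning("no classification rule matched any particle; system unchanged")
  system$particles <- p
  system
}

#' Default particle radii (nm)
#'
#' Assigns SASA radii: coarse-grained beads (site names not matching a
#' chemical element) get the generic bead radius 0.23 nm; atomistic sites
#' get van der Waals radii by leading element letter (C 0.17, N 0.155,
#' O 0.152, S 0.18, H 0.12, P 0.18 nm).
#'
#' @param system a [molecular_system()]
#' @param bead_radius radius for coarse-grained beads, nm.
#' @return the system with `radius` filled where it was `NA`
#' @export
assign_default_radii <- function(system, bead_radius = 0.23) {
  p <- system$particles
  vdw <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120, P = 0.180)
  fill <- is.na(p$radius)
  elem <- substr(p$site_name, 1, 1)
  r <- unname(vdw[elem])
  atomistic <- !is.na(r) & grepl("^(N|C|O|S|H|P)[A-Z0-9]*$", p$site_name) &
    !p$site_name %in% c("BB", "HD", "PO", "TA", "SCP")
  p$radius[fill & atomistic] <- r[fill & atomistic]
  p$radius[is.na(p$radius)] <- bead_radius
  system$particles <- p
  system
}

#' Particle indices matching a condition
#'
#' Convenience selector over the particle table. All arguments are
#' optional filters combined with AND.
#'
#' @param system a [molecular_system()]
#' @param kind molecule kind(s)
#' @param tag group tag(s)
#' @param molecule molecule id(s)
#' @param residue residue index(es)
#' @param site site name(s)
#' @return integer vector of row indices into the particle table
#' @export
select_particles <- function(system, kind = NULL, tag = NULL,
                             molecule = NULL, residue = NULL, site = NULL) {
  p <- system$particles
  keep <- rep(TRUE, nrow(p))
  if (!is.null(kind)) keep <- keep & p$molecule_kind %in% kind
  if (!is.null(tag)) keep <- keep & p$group_tag %in% tag
  if (!is.null(molecule)) keep <- keep & p$molecule_id %in% molecule
  if (!is.null(residue)) keep <- keep & p$residue_index %in% residue
  if (!is.null(site)) keep <- keep & p$site_name %in% site
  which(keep)
}

AA_321 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
            X = "XAL")

#' Build a one-bead-per-residue peptide particle table
#'
#' Creates a coarse-grained peptide template from a one-letter sequence
#' ('X' denotes a non-standard staple residue, mapped to residue name
#' "XAL"). One backbone bead ("BB") per residue.
#'
#' @param sequence one-letter amino-acid string
#' @param molecule_id molecule id to assign
#' @param first_particle_id id of the first bead
#' @return data.frame of particles (see [molecular_system()])
#' @export
peptide_template <- function(sequence, molecule_id = 1L,
                             first_particle_id = 1L) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(AA_321))
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(bad, collapse = ", "))
  n <- length(letters1)
  data.frame(particle_id = seq.int(first_particle_id, length.out = n),
             molecule_id = as.integer(molecule_id),
             molecule_kind = "peptide",
             residue_index = seq_len(n),
             residue_name = unname(AA_321[letters1]),
             site_name = "BB",
             group_tag = "none",
             radius = NA_real_)
}
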