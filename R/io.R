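# Structure and trajectory I/O. Internal unit is nm everywhere; PDB
# coordinates are converted at the boundary (PDB files are in Angstrom).
# PDB is handled through bio3d; GRO (fixed-width, nm-native) and the
# per-frame XYZ table format are read/written here.

ION_NAMES <- c("ION", "CA", "CA2", "NA", "CL", "MG", "ZN", "K")
SOLVENT_NAMES <- c("W", "PW", "SOL", "HOH", "WAT", "TIP3", "TIP", "SPC")

# kind from residue names of one molecule
infer_kind <- function(resnames) {
  if (all(resnames %in% SOLVENT_NAMES)) return("other")
  if (all(resnames %in% ION_NAMES)) return("ion")
  if (all(resnames %in% AA_321)) return("peptide")
  if (any(grepl("^(LIP|LPA|POP|DPP|DOP|DLP|CDL|PIP)", resnames)))
    return("lipid")
  "other"
}

# split particles into molecules: a new molecule starts where segid
# changes (when present) or where the chain changes or residue numbering
# restarts
molecule_breaks <- function(chain, resno, segid = NULL) {
  n <- length(resno)
  if (!is.null(segid) && any(nzchar(trimws(segid)))) {
    newmol <- c(TRUE, segid[-1] != segid[-n])
  } else {
    chain[is.na(chain)] <- ""
    newmol <- c(TRUE, chain[-1] != chain[-n] | resno[-1] < resno[-n])
  }
  cumsum(newmol)
}

build_system_from_atoms <- function(resno, resid, elety, chain,
                                    segid = NULL) {
  mol <- molecule_breaks(chain, resno, segid)
  resid <- trimws(resid); elety <- trimws(elety)
  # residue_index: 1-based within molecule, following numbering order
  resix <- integer(length(resno))
  kinds <- character(max(mol))
  for (m in unique(mol)) {
    sel <- which(mol == m)
    r <- resno[sel]
    resix[sel] <- match(r, sort(unique(r)))
    kinds[m] <- infer_kind(unique(resid[sel]))
  }
  data.frame(particle_id = seq_along(resno),
             molecule_id = mol,
             molecule_kind = kinds[mol],
             residue_index = resix,
             residue_name = resid,
             site_name = elety,
             group_tag = "none",
             radius = NA_real_)
}

read_pdb_box <- function(path) {
  lines <- readLines(path, n = 200L)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  edges <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33))) / 10
  angles <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                         substr(cl[1], 48, 54)))
  if (any(!is.na(angles) & abs(angles - 90) > 1e-3))
    stop("triclinic boxes are unsupported (orthorhombic only)")
  if (anyNA(edges) || any(edges <= 0)) return(NULL)
  edges
}

parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file: fewer than 3 lines")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("malformed GRO record at line 2: bad atom count")
  if (length(lines) < nat + 3L)
    stop("malformed GRO file: expected ", nat + 3L, " lines, found ",
         length(lines))
  at <- lines[3:(2 + nat)]
  resno <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resid <- trimws(substr(at, 6, 10))
  elety <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", bad[1] + 2L)
  boxvals <- suppressWarnings(as.numeric(strsplit(trimws(
    lines[nat + 3L]), "\\s+")[[1]]))
  box <- NULL
  if (length(boxvals) >= 3L && !anyNA(boxvals[1:3])) {
    if (length(boxvals) > 3L && any(abs(boxvals[-(1:3)]) > 1e-9))
      stop("triclinic boxes are unsupported (orthorhombic only)")
    if (all(boxvals[1:3] > 0)) box <- boxvals[1:3]
  }
  list(resno = resno, resid = resid, elety = elety,
       coords = cbind(x, y, z), box = box)
}

#' Read a structure file (PDB or GRO)
#'
#' Parses a single-frame coordinate file into a particle table plus one
#' frame. PDB coordinates (Angstrom) are converted to nm; GRO files are
#' nm-native. Residue and site names are preserved verbatim; group tags
#' default to `"none"` pending [classify_groups()]. Molecule kinds are
#' inferred from residue names (standard amino acids to peptide, or
#' receptor above `receptor_min_residues` residues; known ion and
#' solvent names; lipid residue-name prefixes).
#'
#' @param path file path
#' @param format `"pdb"`, `"gro"`, or `"auto"` (by extension).
#' @param receptor_min_residues protein molecules longer than this are
#'   tagged `receptor` rather than `peptide`.
#' @return list with elements `system` ([molecular_system()]) and
#'   `frame` ([md_frame()])
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           receptor_min_residues = 30L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    a <- pdb$atom
    particles <- build_system_from_atoms(a$resno, a$resid, a$elety,
                                         a$chain, a$segid)
    coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    box <- read_pdb_box(path)
  } else {
    g <- parse_gro(path)
    particles <- build_system_from_atoms(g$resno, g$resid, g$elety,
                                         chain = rep("", length(g$resno)))
    coords <- g$coords
    box <- g$box
  }
  particles <- relabel_receptors(particles, receptor_min_residues)
  list(system = molecular_system(particles),
       frame = md_frame(coords, box = box, time = 0))
}

relabel_receptors <- function(particles, receptor_min_residues) {
  for (m in unique(particles$molecule_id)) {
    sel <- particles$molecule_id == m
    if (all(particles$molecule_kind[sel] == "peptide") &&
        max(particles$residue_index[sel]) > receptor_min_residues)
      particles$molecule_kind[sel] <- "receptor"
  }
  particles
}

#' Read a multi-frame trajectory
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` records) and the
#' package's plain-text per-frame XYZ table (see [write_trajectory()]).
#' All frames must share the particle roster of the first; frames without
#' time stamps are assigned 0, 1, 2, ... ns.
#'
#' @param path file path
#' @param format `"multi_model_pdb"`, `"xyz_frames"`, or `"auto"`.
#' @inheritParams read_structure
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path,
                            format = c("auto", "multi_model_pdb",
                                       "xyz_frames"),
                            receptor_min_residues = 30L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xyz|txt)$", path, ignore.case = TRUE))
      "xyz_frames" else "multi_model_pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "multi_model_pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    a <- pdb$atom
    particles <- build_system_from_atoms(a$resno, a$resid, a$elety,
                                         a$chain, a$segid)
    particles <- relabel_receptors(particles, receptor_min_residues)
    box <- read_pdb_box(path)
    nf <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nf), function(i) {
      md_frame(matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10,
               box = box, time = i - 1)
    })
    trajectory(molecular_system(particles), frames)
  } else {
    read_xyz_frames(path)
  }
}

# --- plain-text per-frame XYZ table -----------------------------------
# Layout per frame:
#   <n_particles>
#   time=<ns> [box=<bx>,<by>,<bz>]
#   molecule_id kind residue_index residue_name site_name group_tag radius x y z
# The roster (all columns except x,y,z) must be identical in every frame.

#' Write a trajectory as a plain-text per-frame XYZ table
#'
#' Self-contained text format: each frame holds a particle-count line, a
#' `time=`/`box=` comment line, and one row per particle carrying the
#' full particle metadata plus coordinates in nm. Round-trips exactly at
#' the written precision.
#'
#' @param traj a [trajectory()]
#' @param path output file path
#' @param digits coordinate digits written
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  p <- traj$system$particles
  fmt <- paste0("%.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(as.character(nrow(p)), con)
    hdr <- paste0("time=", format(f$time, digits = 12))
    if (!is.null(f$box))
      hdr <- paste0(hdr, " box=", paste(sprintf(fmt, f$box), collapse = ","))
    writeLines(hdr, con)
    writeLines(paste(p$molecule_id, p$molecule_kind, p$residue_index,
                     p$residue_name, p$site_name, p$group_tag,
                     ifelse(is.na(p$radius), "NA", sprintf(fmt, p$radius)),
                     sprintf(fmt, f$coords[, 1]),
                     sprintf(fmt, f$coords[, 2]),
                     sprintf(fmt, f$coords[, 3])), con)
  }
  invisible(path)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  roster <- NULL
  system <- NULL
  nframe <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed frame header at line ", i)
    hdr <- lines[i + 1L]
    tm <- sub(".*time=([-0-9.eE+]+).*", "\\1", hdr)
    time <- suppressWarnings(as.numeric(tm))
    box <- NULL
    if (grepl("box=", hdr)) {
      bx <- sub(".*box=([^ ]+).*", "\\1", hdr)
      box <- as.numeric(strsplit(bx, ",")[[1]])
    }
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(rows, "\\s+")
    bad <- which(lengths(parts) != 10L)
    if (length(bad))
      stop("malformed particle record at line ", i + 1L + bad[1])
    m <- do.call(rbind, parts)
    this_roster <- m[, 1:7, drop = FALSE]
    if (is.null(roster)) {
      roster <- this_roster
      system <- molecular_system(data.frame(
        particle_id = seq_len(nat),
        molecule_id = as.integer(m[, 1]),
        molecule_kind = m[, 2],
        residue_index = as.integer(m[, 3]),
        residue_name = m[, 4],
        site_name = m[, 5],
        group_tag = m[, 6],
        radius = suppressWarnings(as.numeric(m[, 7]))))
    } else if (nrow(this_roster) != nrow(roster) ||
               !all(this_roster == roster)) {
      stop("frame ", nframe + 1L,
           " particle roster differs from the first frame")
    }
    coords <- cbind(as.numeric(m[, 8]), as.numeric(m[, 9]),
                    as.numeric(m[, 10]))
    nframe <- nframe + 1L
    frames[[nframe]] <- md_frame(coords, box = box,
                                 time = if (is.na(time)) NA else time)
    i <- i + 2L + nat
  }
  if (!nframe) stop("no frames found in ", path)
  trajectory(system, frames)
}

#' Write a structure or trajectory to PDB
#'
#' Coordinates are converted from nm to Angstrom. Molecule ids are
#' written to both the chain column (letters, recycled) and the segid
#' column so that molecules round-trip; multi-frame trajectories use
#' MODEL/ENDMDL records. The box, when present, is written as a CRYST1
#' record.
#'
#' @param x a [trajectory()], or a [molecular_system()] with `frame` given
#' @param path output path
#' @param frame an [md_frame()] when `x` is a system
#' @return `path`, invisibly
#' @export
write_pdb_file <- function(x, path, frame = NULL) {
  if (inherits(x, "trajectory")) {
    system <- x$system
    frames <- x$frames
  } else {
    stopifnot(inherits(x, "molecular_system"), inherits(frame, "md_frame"))
    system <- x
    frames <- list(frame)
  }
  p <- system$particles
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords * 10))))
  box <- frames[[1]]$box
  if (!is.null(box)) {
    cat(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1\n",
                box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90),
        file = path)
    append <- TRUE
  } else append <- FALSE
  # residue numbers restart inside each molecule; chain letter recycled
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = p$residue_index,
                   resid = p$residue_name,
                   elety = p$site_name,
                   chain = LETTERS[(p$molecule_id - 1L) %% 26L + 1L],
                   segid = sprintf("M%03d", p$molecule_id %% 1000L),
                   print.segid = TRUE, append = append)
  invisible(path)
}
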