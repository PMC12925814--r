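# Peptide self-assembly metrics: single-linkage clustering of peptide
# molecules by inter-peptide particle contacts, cluster-size time series,
# and per-residue inter-peptide contact propensity.

# minimal union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster peptides in one frame by single-linkage contacts
#'
#' Two peptide molecules are linked when any inter-peptide particle pair
#' lies within the cutoff (minimum-image distance, inclusive boundary);
#' clusters are the connected components of the link graph. This is
#' single-linkage clustering at the contact cutoff.
#'
#' @param frame an [md_frame()]
#' @param system the owning [molecular_system()]
#' @param cutoff contact cutoff in nm (default: the global 0.6 nm
#'   contact cutoff).
#' @param frame_index frame number recorded in the result.
#' @return object of class `cluster_partition`: list with `frame_index`
#'   and `clusters`, a list of peptide `molecule_id` vectors that
#'   partition the peptide set.
#' @export
cluster_frame <- function(frame, system, cutoff = 0.6, frame_index = 1L) {
  pep <- select_particles(system, kind = "peptide")
  if (!length(pep)) stop("system contains no peptide molecules")
  p <- system$particles
  mols <- sort(unique(p$molecule_id[pep]))
  n <- length(mols)
  parent <- uf_new(n)
  pairs <- neighbor_pairs(frame, system, pep, pep, cutoff,
                          exclude_same_molecule = TRUE)
  if (nrow(pairs)) {
    ma <- match(p$molecule_id[match(pairs$id_a, p$particle_id)], mols)
    mb <- match(p$molecule_id[match(pairs$id_b, p$particle_id)], mols)
    for (k in seq_along(ma)) {
      ra <- uf_find(parent, ma[k]); rb <- uf_find(parent, mb[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  clusters <- unname(split(mols, roots))
  structure(list(frame_index = as.integer(frame_index), clusters = clusters),
            class = "cluster_partition")
}

#' Cluster-size time series over a trajectory
#'
#' @param traj a [trajectory()] containing peptide molecules
#' @param cutoff contact cutoff in nm
#' @return object of class `cluster_size_series`: data.frame with columns
#'   `frame`, `time`, `largest`, `n_clusters`; the per-frame size
#'   histograms are attached as attribute `"size_histogram"` (a list of
#'   named count tables).
#' @export
cluster_size_series <- function(traj, cutoff = 0.6) {
  nf <- n_frames(traj)
  largest <- integer(nf); ncl <- integer(nf)
  hists <- vector("list", nf)
  for (i in seq_len(nf)) {
    part <- cluster_frame(traj$frames[[i]], traj$system, cutoff, i)
    sizes <- lengths(part$clusters)
    largest[i] <- max(sizes)
    ncl[i] <- length(sizes)
    hists[[i]] <- table(sizes)
  }
  out <- data.frame(frame = seq_len(nf), time = frame_times(traj),
                    largest = largest, n_clusters = ncl)
  attr(out, "size_histogram") <- hists
  class(out) <- c("cluster_size_series", "data.frame")
  out
}

#' Per-residue inter-peptide contact propensity
#'
#' Counts contact events between particles of different peptides over
#' all frames; each event is attributed to the residue index of the
#' first particle (both orderings of a pair are counted, so the profile
#' is symmetric over peptides). Percentages are normalised over contact
#' events and sum to 100 when any contact exists. All peptides must
#' share one residue template (equal length).
#'
#' @param traj a [trajectory()]
#' @param cutoff contact cutoff in nm
#' @param mode `"events"` (default) normalises over contact events;
#'   `"frames"` counts, per residue, the number of frames in which the
#'   residue touches another peptide, normalised over frame-residue
#'   events.
#' @return data.frame with columns `residue_index`, `residue_name`,
#'   `count`, `contact_percentage`; attribute `"no_contacts"` is `TRUE`
#'   when the trajectory shows no inter-peptide contact.
#' @export
interpeptide_residue_propensity <- function(traj, cutoff = 0.6,
                                            mode = c("events", "frames")) {
  mode <- match.arg(mode)
  system <- traj$system
  p <- system$particles
  pep <- select_particles(system, kind = "peptide")
  if (!length(pep)) stop("system contains no peptide molecules")
  lens <- tapply(p$residue_index[pep], p$molecule_id[pep], max)
  if (length(unique(lens)) != 1L)
    stop("peptides do not share one residue template (unequal lengths)")
  n_res <- unique(lens)
  counts <- numeric(n_res)
  for (i in seq_len(n_frames(traj))) {
    pairs <- neighbor_pairs(traj$frames[[i]], system, pep, pep, cutoff,
                            exclude_same_molecule = TRUE)
    if (!nrow(pairs)) next
    # unordered pairs returned once; attribute to both members
    ra <- p$residue_index[match(pairs$id_a, p$particle_id)]
    rb <- p$residue_index[match(pairs$id_b, p$particle_id)]
    if (mode == "events") {
      tab <- tabulate(c(ra, rb), nbins = n_res)
    } else {
      tab <- tabulate(unique(c(ra, rb)), nbins = n_res)
    }
    counts <- counts + tab
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts
  resnames <- p$residue_name[pep][match(seq_len(n_res),
                                        p$residue_index[pep])]
  out <- data.frame(residue_index = seq_len(n_res),
                    residue_name = resnames,
                    count = counts,
                    contact_percentage = pct)
  attr(out, "no_contacts") <- total == 0
  out
}
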