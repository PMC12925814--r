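# Small in-code fixtures shared across tests.

# a system of n free particles, one molecule each
point_system <- function(n, kind = "peptide", radius = 0.23) {
  molecular_system(data.frame(
    particle_id = seq_len(n), molecule_id = seq_len(n),
    molecule_kind = kind, residue_index = 1L,
    residue_name = "ALA", site_name = "BB",
    group_tag = "none", radius = radius))
}

# n_mol peptides of n_res single-bead residues with given coordinates
multi_peptide_system <- function(n_mol, n_res) {
  molecular_system(do.call(rbind, lapply(seq_len(n_mol), function(m)
    peptide_template(paste(rep("A", n_res), collapse = ""),
                     molecule_id = m,
                     first_particle_id = (m - 1L) * n_res + 1L))))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_motion <- function(X, R = random_rotation(), t = stats::rnorm(3)) {
  sweep(X %*% t(R), 2, t, "+")
}

sorted_pair_matrix <- function(pairs_df) {
  m <- cbind(pairs_df$id_a, pairs_df$id_b)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}
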