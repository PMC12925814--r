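make_lipid_fixture <- function(pep_xyz, head_xyz, tail_xyz = NULL) {
  n_pep <- nrow(pep_xyz)
  n_head <- nrow(head_xyz)
  n_tail <- if (is.null(tail_xyz)) 0L else nrow(tail_xyz)
  parts <- rbind(
    data.frame(particle_id = seq_len(n_pep), molecule_id = 1L,
               molecule_kind = "peptide", residue_index = seq_len(n_pep),
               residue_name = "ALA", site_name = "BB",
               group_tag = "none", radius = 0.23),
    data.frame(particle_id = n_pep + seq_len(n_head), molecule_id = 2L,
               molecule_kind = "lipid", residue_index = 1L,
               residue_name = "LIP", site_name = "HD",
               group_tag = "headgroup", radius = 0.23),
    if (n_tail) data.frame(particle_id = n_pep + n_head + seq_len(n_tail),
                           molecule_id = 2L, molecule_kind = "lipid",
                           residue_index = 1L, residue_name = "LIP",
                           site_name = "TA", group_tag = "tail",
                           radius = 0.23))
  trajectory(molecular_system(parts),
             list(md_frame(rbind(pep_xyz, head_xyz, tail_xyz))))
}

test_that("head-group contacts attribute to the touching residue only", {
  # 3-residue peptide; only residue 1 within 0.6 nm of a head bead
  tr <- make_lipid_fixture(
    pep_xyz = rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
    head_xyz = rbind(c(0.5, 0, 0), c(10, 0, 0)))
  prof <- residue_lipid_contacts(tr, "headgroup")
  expect_equal(prof$contact_percentage, c(100, 0, 0))
  expect_error(residue_lipid_contacts(tr, "tail"), "tail")
})

test_that("contact profiles are rigid-motion invariant and sum to 100", {
  set.seed(13)
  g <- gen_lipid_interface(n_lipids = 20, n_peptides = 4, n_frames = 10,
                           n_ions = 0, seed = 3, sequence = "HVFRL")
  prof <- residue_lipid_contacts(g$trajectory, "headgroup")
  expect_equal(sum(prof$contact_percentage), 100, tolerance = 1e-9)
  tr2 <- g$trajectory
  R <- random_rotation(); tvec <- stats::rnorm(3)
  tr2$frames <- lapply(tr2$frames, function(f)
    md_frame(rigid_motion(f$coords, R, tvec), time = f$time))
  prof2 <- residue_lipid_contacts(tr2, "headgroup")
  expect_equal(prof2$contact_percentage, prof$contact_percentage,
               tolerance = 1e-9)
})

test_that("planted per-residue head-group bias is recovered", {
  w <- c(2, rep(1, 4))        # N-terminal residue twice as contact-prone
  counts <- numeric(5); n_trials <- 0
  for (s in 1:10) {
    g <- gen_lipid_interface(n_lipids = 30, n_peptides = 10,
                             residue_contact_weights = w,
                             n_frames = 40, n_ions = 0, seed = s,
                             sequence = "HVFRL")
    prof <- residue_lipid_contacts(g$trajectory, "headgroup")
    counts <- counts + prof$count
    n_trials <- n_trials + 10 * 40
  }
  # pooled binomial check: planted contact probabilities are 0.6*w/2
  p <- 0.6 * w / 2
  for (r in 1:5) {
    ci <- stats::binom.test(round(counts[r]), n_trials,
                            p = p[r])$conf.int
    expect_gt(p[r], ci[1] - 0.02)
    expect_lt(p[r], ci[2] + 0.02)
  }
  ratio <- counts[1] / mean(counts[2:5])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("SASA of an isolated sphere matches the analytic value", {
  sys <- point_system(1, radius = 0.23)
  f <- md_frame(matrix(0, 1, 3))
  analytic <- 4 * pi * (0.23 + 0.26)^2
  got <- shrake_rupley_sasa(f, sys, 1, probe = 0.26, n_points = 96)
  expect_equal(got, analytic, tolerance = 0.01)
  # quadrature is exact for a free sphere (all points exposed)
  expect_equal(got, analytic)
  # two disjoint spheres: exactly additive
  sys2 <- point_system(2, radius = 0.23)
  f2 <- md_frame(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(shrake_rupley_sasa(f2, sys2, 1:2, 0.26, 96), 2 * analytic)
  # missing radius is a config error naming the particle
  sys3 <- point_system(1, radius = NA_real_)
  expect_error(shrake_rupley_sasa(f, sys3, 1, 0.26, 96), "radius")
})

test_that("SASA agrees with a Monte-Carlo surface oracle on clusters", {
  set.seed(17)
  n <- 20
  X <- matrix(stats::rnorm(3 * n, sd = 0.5), n, 3)
  radii <- stats::runif(n, 0.15, 0.3)
  sys <- point_system(n)
  sys$particles$radius <- radii
  f <- md_frame(X)
  got <- shrake_rupley_sasa(f, sys, 1:n, probe = 0.26, n_points = 384)
  want <- oracle_mc_sasa(X, radii, 1:n, probe = 0.26, n_mc = 1e5)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("SASA quadrature converges with point count", {
  set.seed(19)
  X <- matrix(stats::rnorm(30, sd = 0.4), 10, 3)
  sys <- point_system(10, radius = 0.23)
  f <- md_frame(X)
  vals <- vapply(c(96, 384, 1536), function(np)
    shrake_rupley_sasa(f, sys, 1:10, 0.26, np), numeric(1))
  expect_lt(abs(vals[2] - vals[3]), abs(vals[1] - vals[3]) + 1e-9)
  # growing the probe on a convex-ish cluster never shrinks the surface
  v1 <- shrake_rupley_sasa(f, sys, 1:10, 0.26, 384)
  v2 <- shrake_rupley_sasa(f, sys, 1:10, 0.52, 384)
  expect_gte(v2, v1)
})

test_that("peptide adsorption lowers head-group SASA", {
  g_with <- gen_lipid_interface(n_lipids = 30, n_peptides = 8,
                                n_frames = 5, n_ions = 0, seed = 7,
                                sequence = "HVFRL")
  g_without <- gen_lipid_interface(n_lipids = 30, n_peptides = 1,
                                   residue_contact_weights = rep(1, 5),
                                   contact_scale = 1e-9,
                                   n_frames = 5, n_ions = 0, seed = 7,
                                   sequence = "HVFRL")
  heads_w <- select_particles(g_with$trajectory$system, tag = "headgroup")
  heads_o <- select_particles(g_without$trajectory$system,
                              tag = "headgroup")
  s_with <- sasa_series(g_with$trajectory, heads_w)
  s_without <- sasa_series(g_without$trajectory, heads_o)
  expect_lt(mean(s_with$sasa), mean(s_without$sasa))
  # a repeated static frame gives a constant series
  tr <- g_with$trajectory
  tr$frames <- rep(tr$frames[1], 3)
  tr <- trajectory(tr$system, tr$frames)
  s_const <- sasa_series(tr, heads_w)
  expect_equal(s_const$sasa, rep(s_const$sasa[1], 3))
})

test_that("ion binding and displacement follow the planted release", {
  g <- gen_lipid_interface(n_lipids = 30, n_peptides = 2, n_ions = 10,
                           released_at = 6, released_k = 5,
                           n_frames = 12, seed = 4, sequence = "HVFRL")
  ib <- ion_binding_series(g$trajectory)
  expect_equal(ib$displaced_count[1:5], rep(0L, 5))
  expect_equal(ib$displaced_count[6:12], rep(5L, 7))
  expect_true(all(ib$bound_count <= 10))
})

test_that("ion series matches a hand-countable fixture", {
  # 3 ions, 2 frames: frame 1 all bound; frame 2 one ion moved away
  parts <- rbind(
    data.frame(particle_id = 1L, molecule_id = 1L,
               molecule_kind = "lipid", residue_index = 1L,
               residue_name = "LIP", site_name = "PO",
               group_tag = "phosphate", radius = 0.23),
    data.frame(particle_id = 2:4, molecule_id = 2:4,
               molecule_kind = "ion", residue_index = 1L,
               residue_name = "CA", site_name = "CA",
               group_tag = "none", radius = 0.23))
  sys <- molecular_system(parts)
  f1 <- md_frame(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0),
                       c(0, 0, 0.3)))
  f2 <- md_frame(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0),
                       c(0, 0, 5)))
  ib <- ion_binding_series(trajectory(sys, list(f1, f2)))
  expect_equal(ib$bound_count, c(3L, 2L))
  expect_equal(ib$displaced_count, c(0L, 1L))
  no_ions <- molecular_system(parts[1, , drop = FALSE])
  expect_error(
    ion_binding_series(trajectory(no_ions,
                                  list(md_frame(matrix(0, 1, 3))))),
    "no ions")
})
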