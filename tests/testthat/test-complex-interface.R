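test_that("Kabsch fit recovers rigid motions exactly", {
  set.seed(23)
  X <- matrix(stats::rnorm(30), 10, 3)
  fit0 <- kabsch_fit(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation about z plus translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- rigid_motion(X, R90, c(1, 2, 3))
  expect_lt(kabsch_fit(Y, X)$rmsd, 1e-10)
  for (k in 1:20) {
    Y2 <- rigid_motion(X)
    expect_lt(kabsch_fit(Y2, X)$rmsd, 1e-10)
    expect_equal(det(kabsch_fit(Y2, X)$rotation), 1, tolerance = 1e-9)
  }
  # degenerate (collinear) fit set
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "degenerate|collinear")
})

test_that("Kabsch RMSD matches a rotation-grid + polish oracle", {
  set.seed(29)
  X <- matrix(stats::rnorm(30), 10, 3)
  Y <- rigid_motion(X) + matrix(stats::rnorm(30, sd = 0.05), 10, 3)
  got <- kabsch_fit(Y, X)$rmsd
  # oracle: coarse grid over rotations (Euler angles), then polish with
  # general-purpose optimisation of the squared deviation
  obj <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    Yr <- sweep(Y, 2, colMeans(Y)) %*% t(R)
    Xr <- sweep(X, 2, colMeans(X))
    mean(rowSums((Yr - Xr)^2))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 7)[-7],
                      b = seq(0, pi, length.out = 5),
                      g = seq(0, 2 * pi, length.out = 7)[-7])
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  best <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(got, sqrt(best$value), tolerance = 1e-6)
})

test_that("RMSD series recovers a planted drift; least-squares optimality", {
  g <- gen_complex(receptor_residues = 12, drift = 0.02, n_frames = 40,
                   seed = 31, sequence = "HVFRL")
  tr <- g$trajectory
  rec <- select_particles(tr$system, kind = "receptor")
  bb <- select_particles(tr$system, kind = "peptide", site = "BB")
  rs <- rmsd_series(tr, fit_selection = rec, measure_selection = bb)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-12)
  expect_true(all(diff(rs$rmsd) > 0))
  expect_equal(rs$rmsd[40], 0.02 * 39, tolerance = 1e-9)
  # fitting on the measured set itself can only lower the RMSD
  rs_self <- rmsd_series(tr, fit_selection = bb, measure_selection = bb)
  expect_true(all(rs_self$rmsd <= rs$rmsd + 1e-12))
  # static trajectory: all zeros
  tr0 <- trajectory(tr$system, rep(tr$frames[1], 5))
  rs0 <- rmsd_series(tr0, rec, bb)
  expect_equal(rs0$rmsd, rep(0, 5), tolerance = 1e-12)
})

test_that("interaction detectors follow their geometric criteria", {
  # ring in the xy-plane at origin
  ring_sys <- point_system(8)
  ring_xyz <- pepscope:::ring_beads(c(0, 0, 0), c(0, 0, 1))
  # cation directly above the ring face
  f_above <- md_frame(rbind(ring_xyz, c(0, 0, 0.4), c(0, 0, 0)))
  above <- detect_cation_pi(f_above, cation = 7L, ring = 1:6)
  expect_true(above$present)
  expect_equal(above$distance, 0.4)
  expect_equal(above$angle, 0, tolerance = 1e-9)
  # cation in the ring plane at the same distance: angle gate fails
  f_side <- md_frame(rbind(ring_xyz, c(0.4, 0, 0), c(0, 0, 0)))
  side <- detect_cation_pi(f_side, cation = 7L, ring = 1:6)
  expect_false(side$present)
  expect_equal(side$angle, 90, tolerance = 1e-9)
  # parallel rings stack; perpendicular rings do not
  ring_b <- pepscope:::ring_beads(c(0, 0, 0.4), c(0, 0, 1))
  fp <- md_frame(rbind(ring_xyz, ring_b[1:2, ]))
  sysp <- point_system(8)
  expect_true(detect_pi_stacking(
    md_frame(rbind(ring_xyz, ring_b)), ring_a = 1:6,
    ring_b = 7:12)$present)
  ring_perp <- pepscope:::ring_beads(c(0, 0, 0.4), c(1, 0, 0))
  expect_false(detect_pi_stacking(
    md_frame(rbind(ring_xyz, ring_perp)), ring_a = 1:6,
    ring_b = 7:12)$present)
  # hydrogen bonds: distance and D-H-A angle gates
  f_hb <- md_frame(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.30, 0, 0)))
  hb <- detect_hbond(f_hb, donor = 1L, acceptor = 3L, hydrogen = 2L)
  expect_true(hb$present)
  expect_equal(hb$angle, 180, tolerance = 1e-9)
  f_far <- md_frame(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.40, 0, 0)))
  expect_false(detect_hbond(f_far, 1L, 3L, 2L)$present)
  # bent geometry below 120 degrees fails even at short distance
  f_bent <- md_frame(rbind(c(0, 0, 0), c(0.15, 0.2, 0), c(0.30, 0, 0)))
  bent <- detect_hbond(f_bent, 1L, 3L, 2L)
  expect_lt(bent$angle, 120)
  expect_false(bent$present)
  # CG mode: distance-only, flagged
  cg <- detect_hbond(f_hb, 1L, 3L)
  expect_true(cg$present)
  expect_true(cg$distance_only)
  expect_error(detect_hbond(f_hb, 1L, 1L), "differ")
  # collinear "ring" is a geometry error
  line <- cbind(seq(0, 1, length.out = 6), 0, 0)
  expect_error(detect_cation_pi(md_frame(rbind(line, c(0, 0, 1))),
                                cation = 7L, ring = 1:6), "collinear")
})

test_that("detectors agree with direct geometry on randomized frames", {
  set.seed(37)
  for (k in 1:50) {
    ctr <- stats::rnorm(3); nrm <- random_rotation()[, 3]
    ring <- pepscope:::ring_beads(ctr, nrm)
    cat_pos <- matrix(stats::rnorm(3, sd = 0.5) + ctr, 1, 3)
    f <- md_frame(rbind(ring, cat_pos))
    got <- detect_cation_pi(f, cation = 7L, ring = 1:6)
    v <- cat_pos[1, ] - colMeans(ring)
    d <- sqrt(sum(v^2))
    cosang <- abs(sum(v * nrm)) / d
    ang <- acos(pmin(1, cosang)) * 180 / pi
    expect_equal(got$distance, d, tolerance = 1e-9)
    expect_equal(got$present, d <= 0.6 && ang <= 45)
    # detectors are invariant under global rigid motion
    R <- random_rotation(); tv <- stats::rnorm(3)
    f2 <- md_frame(rigid_motion(f$coords, R, tv))
    got2 <- detect_cation_pi(f2, cation = 7L, ring = 1:6)
    expect_equal(got2$present, got$present)
    expect_equal(got2$distance, got$distance, tolerance = 1e-9)
  }
})

test_that("occupancy equals the planted fraction of satisfying frames", {
  for (p in c(0, 0.5, 0.8, 1.0)) {
    g <- gen_complex(receptor_residues = 8,
                     specs = list(list(kind = "cation_pi",
                                       receptor_residue = 3, p = p)),
                     n_frames = 50, seed = 41, sequence = "HVFRL")
    occ <- occupancy_series(g$trajectory, g$specs[[1]])
    expect_equal(occ$occupancy, p)
    expect_equal(occ$occupancy, mean(occ$series))
    expect_gte(occ$occupancy, 0); expect_lte(occ$occupancy, 1)
  }
  # alternating planted pattern is recovered exactly
  g8 <- gen_complex(receptor_residues = 8,
                    specs = list(list(kind = "hbond",
                                      receptor_residue = 5, p = 0.8)),
                    n_frames = 10, seed = 43, sequence = "HVFRL")
  occ8 <- occupancy_series(g8$trajectory, g8$specs[[1]])
  expect_equal(occ8$occupancy, 0.8)
  expect_equal(which(occ8$series), g8$truth$satisfied_frames[[1]])
})

test_that("a geometry built to violate the criteria yields occupancy 0", {
  # ammonium-style probe kept in the ring plane in every frame: the
  # distance can pass but the face-angle gate never does
  ring <- pepscope:::ring_beads(c(0, 0, 0), c(0, 0, 1))
  sys <- point_system(7)
  frames <- lapply(1:20, function(t)
    md_frame(rbind(ring, c(0.3 + 0.01 * t, 0, 0)), time = t - 1))
  tr <- trajectory(sys, frames)
  occ <- occupancy_series(tr, interaction_spec("cation_pi", a = 7L,
                                               b = 1:6))
  expect_equal(occ$occupancy, 0)
  expect_equal(occ$longest_event, 0L)
})

test_that("contact maps recover planted mixtures and hand counts", {
  g <- gen_complex(receptor_residues = 25,
                   contact_weights = c("12" = 6, "17" = 3, "22" = 1),
                   n_frames = 200, seed = 47, sequence = "HVFRL")
  prb <- which(g$trajectory$system$particles$site_name == "PRB")
  rec <- select_particles(g$trajectory$system, kind = "receptor")
  cmap <- residue_group_contact_map(g$trajectory, prb, rec)
  expect_equal(sum(cmap$contact_percentage), 100, tolerance = 1e-9)
  # counts equal the planted mixture draws exactly
  draws <- table(factor(g$truth$mixture_choice, levels = c(12, 17, 22)))
  expect_equal(cmap$count[cmap$residue_index == 12], unname(draws[1]))
  expect_equal(cmap$count[cmap$residue_index == 17], unname(draws[2]))
  expect_equal(cmap$count[cmap$residue_index == 22], unname(draws[3]))
  top <- top_contacts(cmap, 3)
  expect_setequal(top$residue_index, c(12, 17, 22))
  expect_error(residue_group_contact_map(g$trajectory, integer(), rec),
               "empty")
})

test_that("contact map matches a hand-countable two-frame fixture", {
  # probe at W45 in frame 1 (touching both ring beads placed there),
  # at Y82 in frame 2 (touching one bead)
  parts <- rbind(
    data.frame(particle_id = 1:2, molecule_id = 1L,
               molecule_kind = "receptor", residue_index = 45L,
               residue_name = "TRP", site_name = c("R1", "R2"),
               group_tag = "aromatic_ring", radius = 0.17),
    data.frame(particle_id = 3L, molecule_id = 1L,
               molecule_kind = "receptor", residue_index = 82L,
               residue_name = "TYR", site_name = "R1",
               group_tag = "aromatic_ring", radius = 0.17),
    data.frame(particle_id = 4L, molecule_id = 2L,
               molecule_kind = "peptide", residue_index = 1L,
               residue_name = "ARG", site_name = "SCP",
               group_tag = "cation_group", radius = 0.23))
  sys <- molecular_system(parts)
  f1 <- md_frame(rbind(c(0, 0, 0), c(0.4, 0, 0), c(5, 0, 0),
                       c(0.2, 0, 0)))
  f2 <- md_frame(rbind(c(0, 0, 0), c(0.4, 0, 0), c(5, 0, 0),
                       c(5.3, 0, 0)))
  tr <- trajectory(sys, list(f1, f2))
  cmap <- residue_group_contact_map(tr, group = 4L, receptor = 1:3)
  expect_equal(cmap$count[cmap$residue_index == 45], 2)
  expect_equal(cmap$count[cmap$residue_index == 82], 1)
  expect_equal(cmap$contact_percentage[cmap$residue_index == 45],
               200 / 3, tolerance = 1e-9)
})

test_that("profile correlation matches the rank-then-Pearson oracle", {
  mk <- function(idx, pct) data.frame(residue = paste0("R", idx),
                                      contact_percentage = pct)
  a <- mk(1:5, c(50, 30, 10, 5, 5))
  expect_equal(profile_spearman(a, a)$rho, 1)
  rev_ <- mk(1:5, c(5, 5, 10, 30, 50))
  b <- mk(1:5, c(1, 2, 3, 4, 5))
  d <- mk(1:5, c(5, 4, 3, 2, 1))
  expect_equal(profile_spearman(b, d)$rho, -1)
  set.seed(53)
  for (k in 1:20) {
    x <- mk(1:20, stats::runif(20, 0, 10))
    y <- mk(sample(1:25, 20), stats::runif(20, 0, 10))
    got <- profile_spearman(x, y)
    keys <- union(x$residue, y$residue)
    vx <- x$contact_percentage[match(keys, x$residue)]
    vy <- y$contact_percentage[match(keys, y$residue)]
    vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
    expect_equal(got$rho, oracle_spearman(vx, vy), tolerance = 1e-12)
    # symmetry
    expect_equal(profile_spearman(y, x)$rho, got$rho, tolerance = 1e-12)
  }
  expect_error(profile_spearman(mk(1:2, c(1, 2)), mk(1:2, c(2, 1))),
               "fewer than 3")
})
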