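test_that("system and trajectory invariants are enforced", {
  sys <- point_system(3)
  expect_s3_class(sys, "molecular_system")
  dup <- sys$particles; dup$particle_id[2] <- 1L
  expect_error(molecular_system(dup), "unique")
  bad <- sys$particles; bad$residue_index[1] <- 0L
  expect_error(molecular_system(bad), "residue_index")
  expect_error(md_frame(matrix(0, 2, 3), box = c(5, 5, -1)), "box")
  f <- md_frame(matrix(0, 3, 3))
  expect_error(trajectory(sys, list()), "at least one frame")
  expect_error(trajectory(sys, list(md_frame(matrix(0, 2, 3)))),
               "particle count")
  # non-increasing times are renumbered 0,1,2,...
  tr <- trajectory(sys, list(md_frame(matrix(0, 3, 3), time = 5),
                             md_frame(matrix(0, 3, 3), time = 5)))
  expect_equal(vapply(tr$frames, function(f) f$time, numeric(1)), c(0, 1))
})

test_that("sHVF18 peptide template has 18 residues starting with HIS", {
  p <- peptide_template("HVFRLKKWIXKVIXQFGE")
  expect_equal(p$residue_index, 1:18)
  expect_equal(p$residue_name[1], "HIS")
  expect_equal(p$residue_name[8], "TRP")
  expect_equal(sum(p$residue_name == "XAL"), 2L)
})

test_that("group classification applies ordered rules, first match wins", {
  sys <- molecular_system(data.frame(
    particle_id = 1:5, molecule_id = 1L, molecule_kind = "lipid",
    residue_index = 1L, residue_name = "LIP",
    site_name = c("PO41", "PO42", "HD1", "TA1", "GL0"),
    group_tag = "none", radius = 0.23))
  out <- classify_groups(sys, data.frame(
    residue = "LIP", site = c("PO4*", "HD*", "TA*"),
    tag = c("phosphate", "headgroup", "tail")))
  expect_equal(out$particles$group_tag,
               c("phosphate", "phosphate", "headgroup", "tail", "none"))
  # arginine guanidinium rule tags exactly its three sites
  arg <- molecular_system(data.frame(
    particle_id = 1:6, molecule_id = 1L, molecule_kind = "peptide",
    residue_index = 1L, residue_name = "ARG",
    site_name = c("N", "CA", "CZ", "NH1", "NH2", "NE"),
    group_tag = "none", radius = NA_real_))
  tagged <- classify_groups(arg)
  expect_equal(sum(tagged$particles$group_tag == "cation_group"), 3L)
  # first-match-wins: a site matching two rules takes the earlier tag
  two <- classify_groups(sys, data.frame(
    residue = c("LIP", "LIP"), site = c("PO4*", "PO41"),
    tag = c("phosphate", "tail")))
  expect_equal(two$particles$group_tag[1], "phosphate")
  expect_error(classify_groups(sys, data.frame(
    residue = "LIP", site = "PO4*", tag = "nonsense")), "group_tag")
  expect_warning(classify_groups(sys, data.frame(
    residue = "ZZZ", site = "QQ*", tag = "tail")), "no classification")
})

test_that("minimum-image distance matches 27-image enumeration", {
  box <- c(5, 5, 5)
  expect_equal(min_image_distance(c(0, 0, 0), c(4.9, 0, 0), box), 0.1)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)
  set.seed(11)
  for (k in 1:200) {
    bx <- stats::runif(3, 2, 8)
    a <- stats::runif(3) * bx; b <- stats::runif(3) * bx
    expect_equal(min_image_distance(a, b, bx), oracle_min_image(a, b, bx),
                 tolerance = 1e-12)
    # PBC distance never exceeds the open-boundary distance
    expect_lte(min_image_distance(a, b, bx),
               min_image_distance(a, b, NULL) + 1e-12)
    # symmetry
    expect_equal(min_image_distance(a, b, bx),
                 min_image_distance(b, a, bx))
  }
})

test_that("neighbor_pairs equals O(n^2) brute force, inclusive cutoff", {
  sys <- point_system(2)
  f <- md_frame(rbind(c(0, 0, 0), c(0.59, 0, 0)))
  expect_equal(nrow(neighbor_pairs(f, sys, 1:2, 1:2, 0.6)), 1L)
  f2 <- md_frame(rbind(c(0, 0, 0), c(0.61, 0, 0)))
  expect_equal(nrow(neighbor_pairs(f2, sys, 1:2, 1:2, 0.6)), 0L)
  expect_equal(nrow(neighbor_pairs(f, sys, integer(), 1:2, 0.6)), 0L)
  set.seed(7)
  for (k in 1:20) {
    n <- sample(20:60, 1)
    box <- if (k %% 2) c(3, 3, 3) else NULL
    X <- matrix(stats::runif(3 * n, 0, 3), n, 3)
    sys <- point_system(n)
    f <- md_frame(X, box = box)
    got <- sorted_pair_matrix(neighbor_pairs(f, sys, 1:n, 1:n, 0.6))
    want <- oracle_pairs(X, box, 1:n, 1:n, 0.6)
    expect_equal(unname(got), unname(want))
  }
})

test_that("PDB round-trip preserves coordinates and metadata", {
  g <- gen_aggregation(n_peptides = 3, beads_per_peptide = 5,
                       n_frames = 4, seed = 1,
                       sequence = "HVFRL")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(g$trajectory, path)
  back <- read_trajectory(path, "multi_model_pdb")
  expect_equal(n_frames(back), 4L)
  expect_equal(back$system$particles$molecule_id,
               g$trajectory$system$particles$molecule_id)
  expect_equal(back$system$particles$residue_name,
               g$trajectory$system$particles$residue_name)
  expect_equal(back$system$particles$molecule_kind,
               g$trajectory$system$particles$molecule_kind)
  # PDB has 3 decimal places in Angstrom -> 1e-4 nm
  expect_equal(back$frames[[2]]$coords, g$trajectory$frames[[2]]$coords,
               tolerance = 1e-3)
  expect_equal(back$frames[[1]]$box, c(15, 15, 15), tolerance = 1e-4)
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00",
    "END"), path)
  st <- read_structure(path, "pdb")
  expect_equal(unname(st$frame$coords[1, ]), c(0.10, 0.20, 0.30))
  expect_equal(st$system$particles$residue_name, "GLY")
})

test_that("GRO files parse with nm coordinates and box line", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "test system",
    "    2",
    "    1ALA     BB    1   1.000   2.000   3.000",
    "    2ALA     BB    2   2.000   2.000   3.000",
    "   5.0   5.0   5.0"), path)
  st <- read_structure(path, "gro")
  expect_equal(st$frame$box, c(5, 5, 5))
  expect_equal(unname(st$frame$coords[1, ]), c(1, 2, 3))
  # triclinic box line is rejected
  path2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               "    1ALA     BB    1   1.000   1.000   1.000",
               "  5.0 5.0 5.0 0.0 0.0 1.2 0.0 0.0 0.0"), path2)
  expect_error(read_structure(path2, "gro"), "triclinic")
  path3 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    3",
               "    1ALA     BB    1   1.000   1.000   1.000"), path3)
  expect_error(read_structure(path3, "gro"), "malformed")
})

test_that("xyz-frame trajectories round-trip bit-identically", {
  g <- gen_lipid_interface(n_lipids = 10, n_peptides = 2, n_ions = 3,
                           n_frames = 3, seed = 2, sequence = "HVFRL")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(g$trajectory, path)
  back <- read_trajectory(path, "xyz_frames")
  first <- readLines(path)
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(back, path2)
  expect_identical(first, readLines(path2))
  expect_equal(back$system$particles$group_tag,
               g$trajectory$system$particles$group_tag)
  # roster mismatch across frames is a format error
  lines <- readLines(path)
  n <- n_particles(g$trajectory$system)
  lines[n + 5L] <- sub("lipid", "ion", lines[n + 5L])
  writeLines(lines, path)
  expect_error(read_trajectory(path, "xyz_frames"), "roster")
})
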