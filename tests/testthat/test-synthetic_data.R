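test_that("references carry the programmed hinge angles exactly", {
  p <- hinge_params(theta_closed = 60, theta_open = 110)
  refs <- generate_references(p)
  dset <- hinge_domain_set(p)
  ang <- function(s) {
    traj <- traj_from_coords(list(s$coords), s$atoms)
    hinge_angle(domain_centers(traj, dset, "cog"), "I", "II", "III")$values
  }
  expect_equal(ang(refs$closed), 60, tolerance = 1e-6)
  expect_equal(ang(refs$open), 110, tolerance = 1e-6)
  # the two conformers differ
  expect_gt(fit_rmsd(refs$open$coords, refs$closed$coords), 0.5)
  # deterministic: no randomness before noise
  refs2 <- generate_references(p)
  expect_identical(refs$closed$coords, refs2$closed$coords)
})

test_that("parameter invariants are enforced", {
  expect_error(hinge_params(theta_closed = 120, theta_open = 110),
               class = "mdh_param_error")
  expect_error(hinge_params(noise_sigma = -1), class = "mdh_param_error")
  expect_error(hinge_params(n_frames = 100, transition_frame = 100),
               class = "mdh_param_error")
  expect_error(hinge_params(atoms_per_domain = 3), class = "mdh_param_error")
  expect_error(hinge_params(park_fraction = 1.5), class = "mdh_param_error")
})

test_that("noise-free closed run equals the closed reference in every frame", {
  p <- hinge_params(atoms_per_domain = 10L, n_frames = 5L, noise_sigma = 0)
  gen <- generate_trajectory(p)
  refs <- generate_references(p)
  for (f in 1:5)
    expect_equal(matrix(gen$trajectory$xyz[f, , ], ncol = 3), refs$closed$coords)
  r <- rmsd_series(gen$trajectory, refs$closed)
  expect_lt(max(r$values), 1e-10)
})

test_that("the seed fully determines the trajectory", {
  p <- hinge_params(atoms_per_domain = 8L, n_frames = 10L, seed = 5L)
  g1 <- generate_trajectory(p)
  g2 <- generate_trajectory(p)
  expect_identical(g1$trajectory$xyz, g2$trajectory$xyz)
  p2 <- hinge_params(atoms_per_domain = 8L, n_frames = 10L, seed = 6L)
  expect_false(identical(generate_trajectory(p2)$trajectory$xyz, g1$trajectory$xyz))
})

test_that("ground truth matches the measured noise-free observables", {
  p <- hinge_params(atoms_per_domain = 15L, n_frames = 30L, noise_sigma = 0,
                    transition_frame = 10L, park_fraction = 1)
  gen <- generate_trajectory(p)
  gt <- gen$ground_truth
  dset <- hinge_domain_set(p)
  rg <- radius_of_gyration(gen$trajectory)
  expect_equal(rg$values, gt$rg_t, tolerance = 1e-10)
  com <- domain_centers(gen$trajectory, dset, "com")
  expect_equal(interdomain_distance(com, "I", "III")$values,
               unname(gt$com_distance_t[, "I-III"]), tolerance = 1e-10)
  cog <- domain_centers(gen$trajectory, dset, "cog")
  expect_equal(hinge_angle(cog, "I", "II", "III")$values, gt$theta_t,
               tolerance = 1e-6)
  expect_equal(gt$state_label_t[1], "closed")
  expect_equal(gt$state_label_t[30], "open")
})

test_that("noisy estimates converge to ground truth as noise shrinks", {
  errs <- sapply(c(1.0, 0.1, 0.01), function(sig) {
    p <- hinge_params(atoms_per_domain = 20L, n_frames = 20L, noise_sigma = sig,
                      seed = 3L)
    gen <- generate_trajectory(p)
    com <- domain_centers(gen$trajectory, hinge_domain_set(p), "com")
    max(abs(interdomain_distance(com, "I", "III")$values -
            gen$ground_truth$com_distance_t[, "I-III"]))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("parked-phase RMSF approaches the isotropic-noise expectation", {
  # i.i.d. Gaussian noise sigma per coordinate about a rigid scaffold:
  # E|r - rbar|^2 = 3 sigma^2, so RMSF -> sqrt(3) * sigma
  p <- hinge_params(atoms_per_domain = 20L, n_frames = 2000L, noise_sigma = 0.5,
                    seed = 8L)
  gen <- generate_trajectory(p)
  prof <- rmsf_profile(gen$trajectory)
  interior <- prof$values[prof$residues %in% domain_residues(hinge_domain_set(p), "II")]
  expect_equal(mean(interior), sqrt(3) * 0.5, tolerance = 0.05)
})

test_that("designed contacts are active exactly while the hinge is closed", {
  p <- hinge_params(atoms_per_domain = 20L, n_frames = 100L, noise_sigma = 0.2,
                    transition_frame = 50L, park_fraction = 1,
                    designed_contacts = list(c(3L, 55L)), seed = 12L)
  # residue 55 lies in domain III for atoms_per_domain = 20, linker 6
  lay_dset <- hinge_domain_set(p)
  expect_true(55L %in% domain_residues(lay_dset, "III"))
  gen <- generate_trajectory(p)
  gt <- gen$ground_truth
  expect_true(all(gt$contact_active_t[1:49, 1]))
  expect_false(any(gt$contact_active_t[60:100, 1]))
  rec <- interaction_persistence(gen$trajectory, "SB", psn_params("residue_center"))
  rec <- rec[rec$residue_a == 3L & rec$residue_b == 55L, ]
  expect_equal(nrow(rec), 1L)
  # persistence tracks the programmed active fraction
  expect_equal(rec$persistence, mean(gt$contact_active_t[, 1]), tolerance = 0.02)
})

test_that("the fixture set is complete, readable and internally consistent", {
  out <- file.path(tempdir(), "mdh-fixtures")
  unlink(out, recursive = TRUE)
  paths <- write_fixture_set(out, hinge_params(atoms_per_domain = 12L,
                                               n_frames = 60L,
                                               designed_contacts = list(c(3L, 40L))))
  expect_length(paths, 7L)
  expect_true(all(file.exists(paths)))
  traj <- read_multimodel_pdb(paths[["traj_closed"]])
  expect_equal(n_frames(traj), 60L)
  dset <- read_domains_yaml(paths[["domains"]])
  expect_equal(sort(names(dset$domains)), c("I", "II", "III"))
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(sort(names(gt)), c("traj_closed", "traj_mutantlike", "traj_open"))
  expect_length(gt$traj_closed$theta_t, 60L)
  # trajectories stay within the documented size contract
  expect_true(all(file.size(paths[grepl("traj", names(paths))]) <= 5e6))
})
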