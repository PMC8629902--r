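test_that("frame accounting matches span/dt + 1 and rejects non-divisible spans", {
  expect_equal(frame_count(10, 2), 5001L)
  expect_equal(frame_count(1, 1), 1001L)
  expect_error(frame_count(10, 3), "divisible")
  expect_error(frame_count(-1, 2), "positive")
})

test_that("multi-model PDB trajectories round trip with timestamps", {
  ref <- toy_reference_structure(5)
  traj <- synth_trajectory(ref, sigma = 0.2, n_frames = 3, dt = 2, seed = 4)
  path <- write_trajectory_pdb(traj, tempfile(fileext = ".pdb"))
  back <- read_trajectory(path, dt = 2)
  expect_equal(nrow(back$xyz), 3L)
  expect_equal(back$times, c(0, 2, 4))
  expect_equal(back$atoms$elety, traj$atoms$elety)
  expect_equal(back$xyz[2, ], unname(traj$xyz[2, ]), tolerance = 1e-3)
})

test_that("a roster mismatch aborts naming the offending model", {
  ref <- toy_reference_structure(4)
  traj <- synth_trajectory(ref, sigma = 0.1, n_frames = 3, seed = 1)
  path <- write_trajectory_pdb(traj, tempfile(fileext = ".pdb"))
  lines <- readLines(path)
  # drop one atom from the second model
  starts <- grep("^MODEL", lines)
  writeLines(lines[-(starts[2] + 3L)], path)
  expect_error(read_trajectory(path), "model 2")
})

test_that("Kabsch superposition is exact on rigid copies and proper on reflections", {
  set.seed(8)
  x <- matrix(rnorm(30), ncol = 3)
  s <- superpose(x, x)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  rot <- zfmut:::.euler_rotation(0.4, 1.2, -0.9)
  y <- sweep(x %*% rot, 2, c(3, -1, 7), `+`)
  s2 <- superpose(y, x)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
  # fitted coordinates actually land on the reference
  expect_equal(s2$fitted, x, tolerance = 1e-9)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "3 paired atoms")
})

test_that("Kabsch minimum RMSD matches the rotation-grid brute force", {
  set.seed(21)
  for (i in 1:3) {
    a <- matrix(rnorm(15), ncol = 3)
    b <- matrix(rnorm(15), ncol = 3)
    kab <- superpose(a, b)$rmsd
    grid <- grid_rmsd_oracle(a, b, step_deg = 10)
    expect_lte(kab, grid + 1e-9)       # optimality
    expect_lt(grid - kab, 0.25)        # grid resolution bound
  }
})

test_that("RMSD series are zero for constant or rigidly moving trajectories", {
  ref <- toy_reference_structure(8)
  still <- synth_trajectory(ref, sigma = 0, n_frames = 5, seed = 2)
  expect_equal(rmsd_series(still)$rmsd, rep(0, 5), tolerance = 1e-9)
  moving <- synth_trajectory(ref, sigma = 0, n_frames = 5, rigid = TRUE,
                             seed = 2)
  expect_equal(rmsd_series(moving)$rmsd, rep(0, 5), tolerance = 1e-6)
  expect_equal(rmsd_series(still)$rmsd[1], 0)
  expect_error(rmsd_series(still, selection = integer(0)), "empty selection")
})

test_that("RMSD equals the hand formula on a constructed 2-atom deviation", {
  # after centring/rotation-free comparison, displacements 0.3 and 0.4 A
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0.3, 0, 0), c(1, 0.4, 0))
  expect_equal(rmsd_xyz(a, b), sqrt((0.09 + 0.16) / 2), tolerance = 1e-12)
})

test_that("random rigid motions do not change the RMSD of a noisy trajectory", {
  ref <- toy_reference_structure(8)
  plain <- synth_trajectory(ref, sigma = 0.4, n_frames = 30, seed = 5)
  moved <- plain
  set.seed(99)
  for (f in seq_len(nrow(moved$xyz))) {
    m <- matrix(moved$xyz[f, ], ncol = 3, byrow = TRUE)
    rot <- zfmut:::.euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                                   runif(1, 0, 2 * pi))
    m <- sweep(m %*% rot, 2, runif(3, -10, 10), `+`)
    moved$xyz[f, ] <- as.numeric(t(m))
  }
  expect_equal(rmsd_series(moved)$rmsd, rmsd_series(plain)$rmsd,
               tolerance = 1e-6)
})

test_that("RMSF profiles localise planted noise and are zero for constant input", {
  ref <- toy_reference_structure(10)
  still <- synth_trajectory(ref, sigma = 0, n_frames = 5, seed = 3)
  expect_equal(rmsf_profile(still)$rmsf, rep(0, 10), tolerance = 1e-9)
  sig <- c(rep(0.01, 4), 1.0, rep(0.01, 5))  # protein residues 1..10
  sig_all <- c(sig, rep(0.01, 6))            # DNA residues get none
  noisy <- synth_trajectory(ref, sigma = sig_all, n_frames = 300, seed = 6)
  prof <- rmsf_profile(noisy)                # backbone = protein only
  expect_equal(which.max(prof$rmsf), 5L)
  expect_gt(prof$rmsf[5], 5 * median(prof$rmsf[-5]))
  one_frame <- structure(list(atoms = still$atoms,
                              xyz = still$xyz[1, , drop = FALSE],
                              dt = 2, t0 = 0), class = "zf_trajectory")
  expect_error(rmsf_profile(one_frame), "2 frames")
})

test_that("planted per-residue sigma is recovered with high rank correlation", {
  ref <- toy_reference_structure(12)
  sig_prot <- seq(0.1, 1.2, length.out = 12)
  sig_all <- c(sig_prot, rep(0.05, 6))
  traj <- synth_trajectory(ref, sigma = sig_all, n_frames = 600, seed = 17)
  prof <- rmsf_profile(traj)
  expect_gt(cor(prof$rmsf, sig_prot, method = "spearman"), 0.95)
})

test_that("paired Wilcoxon matches sign-assignment enumeration and handles degeneracy", {
  x <- c(1.2, 0.8, 2.0, 1.5, 0.3, 1.1)
  y <- c(1.0, 1.1, 1.2, 1.1, 0.9, 0.4)
  out <- paired_wilcoxon(x, y)
  expect_true(out$exact)
  expect_equal(out$p_value, wilcoxon_exact_oracle(x - y), tolerance = 1e-12)
  same <- paired_wilcoxon(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$W, 0)
  expect_error(paired_wilcoxon(x, y[-1]), "paired")
})

test_that("series summaries use interpolated quartiles", {
  out <- series_summary(c(1, 2, 3, 4, 5))
  expect_equal(out$median, 3)
  expect_equal(out$q1, 2)
  expect_equal(out$q3, 4)
  expect_equal(series_summary(rep(7, 4))$sd, 0)
  set.seed(12)
  x <- rnorm(101)
  out2 <- series_summary(x)
  expect_equal(out2$q1, unname(quantile(x, 0.25, type = 7)),
               tolerance = 1e-12)
  expect_error(series_summary(numeric(0)), "empty")
})
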