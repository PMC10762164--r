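test_that("leaflet assignment uses the phosphorus-centroid midplane", {
  m <- structure_model(data.frame(
    name = "P", element = "P", resname = "POPC", chain = "L",
    resid = 1:3, x = c(0, 5, 10), y = 0, z = c(19, 18, -19),
    occ = 1, b = 0))
  la <- assign_leaflets(m, phosphorus_sel = select_atoms(m, "name P"))
  expect_equal(la$midplane_z, 6)
  expect_setequal(la$upper, c("L|1", "L|2"))
  expect_setequal(la$lower, "L|3")

  # symmetric bilayer splits evenly about z = 0
  fs <- make_toy_bilayer_series(n_lipids = 40, n_frames = 1, seed = 4)
  la2 <- assign_leaflets(fs$topology,
                         phosphorus_sel = select_atoms(fs$topology, "name P"))
  expect_equal(la2$midplane_z, 0, tolerance = 1e-9)
  expect_equal(length(la2$upper), length(la2$lower))
})

test_that("a flat bilayer reports its exact thickness in every defined bin", {
  fs <- make_toy_bilayer_series(n_lipids = 260, n_frames = 4, seed = 10)
  top <- fs$topology
  pr <- thickness_vs_distance(fs, select_atoms(top, "backbone"),
                              select_atoms(top, "resname POPC"),
                              r_max = 34.5)
  def <- !is.na(pr$mean_A)
  expect_true(any(def))
  expect_true(all(abs(pr$mean_A[def] - 38.6) < 1e-9))
  expect_true(all(pr$sd_A[def] < 1e-9))
  # conservation: every lipid lands in exactly one bin each frame
  expect_equal(sum(pr$n_obs), 260 * 4)

  # glycerol-centre marker reads the hydrophobic thickness, phosphate inset
  prg <- thickness_vs_distance(fs, select_atoms(top, "backbone"),
                               select_atoms(top, "resname POPC"),
                               marker = "glycerol_center", r_max = 34.5)
  defg <- !is.na(prg$mean_A)
  expect_true(all(abs(prg$mean_A[defg] - 30.6) < 1e-9))
  expect_true(all(pr$mean_A[def & defg] >= prg$mean_A[def & defg]))
})

test_that("a radially thinning bilayer is recovered at bin centres", {
  tfun <- function(d) 38 - 6 * exp(-d / 10)
  fs <- make_toy_bilayer_series(n_lipids = 600, disc_radius = 45,
                                thickness_fn = tfun, n_frames = 3,
                                seed = 12)
  top <- fs$topology
  pr <- thickness_vs_distance(fs, select_atoms(top, "backbone"),
                              select_atoms(top, "resname POPC"),
                              r_max = 34.5)
  ctr <- (pr$bin_lo_A + pr$bin_hi_A) / 2
  def <- !is.na(pr$mean_A) & pr$n_obs >= 15
  expect_gt(sum(def), 5)
  expect_lt(max(abs(pr$mean_A[def] - tfun(ctr[def]))), 0.3)
})

test_that("empty bins are flagged undefined, never silent zeros", {
  fs <- make_toy_bilayer_series(n_lipids = 60, disc_radius = 30,
                                n_frames = 1, seed = 2)
  top <- fs$topology
  pr <- thickness_vs_distance(fs, select_atoms(top, "backbone"),
                              select_atoms(top, "resname POPC"),
                              r_max = 60)
  far <- pr$bin_lo_A >= 30
  expect_true(all(is.na(pr$mean_A[far])))
  expect_true(all(pr$n_obs[far] == 0))
})

test_that("the polar map localises a thinned sector and is flat elsewhere", {
  fs_flat <- make_toy_bilayer_series(n_lipids = 400, n_frames = 2, seed = 5)
  ax <- pore_axis()
  pm <- polar_thickness_map(fs_flat, ax,
                            select_atoms(fs_flat$topology, "resname POPC"),
                            r_max = 45)
  def <- !is.na(pm$mean_A)
  expect_true(all(abs(pm$mean_A[def] - 38.6) < 1e-9))

  # one thinned sector: theta in [0, pi/15) at 30 A
  tfun <- function(d, th) ifelse(th < pi / 15, 30, 38.6)
  fs_sec <- make_toy_bilayer_series(n_lipids = 900, thickness_fn = tfun,
                                    n_frames = 2, seed = 6)
  pm2 <- polar_thickness_map(fs_sec, ax,
                             select_atoms(fs_sec$topology, "resname POPC"),
                             r_max = 45)
  in_sector <- pm2$theta_lo < pi / 15 - 1e-9
  def2 <- !is.na(pm2$mean_A)
  expect_true(all(abs(pm2$mean_A[def2 & in_sector] - 30) < 1e-6))
  expect_true(all(abs(pm2$mean_A[def2 & !in_sector] - 38.6) < 1e-6))
})

test_that("in-plane rotation leaves the radial profile unchanged and rotates the polar map", {
  fs <- make_toy_bilayer_series(n_lipids = 500, n_frames = 1, seed = 20,
                                thickness_fn = function(d, th)
                                  ifelse(th < pi / 15, 30, 38.6))
  top <- fs$topology
  pr1 <- thickness_vs_distance(fs, select_atoms(top, "backbone"),
                               select_atoms(top, "resname POPC"),
                               r_max = 34.5)
  rotated <- fs
  R <- discmetrics:::rotation_about(c(0, 0, 1), 2 * pi / 15)
  rotated$frames[1, , ] <- frame_coords(fs, 1) %*% t(R)
  pr2 <- thickness_vs_distance(rotated, select_atoms(top, "backbone"),
                               select_atoms(top, "resname POPC"),
                               r_max = 34.5)
  expect_equal(pr2$mean_A, pr1$mean_A, tolerance = 1e-9)

  ax <- pore_axis()
  pm1 <- polar_thickness_map(fs, ax, select_atoms(top, "resname POPC"),
                             r_max = 45)
  pm2 <- polar_thickness_map(rotated, ax, select_atoms(top, "resname POPC"),
                             r_max = 45)
  # rotating by two sectors shifts cell contents by two theta bins
  n_theta <- 30
  for (ri in unique(pm1$r_lo_A)) {
    a <- pm1$mean_A[pm1$r_lo_A == ri]
    b <- pm2$mean_A[pm2$r_lo_A == ri]
    shifted <- a[(seq_len(n_theta) - 1 - 2) %% n_theta + 1]
    expect_equal(b, shifted, tolerance = 1e-9)
  }
})

test_that("halving the sampling rate moves stochastic bin means only within noise", {
  fs <- make_toy_bilayer_series(n_lipids = 300, n_frames = 12,
                                noise_sd = 1, seed = 30)
  top <- fs$topology
  bb <- select_atoms(top, "backbone")
  lip <- select_atoms(top, "resname POPC")
  p_all <- thickness_vs_distance(fs, bb, lip, r_max = 34.5,
                                 sample_every_ps = 200)
  p_half <- thickness_vs_distance(fs, bb, lip, r_max = 34.5,
                                  sample_every_ps = 400)
  def <- !is.na(p_all$mean_A) & !is.na(p_half$mean_A) & p_all$n_obs > 40
  tol <- 2 * p_all$sd_A[def] / sqrt(pmax(attr(p_all, "frames_used"), 1)) +
    2 * p_all$sd_A[def]   # generous noise band for few frames
  expect_true(all(abs(p_all$mean_A[def] - p_half$mean_A[def]) <= tol))
})

test_that("windowing errors are raised for impossible requests", {
  fs <- make_toy_bilayer_series(n_lipids = 30, n_frames = 3, seed = 1)
  top <- fs$topology
  expect_error(
    thickness_vs_distance(fs, select_atoms(top, "backbone"),
                          select_atoms(top, "resname POPC"),
                          r_max = 34.5, window_ns = 10),
    "window")
})
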