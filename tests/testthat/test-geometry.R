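ptm <- make_toy_pentamer(tilt_m2 = 5, tilt_m4 = 20, seed = 42)
m2_sel <- select_atoms(ptm, "calpha and resid 230:247")
pax <- compute_pore_axis(ptm, m2_sel)

test_that("the pore axis of a z-built pentamer is +z through the centroid", {
  expect_equal(abs(sum(pax$direction * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_equal(pax$origin[1:2], c(0, 0), tolerance = 1e-6)
})

test_that("the pore axis is equivariant under a known rigid motion", {
  u <- c(1, 2, 2) / 3
  t_ <- c(10, -5, 3)
  rot <- rotate_model(ptm, u, 25, t_)
  R <- discmetrics:::rotation_about(u, 25 * pi / 180)
  ax2 <- compute_pore_axis(rot, select_atoms(rot, "calpha and resid 230:247"),
                           orient_ref = drop(R %*% c(0, 0, 1)))
  expect_equal(abs(sum(ax2$direction * drop(R %*% pax$direction))), 1,
               tolerance = 1e-6)
  expected_origin <- drop(R %*% pax$origin) + t_
  expect_equal(ax2$origin, expected_origin, tolerance = 1e-6)
})

test_that("a single-chain fragment raises a symmetry error", {
  frag <- ptm[ptm$chain == "A", ]
  class(frag) <- c("structure_model", "data.frame")
  expect_error(
    compute_pore_axis(frag, select_atoms(frag, "calpha and resid 230:247")),
    "symmetry")
})

test_that("residue-axis distance matches hand values and a brute-force oracle", {
  one <- structure_model(data.frame(
    name = "CA", element = "C", resname = "ALA", chain = "A", resid = 1L,
    x = 5, y = 0, z = 10, occ = 1, b = 0))
  ax <- pore_axis(c(0, 0, 0), c(0, 0, 1))
  dp <- residue_axis_distance(one, ax, select_atoms(one, "calpha"))
  expect_equal(dp$value, 5)

  # five-fold symmetry: per-residue SD across subunits is zero
  dp5 <- residue_axis_distance(ptm, pax, m2_sel)
  s <- attr(dp5, "summary")
  expect_true(all(s$sd < 1e-9))
  expect_true(all(s$n == 5))
  # helix CA ring oscillates about the ring radius by the coil radius
  expect_equal(mean(s$mean), 8, tolerance = 0.35)

  # arbitrary axis, random points, vs dense line-sampling oracle
  set.seed(7)
  ax2 <- pore_axis(origin = c(3, -2, 1), direction = c(1, 1, 0.5))
  pts <- matrix(rnorm(60, sd = 10), ncol = 3)
  got <- discmetrics:::axis_distance(pts, ax2)
  want <- apply(pts, 1, brute_axis_distance, origin = ax2$origin,
                direction = ax2$direction)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("helix tilt recovers generator ground truth and its edge cases", {
  flat <- make_toy_pentamer(tilt_m4 = 0, seed = 1)
  axf <- compute_pore_axis(flat, select_atoms(flat, "calpha and resid 230:247"))
  t0 <- helix_tilt_angle(flat, select_atoms(flat, "calpha and resid 305:322"),
                         axf)
  expect_lt(abs(t0$mean_deg - 0), 0.1)

  m20 <- make_toy_pentamer(tilt_m4 = 20, seed = 1)
  t20 <- helix_tilt_angle(
    m20, select_atoms(m20, "calpha and resid 305:322"),
    compute_pore_axis(m20, select_atoms(m20, "calpha and resid 230:247")))
  expect_lt(abs(t20$mean_deg - 20), 0.2)

  # invariance to reversing the CA order
  rev20 <- m20[rev(seq_len(nrow(m20))), ]
  class(rev20) <- c("structure_model", "data.frame")
  trev <- helix_tilt_angle(rev20, select_atoms(rev20,
                                               "calpha and resid 305:322"),
                           compute_pore_axis(rev20,
                             select_atoms(rev20, "calpha and resid 230:247")))
  expect_equal(trev$mean_deg, t20$mean_deg, tolerance = 1e-9)

  # too few points
  tiny <- m20[m20$chain == "A" & m20$resid %in% 305:307, ]
  class(tiny) <- c("structure_model", "data.frame")
  expect_error(helix_tilt_angle(tiny, select_atoms(tiny, "calpha"), pax),
               "insufficient")
})

test_that("superposition recovers exact rigid motions and stays proper", {
  sel <- select_atoms(ptm, "calpha")
  idt <- superpose(ptm, ptm, sel, sel)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idt$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(idt$rmsd, 0, tolerance = 1e-9)

  rot <- rotate_model(ptm, c(0, 0, 1), 10)
  tf <- superpose(ptm, rot, sel, select_atoms(rot, "calpha"))
  ang <- acos((sum(diag(tf$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-6)
  expect_lt(tf$rmsd, 1e-9)

  # cross-check rotation against bio3d's least-squares fit
  P <- coords(ptm, sel)
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(coords(rot))),
                   mobile = as.vector(t(P))))
  fitted_bio3d <- matrix(xyz_fit, ncol = 3, byrow = TRUE)
  ours <- discmetrics:::apply_transform(P, tf)
  expect_lt(max(abs(ours - fitted_bio3d)), 1e-6)

  # mirror image: proper rotation enforced, residual nonzero
  mir <- set_coords(ptm, coords(ptm) %*% diag(c(-1, 1, 1)))
  tfm <- superpose(mir, ptm, select_atoms(mir, "calpha"), sel)
  expect_equal(det(tfm$rotation), 1, tolerance = 1e-9)
  expect_gt(tfm$rmsd, 0.1)
})

test_that("ECD rotation reports the signed axial twist with the stated convention", {
  ref <- make_toy_pentamer(tilt_m4 = 20, ecd_twist = 0, seed = 13)
  tw <- make_toy_pentamer(tilt_m4 = 20, ecd_twist = 2, seed = 13)
  er <- ecd_rotation_angle(ref, tw)
  expect_equal(er$twist_deg, 2, tolerance = 0.05)
  expect_equal(ecd_rotation_angle(ref, ref)$twist_deg, 0, tolerance = 1e-9)
  # antisymmetry under swapping the two structures
  expect_equal(ecd_rotation_angle(tw, ref)$twist_deg, -er$twist_deg,
               tolerance = 0.05)
})

test_that("pairwise distances follow Euclid and ring symmetry", {
  two <- structure_model(data.frame(
    name = c("CA", "CB"), element = "C", resname = "ALA", chain = "A",
    resid = c(1L, 2L), x = c(0, 3), y = c(0, 4), z = 0, occ = 1, b = 0))
  expect_equal(pairwise_residue_distance(two, list("A", 1, "CA"),
                                         list("A", 2, "CB")), 5)
  expect_equal(pairwise_residue_distance(two, list("A", 1, "CA"),
                                         list("A", 1, "CA")), 0)
  ring <- pairwise_residue_distance(ptm, list("A", 240, "CA"),
                                    list("B", 240, "CA"),
                                    around_ring = TRUE)
  expect_equal(nrow(ring), 5)
  expect_lt(max(ring$distance) - min(ring$distance), 1e-9)
  expect_error(pairwise_residue_distance(ptm, list("A", 999, "CA"),
                                         list("A", 240, "CA")), "not found")
})

test_that("pore radius equals ring arithmetic and a polar-grid oracle", {
  ring <- toy_ring_model(radius = 6, n = 12, z = 0)
  ax <- pore_axis()
  pp <- pore_radius_profile(ring, ax, z_range = c(0, 0), step = 1)
  expect_equal(pp$radius_A[1], 6 - 1.70, tolerance = 1e-9)

  # vdW inflation shifts every defined sample down by exactly delta
  infl <- discmetrics:::VDW_RADII + 0.25
  pp2 <- pore_radius_profile(ring, ax, z_range = c(0, 0), step = 1,
                             vdw = infl)
  expect_equal(pp2$radius_A[1], pp$radius_A[1] - 0.25, tolerance = 1e-12)

  # random cloud vs brute-force slab minimum
  set.seed(31)
  n <- 40
  cloud <- structure_model(data.frame(
    name = paste0("C", 1:n), element = sample(c("C", "N", "O", "S"), n, TRUE),
    resname = "XXX", chain = "A", resid = 1:n,
    x = rnorm(n, sd = 6), y = rnorm(n, sd = 6), z = runif(n, -8, 8),
    occ = 1, b = 0))
  prof <- pore_radius_profile(cloud, ax, z_range = c(-6, 6), step = 2)
  lookup <- function(e) discmetrics:::vdw_radius(e)
  for (i in seq_len(nrow(prof))) {
    want <- brute_pore_radius(cloud, ax, prof$z[i], 2, lookup)
    if (is.na(want)) expect_true(is.na(prof$radius_A[i]))
    else expect_equal(prof$radius_A[i], want, tolerance = 0.05)
  }
})

test_that("geometry is invariant under a global rigid motion", {
  u <- c(0.2, -0.4, 0.89)
  mov <- rotate_model(ptm, u, 33, c(5, 6, -7))
  ax2 <- compute_pore_axis(mov, select_atoms(mov, "calpha and resid 230:247"),
                           orient_ref = drop(
                             discmetrics:::rotation_about(
                               u / sqrt(sum(u^2)), 33 * pi / 180) %*% c(0, 0, 1)))
  s1 <- attr(residue_axis_distance(ptm, pax, m2_sel), "summary")
  s2 <- attr(residue_axis_distance(
    mov, ax2, select_atoms(mov, "calpha and resid 230:247")), "summary")
  expect_equal(s2$mean, s1$mean, tolerance = 1e-6)
  t1 <- helix_tilt_angle(ptm, select_atoms(ptm, "calpha and resid 305:322"),
                         pax)
  t2 <- helix_tilt_angle(mov, select_atoms(mov, "calpha and resid 305:322"),
                         ax2)
  expect_equal(t2$mean_deg, t1$mean_deg, tolerance = 1e-6)
})
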