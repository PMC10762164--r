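test_that("scripted contacts yield exact probabilities and threshold behaviour", {
  scr <- list(list(resid = 2, partner_resname = "LYS", frames = 1:25),
              list(resid = 4, partner_resname = "SER", frames = 1:30))
  fs <- make_toy_scaffold_series(contact_script = scr, n_frames = 100,
                                 seed = 17)
  top <- fs$topology
  cp <- contact_probability(fs, select_atoms(top, "chain P"),
                            select_atoms(top, "chain M N S"))
  expect_equal(cp$probability[cp$resid == 2], 0.25)
  expect_equal(cp$probability[cp$resid == 4], 0.30)
  # strict > 25% rule: 0.25 is excluded, 0.30 is in
  expect_false(cp$is_high_contact[cp$resid == 2])
  expect_true(cp$is_high_contact[cp$resid == 4])
  expect_true(all(cp$probability >= 0 & cp$probability <= 1))
})

test_that("an atom pair at exactly the cutoff counts as a contact", {
  top <- structure_model(data.frame(
    name = c("CA", "CB"), element = "C", resname = c("LEU", "ALA"),
    chain = c("P", "M"), resid = c(1L, 1L),
    x = c(0, 4.5), y = 0, z = 0, occ = 1, b = 0))
  fr <- array(0, c(1, 2, 3))
  fr[1, , ] <- coords(top)
  fs <- frame_series(top, fr, 200)
  cp <- contact_probability(fs, select_atoms(top, "chain P"),
                            select_atoms(top, "chain M"), cutoff_A = 4.5)
  expect_equal(cp$probability, 1)
  fr[1, 2, 1] <- 4.5 + 1e-9
  fs2 <- frame_series(top, fr, 200)
  cp2 <- contact_probability(fs2, select_atoms(top, "chain P"),
                             select_atoms(top, "chain M"), cutoff_A = 4.5)
  expect_equal(cp2$probability, 0)
})

test_that("grid-accelerated contacts equal the naive all-pairs oracle exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    n_p <- 12; n_s <- 25; nf <- 4
    top <- structure_model(data.frame(
      name = c(paste0("A", 1:n_p), paste0("B", 1:n_s)),
      element = "C",
      resname = c(rep("LEU", n_p), rep("ALA", n_s)),
      chain = rep(c("P", "M"), c(n_p, n_s)),
      resid = c(rep(1:4, length.out = n_p), seq_len(n_s)),
      x = runif(n_p + n_s, -12, 12), y = runif(n_p + n_s, -12, 12),
      z = runif(n_p + n_s, -12, 12), occ = 1, b = 0))
    fr <- array(rnorm(nf * nrow(top) * 3, sd = 6), c(nf, nrow(top), 3))
    fs <- frame_series(top, fr, 200)
    p_idx <- selection_indices(select_atoms(top, "chain P"))
    s_idx <- selection_indices(select_atoms(top, "chain M"))
    got <- contact_probability(fs, select_atoms(top, "chain P"),
                               select_atoms(top, "chain M"))
    want <- naive_contact_probability(fs, p_idx, s_idx, 4.5)
    expect_identical(got$probability,
                     want$probability[match(paste(got$chain, got$resid),
                                            want$residue)])
  }
})

test_that("contact probability is monotone non-decreasing in the cutoff", {
  fs <- make_toy_scaffold_series(
    contact_script = list(list(resid = 1, partner_resname = "LYS",
                               frames = 1:50)),
    n_frames = 100, seed = 3)
  top <- fs$topology
  p1 <- contact_probability(fs, select_atoms(top, "chain P"),
                            select_atoms(top, "chain M N S"),
                            cutoff_A = 3.0)
  p2 <- contact_probability(fs, select_atoms(top, "chain P"),
                            select_atoms(top, "chain M N S"),
                            cutoff_A = 6.0)
  expect_true(all(p2$probability >= p1$probability))
})

test_that("partner ratios count residue-frame events and sum to one", {
  scr <- list(list(resid = 1, partner_resname = "LYS", frames = 1:40))
  fs <- make_toy_scaffold_series(contact_script = scr, n_frames = 100,
                                 seed = 9)
  top <- fs$topology
  cp <- contact_probability(fs, select_atoms(top, "chain P"),
                            select_atoms(top, "chain M N S"))
  pr <- partner_type_ratio(cp)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$charged, 1)
  expect_equal(pr$nonpolar + pr$polar + pr$charged + pr$aromatic, 1,
               tolerance = 1e-9)

  # mixed partners: 3 leucine events to 1 serine event -> 0.75 / 0.25
  scr2 <- list(list(resid = 1, partner_resname = "LEU", frames = 1:30),
               list(resid = 1, partner_resname = "SER", frames = 1:10))
  fs2 <- make_toy_scaffold_series(contact_script = scr2, n_frames = 100,
                                  seed = 9)
  top2 <- fs2$topology
  cp2 <- contact_probability(fs2, select_atoms(top2, "chain P"),
                             select_atoms(top2, "chain M N S"))
  pr2 <- partner_type_ratio(cp2)
  expect_equal(pr2$nonpolar, 0.75)
  expect_equal(pr2$polar, 0.25)
})

test_that("overlapping protein/scaffold selections are rejected", {
  fs <- make_toy_scaffold_series(n_frames = 5, seed = 2)
  top <- fs$topology
  expect_error(contact_probability(fs, select_atoms(top, "chain P"),
                                   select_atoms(top, "chain P M")),
               "overlap")
})
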