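# All generators draw from an explicitly seeded local RNG stream
# (withr-style, restored on exit) so identical specs give bit-identical
# output and the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# ideal alpha-helix C-alpha trace: rise 1.5 A, 100 deg twist per residue,
# coil radius `coil_r`, centred on the origin, axis = +z
ideal_helix <- function(n_res, coil_r = 2.3) {
  j <- seq_len(n_res) - 1
  phi <- j * 100 * pi / 180
  pts <- cbind(coil_r * cos(phi), coil_r * sin(phi), 1.5 * j)
  sweep(pts, 2, colMeans(pts))
}

#' Synthetic C5 pentamer with known geometry
#'
#' Builds a five-fold symmetric two-domain pentamer mimicking a pLGIC:
#' per chain an "M2" ideal alpha-helix (pore-lining ring), an "M4" helix
#' (lipid-facing ring), both C-alpha only with parameterisable ring radius
#' and tilt away from the pore axis (+z), and an "ECD" blob of C-alpha
#' pseudo-atoms that can be twisted about the axis by a known angle
#' relative to the untwisted reference. Chains A-E are exact 72-degree
#' copies. Residue numbering places the helices in the transmembrane range
#' (M2 230-247, M4 305-322) and the ECD below 201.
#'
#' @param ring_m2,ring_m4 ring radii of the helix axes, Angstrom
#' @param tilt_m2,tilt_m4 helix tilt from the pore axis, degrees (0-80);
#'   tilting is radial (top leans away from the pore)
#' @param ecd_twist rotation of the ECD about the pore axis, degrees
#'   (positive = counter-clockwise seen from the extracellular side)
#' @param n_res_helix residues per helix (default 18 = five exact turns,
#'   which makes the principal helix axis exact)
#' @param n_res_ecd ECD pseudo-residues per chain
#' @param noise_sd isotropic coordinate jitter, Angstrom
#' @param seed RNG seed (used for the ECD blob and noise)
#' @return a `structure_model`; attribute `ground_truth` records all
#'   generating parameters
#' @export
make_toy_pentamer <- function(ring_m2 = 8, ring_m4 = 20,
                              tilt_m2 = 0, tilt_m4 = 0,
                              ecd_twist = 0, n_res_helix = 18,
                              n_res_ecd = 30, noise_sd = 0, seed = 1) {
  stopifnot(ring_m2 > 0, ring_m4 > 0,
            tilt_m2 >= 0, tilt_m2 <= 80, tilt_m4 >= 0, tilt_m4 <= 80)
  with_seed(seed, {
    ecd_local <- cbind(stats::runif(n_res_ecd, -6, 6),
                       stats::runif(n_res_ecd, -6, 6),
                       stats::runif(n_res_ecd, -6, 6))
    helix_block <- function(n, ring_r, tilt_deg, z_center, resid0) {
      h <- ideal_helix(n)
      # tilt about the tangential (y) direction: top leans radially (+x)
      R <- rotation_about(c(0, -1, 0), tilt_deg * pi / 180)
      h <- h %*% t(R)
      h <- sweep(h, 2, c(ring_r, 0, z_center), "+")
      list(xyz = h, resid = resid0 + seq_len(n) - 1)
    }
    m2 <- helix_block(n_res_helix, ring_m2, tilt_m2, -17, 230)
    m4 <- helix_block(n_res_helix, ring_m4, tilt_m4, -17,
                      323 - n_res_helix)
    ecd <- sweep(ecd_local, 2, c(15, 0, 12), "+")
    Rtw <- rotation_about(c(0, 0, 1), ecd_twist * pi / 180)
    ecd <- ecd %*% t(Rtw)
    chains <- LETTERS[1:5]
    rows <- list()
    for (k in 1:5) {
      Rc <- rotation_about(c(0, 0, 1), (k - 1) * 2 * pi / 5)
      block <- function(xyz, resid, seg) {
        xyz <- xyz %*% t(Rc)
        data.frame(name = "CA", element = "C", resname = "ALA",
                   chain = chains[k], resid = resid,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occ = 1, b = 0, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- block(m2$xyz, m2$resid)
      rows[[length(rows) + 1]] <- block(m4$xyz, m4$resid)
      rows[[length(rows) + 1]] <- block(ecd, 50 + seq_len(n_res_ecd) - 1)
    }
    df <- do.call(rbind, rows)
    if (noise_sd > 0) {
      df$x <- df$x + stats::rnorm(nrow(df), 0, noise_sd)
      df$y <- df$y + stats::rnorm(nrow(df), 0, noise_sd)
      df$z <- df$z + stats::rnorm(nrow(df), 0, noise_sd)
    }
    m <- structure_model(df)
    attr(m, "ground_truth") <- list(
      ring_m2 = ring_m2, ring_m4 = ring_m4, tilt_m2 = tilt_m2,
      tilt_m4 = tilt_m4, ecd_twist = ecd_twist,
      n_res_helix = n_res_helix, n_res_ecd = n_res_ecd,
      m2_resid = range(m2$resid), m4_resid = range(m4$resid),
      ecd_resid = c(50, 50 + n_res_ecd - 1),
      noise_sd = noise_sd, seed = seed)
    m
  })
}

# rigid cylindrical "protein" inclusion: backbone rings every 0.75 A in z,
# 16 residues x 4 atoms (N, CA, C, O) per ring, resids cycling through the
# transmembrane range 201-322 across spare chain letters. Dense enough
# that the min atom distance tracks the cylinder-surface distance to a
# few tenths of an Angstrom.
inclusion_ring_atoms <- function(inclusion_radius) {
  zr <- seq(-24, 24, by = 0.75)
  n_per_ring <- 64
  angs <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  rows <- vector("list", length(zr))
  res_counter <- 0
  bb_names <- c("N", "CA", "C", "O")
  bb_elem <- c("N", "C", "C", "O")
  for (zi in seq_along(zr)) {
    res_idx <- res_counter + rep(seq_len(n_per_ring / 4), each = 4)
    res_counter <- max(res_idx)
    rows[[zi]] <- data.frame(
      name = rep(bb_names, n_per_ring / 4),
      element = rep(bb_elem, n_per_ring / 4),
      resname = "ALA",
      chain = c("F", "G", "H", "I", "J", "K", "Q", "R", "T", "U", "V",
                "W", "X", "Y", "Z")[1 + (res_idx - 1) %/% 122],
      resid = 201 + (res_idx - 1) %% 122,
      x = inclusion_radius * cos(angs),
      y = inclusion_radius * sin(angs),
      z = zr[zi], occ = 1, b = 0, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  list(atoms = atoms, xyz = as.matrix(atoms[, c("x", "y", "z")]))
}

#' Synthetic nanodisc bilayer trajectory with known thickness field
#'
#' Places `n_lipids` two-leaflet "lipids" uniformly in the annulus between
#' a rigid cylindrical protein inclusion and the disc rim. Each lipid is
#' one residue carrying a phosphorus marker atom (name P) at height
#' `+/- thickness_fn(d) / 2` — `d` the smallest distance between the
#' phosphorus and any inclusion backbone atom, the same quantity the
#' thickness analysis bins on — and a glycerol-like group (C1, C2, C3,
#' O21, O31) whose geometric centre sits `glycerol_inset` Angstrom inside
#' the phosphate height. The inclusion contributes backbone atoms
#' (N, CA, C, O) on a cylinder of rings spanning the lipid heights.
#' Optional per-frame Gaussian jitter of lipid heights emulates thermal
#' noise.
#'
#' @param n_lipids number of lipids (half per leaflet, alternating)
#' @param disc_radius outer rim radius, Angstrom
#' @param thickness_fn function d -> bilayer thickness (Angstrom); either
#'   vectorised over d, or of (d, theta)
#' @param inclusion_radius protein cylinder radius, Angstrom
#' @param n_frames,dt_ps trajectory length and frame interval
#' @param noise_sd per-frame SD of lipid z jitter, Angstrom
#' @param glycerol_inset offset of glycerol centre from phosphate height
#' @param seed RNG seed
#' @return a `frame_series`; attribute `ground_truth` records parameters
#' @export
make_toy_bilayer_series <- function(n_lipids = 500, disc_radius = 45,
                                    thickness_fn = function(d) 38.6,
                                    inclusion_radius = 12,
                                    n_frames = 10, dt_ps = 200,
                                    noise_sd = 0, glycerol_inset = 4,
                                    seed = 1) {
  stopifnot(inclusion_radius < disc_radius, n_lipids >= 2)
  with_seed(seed, {
    r <- sqrt(stats::runif(n_lipids, inclusion_radius^2, disc_radius^2))
    th <- stats::runif(n_lipids, 0, 2 * pi)
    upper <- (seq_len(n_lipids) %% 2) == 1
    # the thickness field is a function of the distance the analysis
    # measures: min distance from the lipid phosphorus to any inclusion
    # backbone atom. That distance depends weakly on the phosphate height,
    # so iterate once from the in-plane estimate.
    inc_xyz <- inclusion_ring_atoms(inclusion_radius)$xyz
    eval_t <- function(d) {
      t_arg <- tryCatch(thickness_fn(d, th), error = function(e) NULL)
      tk <- if (is.null(t_arg)) thickness_fn(d) else t_arg
      rep_len(tk, n_lipids)
    }
    lx <- r * cos(th); ly <- r * sin(th)
    d <- r - inclusion_radius
    for (it in 1:2) {
      tk <- eval_t(d)
      zP <- ifelse(upper, tk / 2, -tk / 2)
      d <- min_cross_distance(cbind(lx, ly, zP), inc_xyz)
    }
    tk <- eval_t(d)
    if (any(tk <= 2 * glycerol_inset))
      stop("make_toy_bilayer_series: thickness_fn must exceed ",
           "2 * glycerol_inset over the disc")
    half <- ifelse(upper, tk / 2, -tk / 2)
    ghalf <- ifelse(upper, tk / 2 - glycerol_inset,
                    -(tk / 2 - glycerol_inset))
    # glycerol group: 5 atoms, zero-mean offsets so the centre is exact
    goff <- cbind(c(0.8, -0.8, 0, 0.4, -0.4),
                  c(0, 0, 0.9, -0.45, -0.45),
                  c(0.5, 0.5, -0.4, -0.3, -0.3))
    goff <- sweep(goff, 2, colMeans(goff))
    lip_rows <- vector("list", n_lipids)
    for (i in seq_len(n_lipids)) {
      gx <- lx[i] + goff[, 1]; gy <- ly[i] + goff[, 2]
      gz <- ghalf[i] + goff[, 3]
      lip_rows[[i]] <- data.frame(
        name = c("P", "C1", "C2", "C3", "O21", "O31"),
        element = c("P", "C", "C", "C", "O", "O"),
        resname = "POPC", chain = "L", resid = i,
        x = c(lx[i], gx), y = c(ly[i], gy), z = c(half[i], gz),
        occ = 1, b = 0, stringsAsFactors = FALSE)
    }
    top <- structure_model(do.call(rbind,
      c(lip_rows, list(inclusion_ring_atoms(inclusion_radius)$atoms))))
    base <- coords(top)
    frames <- array(0, c(n_frames, nrow(top), 3))
    lip_atom_idx <- which(top$chain == "L")
    for (f in seq_len(n_frames)) {
      xyz <- base
      if (noise_sd > 0) {
        jit <- rep(stats::rnorm(n_lipids, 0, noise_sd), each = 6)
        xyz[lip_atom_idx, 3] <- xyz[lip_atom_idx, 3] + jit
      }
      frames[f, , ] <- xyz
    }
    fs <- frame_series(top, frames, dt_ps)
    attr(fs, "ground_truth") <- list(
      n_lipids = n_lipids, disc_radius = disc_radius,
      inclusion_radius = inclusion_radius,
      thickness_fn = thickness_fn, glycerol_inset = glycerol_inset,
      noise_sd = noise_sd, seed = seed,
      lipid_d = d, lipid_theta = th, lipid_upper = upper)
    fs
  })
}

#' Synthetic scaffold-belt trajectory with scripted contacts
#'
#' Builds a trajectory holding a small protein (chain P, one C-alpha per
#' residue, leucines by default), a scaffold belt of backbone-like points
#' on an ellipse (chains M and N, stacked rings), and optional scripted
#' scaffold partner residues (chain S) that sit within the contact cutoff
#' of chosen protein residues in exactly the scripted frames and far away
#' otherwise. The belt may "breathe": `a(t) = a + amp * sin(2 pi t / T)`.
#'
#' @param a,b ellipse semi-axes, Angstrom (`a >= b`)
#' @param orientation major-axis angle, radians
#' @param n_points belt points (split over the two scaffold chains)
#' @param breathing_amp,breathing_period_ps amplitude (Angstrom) and
#'   period (ps) of the semi-major axis oscillation; amp 0 = static
#' @param n_prot_res protein residues (resid 1..n)
#' @param contact_script list of entries
#'   `list(resid =, partner_resname =, frames =)`: scripted contact frames
#'   (1-based indices) for each protein residue
#' @param contact_distance in-contact atom distance, Angstrom
#' @param n_frames,dt_ps trajectory length and frame interval
#' @param seed RNG seed
#' @return a `frame_series`; attribute `ground_truth` records parameters
#' @export
make_toy_scaffold_series <- function(a = 45, b = 45, orientation = 0,
                                     n_points = 80, breathing_amp = 0,
                                     breathing_period_ps = 2000,
                                     n_prot_res = 5,
                                     contact_script = list(),
                                     contact_distance = 3,
                                     n_frames = 100, dt_ps = 200,
                                     seed = 1) {
  stopifnot(a >= b, b > 0)
  with_seed(seed, {
    for (sc in contact_script)
      if (sc$resid > n_prot_res || sc$resid < 1)
        stop("make_toy_scaffold_series: contact script references ",
             "unknown protein residue ", sc$resid)
    # protein residues spaced 12 A apart so scripted partners placed near
    # one residue never graze another
    prot <- data.frame(name = "CA", element = "C", resname = "LEU",
                       chain = "P", resid = seq_len(n_prot_res),
                       x = stats::runif(n_prot_res, -1, 1),
                       y = stats::runif(n_prot_res, -1, 1),
                       z = seq_len(n_prot_res) * 12,
                       occ = 1, b = 0, stringsAsFactors = FALSE)
    half <- n_points %/% 2
    t_par <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    belt <- data.frame(name = "CA", element = "C", resname = "ALA",
                       chain = rep(c("M", "N"),
                                   c(half, n_points - half)),
                       resid = c(seq_len(half),
                                 seq_len(n_points - half)),
                       x = 0, y = 0,
                       z = rep(c(-2, 2), length.out = n_points),
                       occ = 1, b = 0, stringsAsFactors = FALSE)
    scr <- if (length(contact_script)) {
      data.frame(name = "CB", element = "C",
                 resname = vapply(contact_script,
                                  function(s) s$partner_resname,
                                  character(1)),
                 chain = "S", resid = seq_along(contact_script),
                 x = 0, y = 0, z = 0, occ = 1, b = 0,
                 stringsAsFactors = FALSE)
    } else NULL
    top_df <- rbind(prot, belt, if (!is.null(scr)) scr)
    top <- structure_model(top_df)
    n_at <- nrow(top)
    belt_idx <- which(top$chain %in% c("M", "N"))
    Rori <- matrix(c(cos(orientation), sin(orientation),
                     -sin(orientation), cos(orientation)), 2, 2)
    frames <- array(0, c(n_frames, n_at, 3))
    for (f in seq_len(n_frames)) {
      t_ps <- (f - 1) * dt_ps
      af <- a + breathing_amp * sin(2 * pi * t_ps / breathing_period_ps)
      xy <- cbind(af * cos(t_par), b * sin(t_par)) %*% t(Rori)
      xyz <- coords(top)
      xyz[belt_idx, 1] <- xy[, 1]
      xyz[belt_idx, 2] <- xy[, 2]
      if (!is.null(scr)) {
        for (si in seq_along(contact_script)) {
          sc <- contact_script[[si]]
          at <- which(top$chain == "S" & top$resid == si)
          pr <- which(top$chain == "P" & top$resid == sc$resid)
          off <- if (f %in% sc$frames) contact_distance else 60
          xyz[at, ] <- xyz[pr, ] + c(off, 0, 0)
        }
      }
      frames[f, , ] <- xyz
    }
    fs <- frame_series(top, frames, dt_ps)
    attr(fs, "ground_truth") <- list(
      a = a, b = b, orientation = orientation, n_points = n_points,
      breathing_amp = breathing_amp,
      breathing_period_ps = breathing_period_ps,
      contact_script = contact_script, seed = seed)
    fs
  })
}

#' Synthetic cryo-EM style density map of a nanodisc
#'
#' A voxel map containing a solid disc (membrane mimic) of known radius
#' and height, optionally a denser central cylinder (protein mimic)
#' spanning the full grid height, over a flat background with optional
#' Gaussian noise. The grid is centred on the origin.
#'
#' @param shape grid dimensions (length 3)
#' @param voxel_size voxel edge, Angstrom (scalar or length 3)
#' @param disc_radius,disc_height disc geometry, Angstrom
#' @param disc_value density value inside the disc
#' @param protein_radius,protein_value central cylinder (radius 0 = none)
#' @param background background value
#' @param noise_sd Gaussian noise SD
#' @param seed RNG seed
#' @return a `density_map`; attribute `ground_truth` records parameters
#' @export
make_toy_density_map <- function(shape = c(64, 64, 48), voxel_size = 2,
                                 disc_radius = 45, disc_height = 30,
                                 disc_value = 1, protein_radius = 0,
                                 protein_value = 2, background = 0,
                                 noise_sd = 0, seed = 1) {
  voxel_size <- rep_len(voxel_size, 3)
  ext <- (shape - 1) * voxel_size
  if (2 * disc_radius >= min(ext[1:2]))
    stop("make_toy_density_map: disc does not fit in the grid")
  with_seed(seed, {
    origin <- -ext / 2
    xs <- origin[1] + (seq_len(shape[1]) - 1) * voxel_size[1]
    ys <- origin[2] + (seq_len(shape[2]) - 1) * voxel_size[2]
    zs <- origin[3] + (seq_len(shape[3]) - 1) * voxel_size[3]
    r2 <- outer(xs^2, ys^2, "+")
    g <- array(background, shape)
    in_disc_xy <- r2 <= disc_radius^2
    in_z <- abs(zs) <= disc_height / 2
    for (k in which(in_z)) g[, , k][in_disc_xy] <- disc_value
    if (protein_radius > 0) {
      in_prot <- r2 <= protein_radius^2
      for (k in seq_len(shape[3])) g[, , k][in_prot] <- protein_value
    }
    if (noise_sd > 0)
      g <- g + array(stats::rnorm(prod(shape), 0, noise_sd), shape)
    m <- density_map(g, voxel_size, origin)
    attr(m, "ground_truth") <- list(
      disc_radius = disc_radius, disc_height = disc_height,
      disc_value = disc_value, protein_radius = protein_radius,
      protein_value = protein_value, background = background,
      noise_sd = noise_sd, seed = seed)
    m
  })
}
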