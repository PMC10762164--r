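# Default atom names averaged for the "glycerol backbone" marker. Standard
# phospholipid nomenclature; configurable because force fields differ.
GLYCEROL_ATOMS <- c("C1", "C2", "C3", "O21", "O31")

# Per-lipid marker table for one topology: one row per lipid residue that
# carries a phosphorus atom (name "P"); glycerol centres are averaged over
# whichever of `glycerol_atoms` are present. Lipids lacking the required
# names are dropped and counted in the "skipped" attribute.
lipid_marker_table <- function(model, lipid_sel,
                               glycerol_atoms = GLYCEROL_ATOMS) {
  idx <- selection_indices(lipid_sel)
  if (!length(idx)) stop("lipid markers: empty selection")
  keys <- unique(residue_key(model, idx))
  all_keys <- residue_key(model)
  p_idx <- idx[model$name[idx] == "P"]
  p_map <- match(keys, residue_key(model, p_idx))
  skipped <- sum(is.na(p_map))
  keep <- which(!is.na(p_map))
  gly <- lapply(keep, function(k) {
    ai <- which(all_keys == keys[k] & model$name %in% glycerol_atoms)
    ai
  })
  list(keys = keys[keep],
       p_atom = p_idx[p_map[keep]],
       glycerol_atoms = gly,
       skipped = skipped)
}

#' Assign lipids to bilayer leaflets
#'
#' The instantaneous membrane midplane is the z-component of the geometric
#' centre of all phosphorus atoms in the frame; each lipid joins the upper
#' leaflet if its phosphorus z is at or above the midplane, else the lower
#' leaflet. The caller is expected to have aligned the frame so the
#' membrane normal is approximately z (e.g. via the pore axis).
#'
#' @param model topology `structure_model`
#' @param xyz frame coordinates (n_atoms x 3); defaults to the model's own
#' @param phosphorus_sel `atom_selection` of lipid phosphorus atoms
#' @return a `leaflet_assignment`: `midplane_z`, `upper`, `lower`
#'   (character vectors of lipid residue keys `"chain|resid"`)
#' @export
assign_leaflets <- function(model, xyz = NULL, phosphorus_sel) {
  idx <- selection_indices(phosphorus_sel)
  if (!length(idx)) stop("assign_leaflets: empty phosphorus selection")
  if (is.null(xyz)) xyz <- coords(model)
  zs <- xyz[idx, 3]
  mid <- mean(zs)
  keys <- residue_key(model, idx)
  structure(list(midplane_z = mid,
                 upper = keys[zs >= mid],
                 lower = keys[zs < mid]),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("<leaflet_assignment> midplane z = %.3f A; %d upper / %d lower\n",
              x$midplane_z, length(x$upper), length(x$lower)))
  invisible(x)
}

# min distance from each point in A (n x 3) to any point in B (m x 3)
min_cross_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Membrane thickness vs distance from the protein
#'
#' For every analysed frame: lipids are assigned to leaflets by the
#' instantaneous midplane; each lipid falls in a radial bin by the
#' smallest distance between its phosphorus atom and any protein backbone
#' atom of the transmembrane selection; per bin the thickness is the mean
#' marker height of upper lipids minus that of lower lipids. Marker height
#' uses either the phosphorus atom ("phosphorus", overall thickness) or
#' the geometric centre of the glycerol backbone ("glycerol_center",
#' hydrophobic thickness). The profile aggregates the per-frame bin
#' thicknesses as mean and SD across frames; bins never populated are NA
#' with `n_obs = 0`, never silent zeros.
#'
#' @param series a `frame_series`, already aligned on the transmembrane
#'   domain (no periodic imaging is applied; finite nanodisc systems)
#' @param tmd_backbone `atom_selection` of protein backbone atoms
#' @param lipid_sel `atom_selection` covering the lipid residues
#' @param marker `"phosphorus"` or `"glycerol_center"`
#' @param bin_width bin width, Angstrom (default 3, i.e. 0.3 nm)
#' @param r_max outer edge of the last bin, Angstrom
#' @param window_ns trailing analysis window, ns (NULL = all frames)
#' @param sample_every_ps sampling interval, ps (NULL = every frame)
#' @param glycerol_atoms atom names averaged for the glycerol centre
#' @param average_frames_first if TRUE, average leaflet heights across all
#'   frames before differencing (alternative aggregation order); default
#'   differences within each frame, then averages across frames
#' @return a `thickness_profile` data frame: bin_lo_A, bin_hi_A, mean_A,
#'   sd_A, n_obs, marker
#' @export
thickness_vs_distance <- function(series, tmd_backbone, lipid_sel,
                                  marker = c("phosphorus",
                                             "glycerol_center"),
                                  bin_width = 3, r_max = 45,
                                  window_ns = NULL,
                                  sample_every_ps = NULL,
                                  glycerol_atoms = GLYCEROL_ATOMS,
                                  average_frames_first = FALSE) {
  marker <- match.arg(marker)
  stopifnot(bin_width > 0, r_max > bin_width)
  top <- series$topology
  lm <- lipid_marker_table(top, lipid_sel, glycerol_atoms)
  bb <- selection_indices(tmd_backbone)
  if (!length(bb)) stop("thickness_vs_distance: empty backbone selection")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  fr <- window_frames(series, window_ns, sample_every_ps)
  per_frame <- matrix(NA_real_, length(fr), nb)
  up_sum <- lo_sum <- matrix(0, length(edges) - 1, 2)  # [sum, n] accumulators
  counts <- matrix(0L, length(fr), nb)
  for (fi in seq_along(fr)) {
    xyz <- frame_coords(series, fr[fi])
    pz <- xyz[lm$p_atom, 3]
    mid <- mean(pz)
    upper <- pz >= mid
    d <- min_cross_distance(xyz[lm$p_atom, , drop = FALSE],
                            xyz[bb, , drop = FALSE])
    bin <- findInterval(d, edges, rightmost.closed = TRUE,
                        left.open = FALSE)
    bin[bin < 1 | bin > nb] <- NA
    h <- if (marker == "phosphorus") pz else
      vapply(lm$glycerol_atoms, function(ai) mean(xyz[ai, 3]), numeric(1))
    for (b in unique(bin[!is.na(bin)])) {
      in_b <- which(bin == b)
      hu <- h[in_b[upper[in_b]]]; hl <- h[in_b[!upper[in_b]]]
      counts[fi, b] <- length(in_b)
      if (length(hu) && length(hl)) {
        per_frame[fi, b] <- mean(hu) - mean(hl)
        up_sum[b, ] <- up_sum[b, ] + c(sum(hu), length(hu))
        lo_sum[b, ] <- lo_sum[b, ] + c(sum(hl), length(hl))
      }
    }
  }
  if (average_frames_first) {
    mean_t <- ifelse(up_sum[, 2] > 0 & lo_sum[, 2] > 0,
                     up_sum[, 1] / pmax(up_sum[, 2], 1) -
                       lo_sum[, 1] / pmax(lo_sum[, 2], 1), NA_real_)
    sd_t <- rep(NA_real_, nb)
  } else {
    mean_t <- ifelse(colSums(!is.na(per_frame)) > 0,
                     colMeans(per_frame, na.rm = TRUE), NA_real_)
    sd_t <- apply(per_frame, 2, function(v)
      if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
    sd_t[colSums(!is.na(per_frame)) == 0] <- NA_real_
  }
  out <- data.frame(bin_lo_A = edges[-length(edges)],
                    bin_hi_A = edges[-1],
                    mean_A = mean_t, sd_A = sd_t,
                    n_obs = colSums(counts),
                    marker = marker, stringsAsFactors = FALSE)
  attr(out, "skipped_lipids") <- lm$skipped
  attr(out, "frames_used") <- length(fr)
  class(out) <- c("thickness_profile", "data.frame")
  out
}

#' Two-dimensional polar membrane thickness map
#'
#' Identical thickness logic to [thickness_vs_distance()], but lipids are
#' binned by polar coordinates (r, theta) of their phosphorus atom about
#' the pore axis: radial bins of `r_bin` Angstrom and angular sectors of
#' `theta_bin` radians (defaults 5 Angstrom and pi/15, i.e. 30 sectors).
#' Theta is measured from the +x direction of the plane frame
#' perpendicular to the axis; bins are half-open `[a, b)`.
#'
#' @inheritParams thickness_vs_distance
#' @param axis a `pore_axis`
#' @param r_bin radial bin width, Angstrom
#' @param theta_bin angular bin width, radians (must divide 2*pi)
#' @return a `polar_thickness_map` data frame: r_lo_A, r_hi_A, theta_lo,
#'   theta_hi, mean_A, sd_A, n_obs, marker
#' @export
polar_thickness_map <- function(series, axis, lipid_sel,
                                marker = c("phosphorus",
                                           "glycerol_center"),
                                r_bin = 5, theta_bin = pi / 15,
                                r_max = 45,
                                window_ns = NULL, sample_every_ps = NULL,
                                glycerol_atoms = GLYCEROL_ATOMS) {
  marker <- match.arg(marker)
  n_theta <- round(2 * pi / theta_bin)
  if (abs(n_theta * theta_bin - 2 * pi) > 1e-9)
    stop("polar_thickness_map: theta_bin must divide 2*pi")
  top <- series$topology
  lm <- lipid_marker_table(top, lipid_sel, glycerol_atoms)
  r_edges <- seq(0, r_max, by = r_bin)
  if (r_edges[length(r_edges)] < r_max) r_edges <- c(r_edges, r_max)
  nr <- length(r_edges) - 1
  th_edges <- seq(0, 2 * pi, length.out = n_theta + 1)
  basis <- plane_basis(axis$direction)
  fr <- window_frames(series, window_ns, sample_every_ps)
  ncell <- nr * n_theta
  per_frame <- matrix(NA_real_, length(fr), ncell)
  counts <- matrix(0L, length(fr), ncell)
  for (fi in seq_along(fr)) {
    xyz <- frame_coords(series, fr[fi])
    pp <- xyz[lm$p_atom, , drop = FALSE]
    pz <- pp[, 3]
    mid <- mean(pz)
    upper <- pz >= mid
    rel <- sweep(pp, 2, axis$origin)
    px <- drop(rel %*% basis$u); py <- drop(rel %*% basis$v)
    r <- sqrt(px^2 + py^2)
    th <- atan2(py, px) %% (2 * pi)
    rb <- findInterval(r, r_edges, rightmost.closed = TRUE)
    tb <- pmin(findInterval(th, th_edges), n_theta)   # [a, b) sectors
    ok <- rb >= 1 & rb <= nr
    cell <- (rb - 1) * n_theta + tb
    h <- if (marker == "phosphorus") pz else
      vapply(lm$glycerol_atoms, function(ai) mean(xyz[ai, 3]), numeric(1))
    for (cl in unique(cell[ok])) {
      in_c <- which(ok & cell == cl)
      hu <- h[in_c[upper[in_c]]]; hl <- h[in_c[!upper[in_c]]]
      counts[fi, cl] <- length(in_c)
      if (length(hu) && length(hl))
        per_frame[fi, cl] <- mean(hu) - mean(hl)
    }
  }
  mean_t <- ifelse(colSums(!is.na(per_frame)) > 0,
                   colMeans(per_frame, na.rm = TRUE), NA_real_)
  sd_t <- apply(per_frame, 2, function(v)
    if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  sd_t[colSums(!is.na(per_frame)) == 0] <- NA_real_
  grid <- expand.grid(theta_i = seq_len(n_theta), r_i = seq_len(nr))
  out <- data.frame(r_lo_A = r_edges[grid$r_i],
                    r_hi_A = r_edges[grid$r_i + 1],
                    theta_lo = th_edges[grid$theta_i],
                    theta_hi = th_edges[grid$theta_i + 1],
                    mean_A = mean_t[(grid$r_i - 1) * n_theta + grid$theta_i],
                    sd_A = sd_t[(grid$r_i - 1) * n_theta + grid$theta_i],
                    n_obs = colSums(counts)[(grid$r_i - 1) * n_theta +
                                              grid$theta_i],
                    marker = marker, stringsAsFactors = FALSE)
  attr(out, "skipped_lipids") <- lm$skipped
  attr(out, "frames_used") <- length(fr)
  class(out) <- c("polar_thickness_map", "data.frame")
  out
}
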