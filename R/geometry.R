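# van der Waals radii (Angstrom) by element, Bondi-style values
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  ifelse(is.na(r), VDW_DEFAULT, r)
}

unit <- function(v) v / sqrt(sum(v * v))

# rotation matrix about unit axis u by angle (radians), right-hand rule
rotation_about <- function(u, angle) {
  u <- unit(u)
  c_ <- cos(angle); s <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# orthonormal basis (u, v) perpendicular to unit vector d; u is the
# projection of +x (the canonical in-plane zero direction for polar
# angles), falling back to +y when d is parallel to x
plane_basis <- function(d) {
  d <- unit(d)
  ref <- if (abs(d[1]) < 0.99) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * d) * d)
  v <- pracma_cross(d, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pore axis of a C5-symmetric channel
#'
#' Determines the channel's symmetry axis intrinsically from the
#' pore-lining C-alpha cloud: candidate axes are the three principal
#' directions of the cloud; the chosen axis is the one that maximises
#' five-fold rotational self-agreement (smallest mean nearest-neighbour
#' distance between the cloud and its copy rotated by 72 degrees about the
#' candidate). The origin is the selection centroid. The direction is
#' canonically oriented so that `direction . orient_ref >= 0` (by
#' convention pointing from the transmembrane toward the extracellular
#' domain, i.e. toward the viewer in extracellular top views).
#'
#' @param model a `structure_model`
#' @param pore_lining an `atom_selection` with >= 3 atoms spread over at
#'   least 3 of the 5 chains
#' @param orient_ref reference vector fixing the sign of the direction
#' @return a `pore_axis`: list with `origin`, `direction`, `orient_ref`
#' @export
compute_pore_axis <- function(model, pore_lining,
                              orient_ref = c(0, 0, 1)) {
  idx <- selection_indices(pore_lining)
  if (length(idx) < 3)
    stop("compute_pore_axis: need >= 3 pore-lining atoms")
  chains <- unique(model$chain[idx])
  if (length(chains) < 3)
    stop("compute_pore_axis: symmetry error: pore lining covers only ",
         length(chains), " chain(s); need >= 3 of 5")
  pts <- coords(model, idx)
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  if (ev$values[2] < 1e-12)
    stop("compute_pore_axis: geometry error: collinear point cloud")
  score <- function(axis) {
    R <- rotation_about(axis, 2 * pi / 5)
    rot <- pc %*% t(R)
    # mean nearest-neighbour distance, rotated cloud vs original
    d2 <- outer(rowSums(rot^2), rowSums(pc^2), "+") - 2 * rot %*% t(pc)
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  scores <- apply(ev$vectors, 2, score)
  dir <- ev$vectors[, which.min(scores)]
  if (sum(dir * orient_ref) < 0) dir <- -dir
  structure(list(origin = ctr, direction = unit(dir),
                 orient_ref = unit(orient_ref)),
            class = "pore_axis")
}

#' @export
print.pore_axis <- function(x, ...) {
  cat(sprintf("<pore_axis> origin (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Construct a pore axis directly
#' @param origin point on the axis (Angstrom)
#' @param direction axis direction (normalised internally)
#' @param orient_ref reference fixing the canonical sign
#' @export
pore_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1),
                      orient_ref = direction) {
  d <- unit(as.numeric(direction))
  if (sum(d * orient_ref) < 0) d <- -d
  structure(list(origin = as.numeric(origin), direction = d,
                 orient_ref = unit(as.numeric(orient_ref))),
            class = "pore_axis")
}

# perpendicular distance of points (n x 3) to an axis
axis_distance <- function(pts, axis) {
  rel <- sweep(pts, 2, axis$origin)
  a <- drop(rel %*% axis$direction)
  sqrt(pmax(rowSums(rel^2) - a^2, 0))
}

# coordinate along the axis
axis_coordinate <- function(pts, axis) {
  drop(sweep(pts, 2, axis$origin) %*% axis$direction)
}

#' Per-residue C-alpha distance to the pore axis
#'
#' The perpendicular distance of each selected C-alpha to the pore axis,
#' grouped by residue number across the five subunits with per-residue
#' mean and SD (the quantity plotted for the pore-lining M2 helix).
#' Residues without a C-alpha in the model are reported as missing, not
#' errors, since lipid-facing helices can be unresolved.
#'
#' @param model a `structure_model`
#' @param axis a `pore_axis`
#' @param residues an `atom_selection`; non-CA atoms are ignored
#' @return a `distance_profile` data frame: per-atom rows
#'   (chain, resid, value) plus a `summary` attribute with per-residue
#'   mean/sd/n
#' @export
residue_axis_distance <- function(model, axis, residues) {
  idx <- selection_indices(residues)
  idx <- idx[model$name[idx] == "CA"]
  if (!length(idx))
    stop("residue_axis_distance: selection contains no CA atoms")
  d <- axis_distance(coords(model, idx), axis)
  per <- data.frame(chain = model$chain[idx], resid = model$resid[idx],
                    value = d, stringsAsFactors = FALSE)
  agg <- stats::aggregate(value ~ resid, per,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  summ <- data.frame(resid = agg$resid,
                     mean = agg$value[, "mean"],
                     sd = agg$value[, "sd"],
                     n = as.integer(agg$value[, "n"]))
  structure(per, summary = summ, class = c("distance_profile",
                                           "data.frame"))
}

# Reduce a helix C-alpha trace toward its axis by moving-average
# smoothing over approximately one helical turn (two passes of a 4-point
# window). The raw C-alpha coil is not orthogonal to the axial trend of a
# finite helix, which biases a principal-direction fit by over a degree;
# turn-smoothing suppresses the coil (amplitude factor ~0.017 after two
# passes) so the dominant principal direction tracks the true axis to
# well under 0.1 degree. Short traces fall back gracefully.
helix_axis_trace <- function(pts) {
  smooth4 <- function(m) {
    n <- nrow(m)
    (m[1:(n - 3), , drop = FALSE] + m[2:(n - 2), , drop = FALSE] +
       m[3:(n - 1), , drop = FALSE] + m[4:n, , drop = FALSE]) / 4
  }
  if (nrow(pts) >= 12) smooth4(smooth4(pts))
  else if (nrow(pts) >= 8) smooth4(pts)
  else pts
}

#' Helix tilt angle relative to the pore axis
#'
#' The helix axis of each subunit copy is the dominant principal direction
#' of its turn-smoothed C-alpha trace (the smoothing removes the helical
#' coil, which otherwise biases the fit), oriented N-to-C; the tilt is
#' `acos(|h . d|)` in degrees, in [0, 90]. Requires >= 5 C-alphas per
#' subunit and an anisotropic cloud (first-to-second principal spread
#' ratio >= 1.5).
#'
#' @param model a `structure_model`
#' @param helix_ca `atom_selection` of the helix C-alphas (all subunits)
#' @param axis a `pore_axis`
#' @return a `helix_tilt` list: `per_subunit` (chain, tilt_deg),
#'   `mean_deg`, `sd_deg`
#' @export
helix_tilt_angle <- function(model, helix_ca, axis) {
  idx <- selection_indices(helix_ca)
  idx <- idx[model$name[idx] == "CA"]
  chains <- sort(unique(model$chain[idx]))
  tilts <- vapply(chains, function(ch) {
    ci <- idx[model$chain[idx] == ch]
    if (length(ci) < 5)
      stop("helix_tilt_angle: insufficient points: chain ", ch,
           " has ", length(ci), " CA (need >= 5)")
    ci <- ci[order(model$resid[ci])]
    pts <- helix_axis_trace(coords(model, ci))
    pc <- sweep(pts, 2, colMeans(pts))
    ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
    if (ev$values[1] < 1.5^2 * ev$values[2])
      stop("helix_tilt_angle: geometry error: chain ", ch,
           " CA cloud has no dominant direction")
    h <- ev$vectors[, 1]
    nc <- pts[nrow(pts), ] - pts[1, ]          # orient N -> C
    if (sum(h * nc) < 0) h <- -h
    acos(pmin(abs(sum(h * axis$direction)), 1)) * 180 / pi
  }, numeric(1))
  structure(list(per_subunit = data.frame(chain = chains, tilt_deg = tilts,
                                          stringsAsFactors = FALSE),
                 mean_deg = mean(tilts),
                 sd_deg = stats::sd(tilts)),
            class = "helix_tilt")
}

#' @export
print.helix_tilt <- function(x, ...) {
  cat(sprintf("<helix_tilt> mean %.2f deg (SD %.2f) over %d subunits\n",
              x$mean_deg, ifelse(is.na(x$sd_deg), 0, x$sd_deg),
              nrow(x$per_subunit)))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atoms of two models. Atoms are paired by (chain, resid, name)
#' within the fit selections; a 1:1 correspondence is required.
#'
#' @param mobile,reference `structure_model`s
#' @param mobile_sel,reference_sel `atom_selection`s defining the fit
#'   atoms (reference_sel defaults to the same expression re-resolved)
#' @return a `rigid_transform`: `rotation` (3x3, det +1), `translation`
#'   (length 3), `rmsd` (Angstrom). Apply with [apply_transform()]:
#'   `x' = R x + t`.
#' @export
superpose <- function(mobile, reference, mobile_sel,
                      reference_sel = NULL) {
  if (is.null(reference_sel)) {
    if (!inherits(mobile_sel, "atom_selection"))
      stop("superpose: pass atom_selection objects")
    reference_sel <- select_atoms(reference, mobile_sel$expression)
  }
  mi <- selection_indices(mobile_sel)
  ri <- selection_indices(reference_sel)
  mkey <- paste(mobile$chain[mi], mobile$resid[mi], mobile$name[mi])
  rkey <- paste(reference$chain[ri], reference$resid[ri],
                reference$name[ri])
  common <- intersect(mkey, rkey)
  unmatched <- c(setdiff(mkey, rkey), setdiff(rkey, mkey))
  if (length(unmatched))
    stop("superpose: pairing error: ", length(unmatched),
         " unmatched atoms, e.g. ",
         paste(utils::head(unmatched, 3), collapse = "; "))
  P <- coords(mobile, mi[match(common, mkey)])
  Q <- coords(reference, ri[match(common, rkey)])
  kabsch(P, Q)
}

# Kabsch: rotation/translation mapping P onto Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cq - drop(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t_, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = t_, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A, rmsd %.4f A\n",
              ang, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform
#' @param x a `structure_model`, `frame_series`, or n x 3 matrix
#' @param transform a `rigid_transform`
#' @return object of the same kind with transformed coordinates
#' @export
apply_transform <- function(x, transform) {
  tf <- function(m) sweep(m %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (inherits(x, "structure_model")) return(set_coords(x, tf(coords(x))))
  if (inherits(x, "frame_series")) {
    for (i in seq_len(n_frames(x)))
      x$frames[i, , ] <- tf(frame_coords(x, i))
    return(x)
  }
  tf(as.matrix(x))
}

# quaternion (w, x, y, z) from a proper rotation matrix (Shepperd)
rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

# signed twist (radians) of rotation R about unit axis d
# (swing-twist decomposition; right-hand rule about d)
rotation_twist_about <- function(R, d) {
  q <- rotation_to_quaternion(R)
  proj <- sum(q[2:4] * d)
  2 * atan2(proj, q[1])
}

#' Rotation of the extracellular domain relative to the transmembrane domain
#'
#' Superposes the second structure onto the first using transmembrane
#' C-alphas, fits the residual best rotation of the extracellular
#' C-alphas, and reports its component about the pore axis as a signed
#' angle: positive is counter-clockwise viewed from the extracellular
#' side (looking down the canonical axis). This axial twist is the
#' reproducible scalar for domain rotation; the total residual rotation
#' angle is also returned.
#'
#' @param apo,bound `structure_model`s sharing residue numbering
#' @param tmd_sel,ecd_sel selection expressions (strings) resolved on
#'   both structures; C-alphas only are used
#' @param axis a `pore_axis` (of `apo`)
#' @return an `ecd_rotation` list: `twist_deg` (signed axial component),
#'   `total_deg`, `tmd_rmsd`
#' @export
ecd_rotation_angle <- function(apo, bound,
                               tmd_sel = "calpha and resid 201:322",
                               ecd_sel = "calpha and resid -999:200",
                               axis = NULL) {
  tmd_a <- select_atoms(apo, tmd_sel)
  tmd_b <- select_atoms(bound, tmd_sel)
  tf <- superpose(bound, apo, tmd_b, tmd_a)
  bound_fit <- apply_transform(bound, tf)
  if (is.null(axis)) axis <- compute_pore_axis(apo, tmd_a)
  ecd_a <- select_atoms(apo, ecd_sel)
  ecd_b <- select_atoms(bound_fit, ecd_sel)
  ia <- selection_indices(ecd_a); ib <- selection_indices(ecd_b)
  akey <- paste(apo$chain[ia], apo$resid[ia], apo$name[ia])
  bkey <- paste(bound_fit$chain[ib], bound_fit$resid[ib],
                bound_fit$name[ib])
  common <- intersect(akey, bkey)
  if (length(common) < 3)
    stop("ecd_rotation_angle: fewer than 3 paired ECD atoms")
  P <- coords(apo, ia[match(common, akey)])
  Q <- coords(bound_fit, ib[match(common, bkey)])
  res <- kabsch(P, Q)              # rotation carrying apo ECD -> bound ECD
  twist <- rotation_twist_about(res$rotation, axis$direction) * 180 / pi
  total <- acos(pmin(pmax((sum(diag(res$rotation)) - 1) / 2, -1), 1)) *
    180 / pi
  structure(list(twist_deg = twist, total_deg = total,
                 tmd_rmsd = tf$rmsd),
            class = "ecd_rotation")
}

#' @export
print.ecd_rotation <- function(x, ...) {
  cat(sprintf(
    "<ecd_rotation> axial twist %+.3f deg (total %.3f deg), TMD rmsd %.3f A\n",
    x$twist_deg, x$total_deg, x$tmd_rmsd))
  invisible(x)
}

#' Distance between two named atoms
#'
#' Euclidean distance between `(chain, resid, name)` atoms, e.g. across
#' the binding-site loops. With `around_ring = TRUE` the same residue pair
#' is measured in all five subunit interfaces by substituting each chain
#' identifier in ring order, reporting all values and their mean.
#'
#' @param model a `structure_model`
#' @param atom_a,atom_b lists/vectors `(chain, resid, name)`
#' @param around_ring measure the equivalent pair in every chain
#' @return for `around_ring = FALSE` a single distance (Angstrom); else a
#'   data frame of per-pair distances with a `mean` attribute
#' @export
pairwise_residue_distance <- function(model, atom_a, atom_b,
                                      around_ring = FALSE) {
  find_atom <- function(spec) {
    i <- which(model$chain == as.character(spec[[1]]) &
               model$resid == as.integer(spec[[2]]) &
               model$name == as.character(spec[[3]]))
    if (length(i) != 1L)
      stop("pairwise_residue_distance: atom not found: ",
           paste(unlist(spec), collapse = " "))
    i
  }
  one <- function(a, b) {
    pa <- coords(model, find_atom(a)); pb <- coords(model, find_atom(b))
    sqrt(sum((pa - pb)^2))
  }
  if (!around_ring) return(one(atom_a, atom_b))
  chains <- sort(unique(model$chain))
  offset <- match(as.character(atom_b[[1]]), chains) -
    match(as.character(atom_a[[1]]), chains)
  vals <- vapply(seq_along(chains), function(k) {
    ca <- chains[k]
    cb <- chains[(k - 1 + offset) %% length(chains) + 1]
    one(list(ca, atom_a[[2]], atom_a[[3]]),
        list(cb, atom_b[[2]], atom_b[[3]]))
  }, numeric(1))
  structure(data.frame(chain = chains, distance = vals,
                       stringsAsFactors = FALSE),
            mean = mean(vals), sd = stats::sd(vals))
}

#' Pore radius profile along the channel axis
#'
#' At each axial sample z, the accessible pore radius is the minimum over
#' atoms in the axial slab `[z - step/2, z + step/2)` of (distance of the
#' atom centre to the axis minus the van der Waals radius of its element),
#' clamped at zero. The residue of the minimising atom is reported as the
#' pore-lining residue. Samples whose slab is empty are flagged
#' undefined (NA radius), not errors.
#'
#' @param model a `structure_model`
#' @param axis a `pore_axis`
#' @param z_range axial range (length 2, Angstrom); default spans the
#'   model's axial extent
#' @param step sample spacing (Angstrom, > 0)
#' @param vdw named per-element radius table (Angstrom)
#' @return a `pore_profile` data frame: z, radius_A, lining_chain,
#'   lining_resid, lining_resname
#' @export
pore_radius_profile <- function(model, axis, z_range = NULL, step = 1,
                                vdw = VDW_RADII) {
  stopifnot(step > 0)
  pts <- coords(model)
  a <- axis_coordinate(pts, axis)
  if (is.null(z_range)) z_range <- range(a)
  z <- seq(z_range[1], z_range[2], by = step)
  r_axis <- axis_distance(pts, axis)
  rv <- vdw[toupper(model$element)]
  rv[is.na(rv)] <- VDW_DEFAULT
  eff <- r_axis - rv
  out <- data.frame(z = z, radius_A = NA_real_,
                    lining_chain = NA_character_,
                    lining_resid = NA_integer_,
                    lining_resname = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(z)) {
    slab <- which(a >= z[i] - step / 2 & a < z[i] + step / 2)
    if (!length(slab)) next
    j <- slab[which.min(eff[slab])]
    out$radius_A[i] <- max(eff[j], 0)
    out$lining_chain[i] <- model$chain[j]
    out$lining_resid[i] <- model$resid[j]
    out$lining_resname[i] <- model$resname[j]
  }
  class(out) <- c("pore_profile", "data.frame")
  out
}
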