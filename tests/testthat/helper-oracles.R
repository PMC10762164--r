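# Independent oracles: deliberately naive implementations used to check
# the package's optimised paths. They never call the code under test.

# point-to-axis distance by dense sampling of points on the axis line
brute_axis_distance <- function(p, origin, direction, span = 200,
                                step = 0.001) {
  s <- seq(-span, span, by = step * 100)
  direction <- direction / sqrt(sum(direction^2))
  # coarse pass then refine around the minimum
  d2 <- vapply(s, function(si)
    sum((p - (origin + si * direction))^2), numeric(1))
  s0 <- s[which.min(d2)]
  s <- seq(s0 - 1, s0 + 1, by = step)
  d2 <- vapply(s, function(si)
    sum((p - (origin + si * direction))^2), numeric(1))
  sqrt(min(d2))
}

# naive O(N^2) per-residue contact probabilities over all frames
naive_contact_probability <- function(series, protein_idx, scaffold_idx,
                                      cutoff) {
  top <- series$topology
  pres <- paste(top$chain[protein_idx], top$resid[protein_idx])
  levels <- unique(pres)
  hits <- integer(length(levels))
  nf <- n_frames(series)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(series, f)
    A <- xyz[protein_idx, , drop = FALSE]
    B <- xyz[scaffold_idx, , drop = FALSE]
    in_contact <- logical(length(levels))
    for (i in seq_len(nrow(A))) {
      dx <- B[, 1] - A[i, 1]; dy <- B[, 2] - A[i, 2]; dz <- B[, 3] - A[i, 3]
      if (any(dx * dx + dy * dy + dz * dz <= cutoff^2))
        in_contact[match(pres[i], levels)] <- TRUE
    }
    hits <- hits + in_contact
  }
  data.frame(residue = levels, probability = hits / nf)
}

# brute-force pore radius at one axial sample via a dense polar grid
brute_pore_radius <- function(model, axis, z, step, vdw_lookup) {
  pts <- discmetrics::coords(model)
  rel <- sweep(pts, 2, axis$origin)
  a <- drop(rel %*% axis$direction)
  slab <- which(a >= z - step / 2 & a < z + step / 2)
  if (!length(slab)) return(NA_real_)
  rad <- vapply(slab, function(j) {
    r_axis <- sqrt(sum(rel[j, ]^2) - a[j]^2)
    r_axis - vdw_lookup(model$element[j])
  }, numeric(1))
  max(min(rad), 0)
}

# ideal pentamer ring helper reused across geometry tests
toy_ring_model <- function(radius = 6, n = 10, z = 0, element = "C",
                           name = "C1", resname = "RNG") {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure_model(data.frame(
    name = paste0(name, seq_len(n)), element = element, resname = resname,
    chain = "A", resid = seq_len(n),
    x = radius * cos(ang), y = radius * sin(ang), z = z,
    occ = 1, b = 0, stringsAsFactors = FALSE))
}

rotate_model <- function(model, axis_vec, angle_deg, translation = c(0, 0, 0)) {
  u <- axis_vec / sqrt(sum(axis_vec^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz <- sweep(coords(model) %*% t(R), 2, translation, "+")
  set_coords(model, xyz)
}
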