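#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points by the constrained algebraic least-squares
#' formulation (conic `ax^2 + bxy + cy^2 + dx + ey + f = 0` with the
#' ellipse-specific normalisation `4ac - b^2 = 1`), solved by the
#' numerically stable partitioned eigen-decomposition. The constraint
#' guarantees an ellipse (never a hyperbola) and makes the fit
#' deterministic and exact on noiseless inputs.
#'
#' @param points n x 2 matrix of coordinates (Angstrom); n >= 5,
#'   non-collinear
#' @return an `ellipse_fit`: `center` (length 2), `a` (semi-major), `b`
#'   (semi-minor, `a >= b`), `orientation` (major-axis angle, radians in
#'   `[0, pi)`), `rms_residual` (RMS Sampson distance, Angstrom)
#' @examples
#' t <- seq(0, 2 * pi, length.out = 31)[-31]
#' fit_ellipse(cbind(55 * cos(t), 45 * sin(t)))
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 5)
    stop("fit_ellipse: need >= 5 points, got ", nrow(points))
  x <- points[, 1]; y <- points[, 2]
  # centre/scale for conditioning; parameters are unscaled afterwards
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s < 1e-12)
    stop("fit_ellipse: degenerate (coincident) points")
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12)
    stop("fit_ellipse: degeneracy error: points are collinear")
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  # premultiply by inv(C) for constraint 4ac - b^2 = 1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond > 0)
  if (!length(k))
    stop("fit_ellipse: degeneracy error: no elliptical solution")
  a1 <- evec[, k[1]]
  par_s <- c(a1, drop(T_ %*% a1))     # conic in scaled frame
  conic <- unscale_conic(par_s, mx, my, s)
  geo <- conic_to_ellipse(conic)
  # RMS Sampson (gradient-normalised algebraic) distance
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5] ; F_ <- conic[6]
  alg <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F_
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  samp <- alg / sqrt(gx^2 + gy^2)
  structure(c(geo, list(rms_residual = sqrt(mean(samp^2)),
                        conic = conic, n = nrow(points))),
            class = "ellipse_fit")
}

# map conic coefficients fitted in scaled coords back to original frame
unscale_conic <- function(p, mx, my, s) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F_ <- p[6]
  A2 <- A / s^2
  B2 <- B / s^2
  C2 <- C / s^2
  D2 <- D / s - 2 * A * mx / s^2 - B * my / s^2
  E2 <- E / s - 2 * C * my / s^2 - B * mx / s^2
  F2 <- F_ + A * mx^2 / s^2 + B * mx * my / s^2 + C * my^2 / s^2 -
    D * mx / s - E * my / s
  c(A2, B2, C2, D2, E2, F2)
}

# geometric parameters of an ellipse from conic coefficients
conic_to_ellipse <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F_ <- p[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("fit_ellipse: conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # conic constant after translating to the centre
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F_
  lam <- eigen(matrix(c(A, B / 2, B / 2, C), 2, 2), symmetric = TRUE)
  # axis^2 = -Fc / lambda_i
  ax2 <- -Fc / lam$values
  if (any(ax2 <= 0)) stop("fit_ellipse: degenerate ellipse")
  lens <- sqrt(ax2)
  major <- which.max(lens)
  vmaj <- lam$vectors[, major]
  theta <- atan2(vmaj[2], vmaj[1]) %% pi
  list(center = unname(c(cx, cy)), a = max(lens), b = min(lens),
       orientation = unname(theta))
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.2f, %.2f), a = %.3f, b = %.3f A, theta = %.2f deg, rms %.4g A (n = %d)\n",
    x$center[1], x$center[2], x$a, x$b, x$orientation * 180 / pi,
    x$rms_residual, x$n))
  invisible(x)
}

#' Nanodisc diameter time series from the scaffold belt
#'
#' Per analysed frame, the scaffold backbone atoms are projected onto the
#' plane perpendicular to the pore axis (anchored at the frame's membrane
#' midplane when lipids are available; the projection is
#' translation-invariant, so the anchor only sets the plane origin), an
#' ellipse of best fit is recorded, and the major/minor diameters 2a, 2b
#' are reported with mean and SD over the trailing window.
#'
#' @param series a `frame_series`
#' @param msp_backbone `atom_selection` of scaffold backbone atoms
#' @param axis a `pore_axis` (default: +z)
#' @param window_ns trailing window for the summary statistics, ns
#' @param sample_every_ps sampling interval, ps (NULL = every frame)
#' @return a `diameter_series` data frame: t_ps, major_A, minor_A, with
#'   attributes `mean_major_A`, `sd_major_A`, `mean_minor_A`,
#'   `sd_minor_A` over the window
#' @export
nanodisc_diameter_series <- function(series, msp_backbone, axis = NULL,
                                     window_ns = NULL,
                                     sample_every_ps = NULL) {
  idx <- selection_indices(msp_backbone)
  if (!length(idx)) stop("nanodisc_diameter_series: empty selection")
  if (is.null(axis)) axis <- pore_axis()
  basis <- plane_basis(axis$direction)
  fr <- window_frames(series, NULL, sample_every_ps)
  major <- minor <- numeric(length(fr))
  for (fi in seq_along(fr)) {
    xyz <- frame_coords(series, fr[fi])[idx, , drop = FALSE]
    rel <- sweep(xyz, 2, axis$origin)
    pts <- cbind(drop(rel %*% basis$u), drop(rel %*% basis$v))
    fit <- fit_ellipse(pts)
    major[fi] <- 2 * fit$a
    minor[fi] <- 2 * fit$b
  }
  t_ps <- (fr - 1) * series$dt_ps
  in_win <- if (is.null(window_ns)) rep(TRUE, length(fr)) else
    t_ps > max(t_ps) - window_ns * 1000 + series$dt_ps * 1e-6
  if (!any(in_win)) stop("nanodisc_diameter_series: empty window")
  out <- data.frame(t_ps = t_ps, major_A = major, minor_A = minor)
  attr(out, "mean_major_A") <- mean(major[in_win])
  attr(out, "sd_major_A") <- stats::sd(major[in_win])
  attr(out, "mean_minor_A") <- mean(minor[in_win])
  attr(out, "sd_minor_A") <- stats::sd(minor[in_win])
  attr(out, "n_window") <- sum(in_win)
  class(out) <- c("diameter_series", "data.frame")
  out
}

#' @export
print.diameter_series <- function(x, ...) {
  cat(sprintf(
    "<diameter_series> %d frames; window mean 2a = %.2f A (SD %.2f), 2b = %.2f A (SD %.2f)\n",
    nrow(x), attr(x, "mean_major_A"),
    ifelse(is.na(attr(x, "sd_major_A")), 0, attr(x, "sd_major_A")),
    attr(x, "mean_minor_A"),
    ifelse(is.na(attr(x, "sd_minor_A")), 0, attr(x, "sd_minor_A"))))
  invisible(x)
}
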