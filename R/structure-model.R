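#' Atomic structure model
#'
#' A `structure_model` is the package's in-memory representation of one
#' atomic model: a data frame with one row per atom and columns
#' `serial`, `name`, `element`, `resname`, `chain`, `resid`, `x`, `y`, `z`,
#' `occ`, `b`. Coordinates are in Angstrom and residue numbers follow the
#' author numbering of the source file, because residues are referred to by
#' author numbers throughout (e.g. the 9' pore-lining leucine L240, the TMD
#' span 201-322).
#'
#' @param atoms data frame with the columns listed above. `serial` may be
#'   missing and is then filled with `1:nrow`.
#' @return an object of class `structure_model` (also a `data.frame`).
#' @examples
#' m <- structure_model(data.frame(
#'   name = "CA", element = "C", resname = "ALA", chain = "A",
#'   resid = 1L, x = 1, y = 2, z = 3, occ = 1, b = 0
#' ))
#' coords(m)
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "element", "resname", "chain", "resid",
                "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("structure_model: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("structure_model: zero atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("structure_model: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("structure_model: duplicate (chain, resid, name) triples: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  atoms <- atoms[, c("serial", "name", "element", "resname", "chain",
                     "resid", "x", "y", "z", "occ", "b")]
  atoms$resid <- as.integer(atoms$resid)
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Coordinates of a structure model
#'
#' @param model a `structure_model`
#' @param selection optional `atom_selection` or integer indices
#' @return n x 3 numeric matrix of coordinates (Angstrom)
#' @export
coords <- function(model, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(model)) else
    selection_indices(selection)
  out <- as.matrix(as.data.frame(model)[idx, c("x", "y", "z")])
  dimnames(out) <- NULL
  out
}

#' Replace coordinates of a structure model
#' @param model a `structure_model`
#' @param xyz n x 3 matrix matching the atom count
#' @return the model with new coordinates
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(model), ncol(xyz) == 3)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chains, %d residues\n",
              nrow(x), length(unique(x$chain)),
              length(unique(paste(x$chain, x$resid)))))
  invisible(x)
}

# residue keys "chain|resid" per atom
residue_key <- function(model, idx = seq_len(nrow(model))) {
  paste(model$chain[idx], model$resid[idx], sep = "|")
}

#' Trajectory frame series
#'
#' Time-ordered coordinate frames sharing one atom topology. Frame `i`
#' (1-based) corresponds to time `(i - 1) * dt_ps` picoseconds; the frame
#' interval is a required user input and is never inferred from file
#' metadata, since trajectories are commonly subsampled before analysis.
#'
#' @param topology a `structure_model` (coordinates of frame 1)
#' @param frames numeric array `n_frames x n_atoms x 3` (Angstrom)
#' @param dt_ps time between stored frames, picoseconds (> 0)
#' @return object of class `frame_series`
#' @export
frame_series <- function(topology, frames, dt_ps) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frame_series: frames must be n_frames x n_atoms x 3")
  if (dim(frames)[2] != nrow(topology))
    stop("frame_series: frame atom count ", dim(frames)[2],
         " does not match topology (", nrow(topology), ")")
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || dt_ps <= 0)
    stop("frame_series: dt_ps must be a positive scalar")
  structure(list(topology = topology, frames = frames, dt_ps = dt_ps),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf(
    "<frame_series> %d frames x %d atoms, dt = %g ps (%.3f ns total)\n",
    n_frames(x), dim(x$frames)[2], x$dt_ps,
    (n_frames(x) - 1) * x$dt_ps / 1000))
  invisible(x)
}

#' @export
n_frames <- function(series) UseMethod("n_frames")

#' @export
n_frames.frame_series <- function(series) dim(series$frames)[1]

#' Coordinates of one frame
#' @param series a `frame_series`
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix
#' @export
frame_coords <- function(series, i) {
  stopifnot(i >= 1, i <= n_frames(series))
  matrix(series$frames[i, , ], ncol = 3)
}

#' Frame indices of a trailing analysis window
#'
#' Selects the frames analysed by the trajectory statistics: those inside
#' the trailing `window_ns` of the series, subsampled to one frame every
#' `sample_every_ps`. With frame times t_i = (i-1) dt_ps, the window covers
#' (t_end - window, t_end].
#'
#' @param series a `frame_series`
#' @param window_ns trailing window length, ns (NULL = whole series)
#' @param sample_every_ps sampling interval, ps; must be a multiple of
#'   `dt_ps` (NULL = every stored frame)
#' @return integer vector of frame indices
#' @export
window_frames <- function(series, window_ns = NULL, sample_every_ps = NULL) {
  nf <- n_frames(series)
  t_ps <- (seq_len(nf) - 1) * series$dt_ps
  total_ns <- t_ps[nf] / 1000
  if (is.null(window_ns)) window_ns <- Inf
  if (is.finite(window_ns) && window_ns > total_ns + 1e-9)
    stop("window_frames: window of ", window_ns,
         " ns exceeds trajectory length of ", total_ns, " ns")
  # strictly trailing: a frame exactly at the window edge is excluded,
  # so "the last W ns" at stride dt holds exactly W/dt frames
  keep <- t_ps > t_ps[nf] - window_ns * 1000 + series$dt_ps * 1e-6
  idx <- which(keep)
  if (!is.null(sample_every_ps)) {
    stride <- sample_every_ps / series$dt_ps
    if (abs(stride - round(stride)) > 1e-9 || stride < 1)
      stop("window_frames: sample_every_ps must be a positive multiple of dt_ps")
    stride <- as.integer(round(stride))
    idx <- idx[seq(1L, length(idx), by = stride)]
  }
  if (!length(idx)) stop("window_frames: empty analysis window")
  idx
}
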