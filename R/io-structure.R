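#' Read an atomic structure (PDB or mmCIF)
#'
#' Parses coordinate files through bio3d and returns a [structure_model()].
#' Author residue numbering is preserved. For multi-model files the first
#' model is returned unless `model` says otherwise. Alternate locations are
#' collapsed to one conformer per (chain, resid, name): the highest
#' occupancy wins, ties broken by altloc letter order. Hydrogens are kept
#' when present (the contact rule downstream counts any atom).
#'
#' @param path file path
#' @param format `"pdb"`, `"cif"`, or NULL to infer from the extension
#' @param model 1-based model index for multi-model files
#' @return a `structure_model`
#' @export
read_structure <- function(path, format = NULL, model = 1L) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif",
                     mmcif = "cif",
                     stop("read_structure: cannot infer format from '.",
                          ext, "'; pass format="))
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = (model > 1L), rm.alt = FALSE,
                      verbose = FALSE)
    } else {
      bio3d::read.cif(path, verbose = FALSE)
    },
    error = function(e) stop("read_structure: failed to parse ", path,
                             ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("read_structure: zero atoms parsed from ", path)
  if (model > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("read_structure: model ", model, " not present in ", path)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  bio3d_atoms_to_model(at)
}

# convert a bio3d atom table to structure_model, resolving altlocs
bio3d_atoms_to_model <- function(at) {
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  guess <- sub("^[0-9]*", "", at$elety)
  guess <- toupper(substr(guess, 1, 1))
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)), guess, trimws(elem))
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  occ <- ifelse(is.na(at$o), 1, at$o)
  bf <- ifelse(is.na(at$b), 0, at$b)
  alt <- if (is.null(at$alt)) rep(NA_character_, nrow(at)) else at$alt
  df <- data.frame(serial = at$eleno, name = at$elety, element = elem,
                   resname = at$resid, chain = chain, resid = at$resno,
                   x = at$x, y = at$y, z = at$z, occ = occ, b = bf,
                   alt = ifelse(is.na(alt), "", alt),
                   stringsAsFactors = FALSE)
  key <- paste(df$chain, df$resid, df$name, sep = "|")
  if (anyDuplicated(key)) {
    # highest occupancy conformer; ties broken by altloc letter order
    ord <- order(key, -df$occ, df$alt)
    df <- df[ord, ]
    df <- df[!duplicated(paste(df$chain, df$resid, df$name, sep = "|")), ]
    df <- df[order(df$serial), ]
  }
  df$alt <- NULL
  structure_model(df)
}

#' Write a structure to PDB or mmCIF
#'
#' @param model a `structure_model`
#' @param path output path
#' @param format `"pdb"` (via bio3d) or `"cif"` (minimal atom_site loop)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) %in% c("cif", "mmcif"))
      "cif" else "pdb"
  if (format == "pdb") {
    writeLines(c(pdb_atom_records(model), "END"), path)
  } else {
    write_mmcif_atoms(model, path)
  }
  invisible(path)
}

# PDB v3 fixed-width ATOM/HETATM records. Written in-package because
# 4-character lipid residue names (POPC etc.) must end at column 21 with
# the chain identifier at column 22.
pdb_atom_records <- function(model, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(model)
  nm <- ifelse(nchar(model$name) < 4, paste0(" ", model$name), model$name)
  rec <- ifelse(model$resname %in% AMINO3, "ATOM  ", "HETATM")
  # lipids and other non-polymer groups still carry coordinates the same
  # way; keep ATOM for anything with a CA to be kind to coarse parsers
  rec[model$name == "CA"] <- "ATOM  "
  sprintf("%s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, model$serial %% 100000, nm, model$resname,
          substr(model$chain, 1, 1), model$resid %% 10000,
          xyz[, 1], xyz[, 2], xyz[, 3], model$occ, model$b,
          model$element)
}

write_mmcif_atoms <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  # standard PDBx/mmCIF atom_site column layout (readers parse by position)
  writeLines(c("data_model", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  grp <- ifelse(model$resname %in% AMINO3, "ATOM", "HETATM")
  writeLines(sprintf(
    "%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    grp, model$serial, model$element, model$name, model$resname,
    model$chain, model$resid, model$x, model$y, model$z, model$occ,
    model$b, model$resid, model$resname, model$chain, model$name), con)
  writeLines("#", con)
}

#' Read a trajectory as a frame series
#'
#' Accepts a multi-model PDB file or a character vector of single-model
#' coordinate files (one frame each, in order). Every frame must match the
#' topology atom count; a mismatch is reported with the offending frame
#' index. Frame times are `(i-1) * dt_ps`; the interval is never inferred
#' from file metadata.
#'
#' @param source multi-model PDB path, or vector of per-frame paths
#' @param topology optional `structure_model`; defaults to frame 1
#' @param dt_ps time between stored frames, ps
#' @return a `frame_series`
#' @export
read_frames <- function(source, topology = NULL, dt_ps) {
  if (length(source) == 1L) {
    pdb <- tryCatch(bio3d::read.pdb(source, multi = TRUE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e) stop("read_frames: failed to parse ",
                                             source, ": ",
                                             conditionMessage(e)))
    first <- bio3d_atoms_to_model(pdb$atom)
    nfr <- nrow(pdb$xyz)
    nat <- ncol(pdb$xyz) / 3
    if (is.null(topology)) topology <- first
    if (nat != nrow(topology))
      stop("read_frames: frame 1 has ", nat, " atoms; topology has ",
           nrow(topology))
    frames <- array(NA_real_, c(nfr, nat, 3))
    for (i in seq_len(nfr))
      frames[i, , ] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  } else {
    models <- lapply(source, read_structure)
    if (is.null(topology)) topology <- models[[1]]
    nat <- nrow(topology)
    for (i in seq_along(models))
      if (nrow(models[[i]]) != nat)
        stop("read_frames: frame ", i, " has ", nrow(models[[i]]),
             " atoms; topology has ", nat)
    frames <- array(NA_real_, c(length(models), nat, 3))
    for (i in seq_along(models)) frames[i, , ] <- coords(models[[i]])
  }
  frame_series(topology, frames, dt_ps)
}

#' Write a frame series as a multi-model PDB
#'
#' @param series a `frame_series`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frames <- function(series, path) {
  stopifnot(inherits(series, "frame_series"))
  top <- series$topology
  lines <- vector("list", n_frames(series))
  for (i in seq_len(n_frames(series)))
    lines[[i]] <- c(sprintf("MODEL     %4d", i),
                    pdb_atom_records(top, frame_coords(series, i)),
                    "ENDMDL")
  writeLines(c(unlist(lines), "END"), path)
  invisible(path)
}
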