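# Residue-type partition used for contact-partner ratios. Histidine is
# counted as charged. Configurable; structural papers rarely print their
# exact scheme.
RESIDUE_CLASSES <- list(
  nonpolar = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "MET", "CYS"),
  polar    = c("SER", "THR", "ASN", "GLN"),
  charged  = c("ASP", "GLU", "LYS", "ARG", "HIS"),
  aromatic = c("PHE", "TYR", "TRP"))

residue_class_of <- function(resname, classes = RESIDUE_CLASSES) {
  out <- rep(NA_character_, length(resname))
  for (cl in names(classes)) out[resname %in% classes[[cl]]] <- cl
  out
}

# Cell-list accelerated neighbour search: for each frame, which (group A
# atom, group B atom) pairs lie within `cutoff`? Returns for given A/B
# coordinate matrices an integer matrix of qualifying pair indices.
# Distances are computed identically to a naive all-pairs evaluation
# (same squared-distance arithmetic), so results match it exactly.
close_pairs <- function(A, B, cutoff) {
  nb <- nrow(B)
  cell <- floor(sweep(B, 2, rep(cutoff, 3), "/"))
  keyB <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(nb), keyB)
  cellA <- floor(sweep(A, 2, rep(cutoff, 3), "/"))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  ai_out <- integer(0); bi_out <- integer(0)
  for (i in seq_len(nrow(A))) {
    cand <- integer(0)
    for (k in seq_len(27)) {
      key <- paste(cellA[i, 1] + offs[k, 1], cellA[i, 2] + offs[k, 2],
                   cellA[i, 3] + offs[k, 3])
      hit <- bins[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    dx <- B[cand, 1] - A[i, 1]
    dy <- B[cand, 2] - A[i, 2]
    dz <- B[cand, 3] - A[i, 3]
    ok <- (dx * dx + dy * dy + dz * dz) <= cut2
    if (any(ok)) {
      ai_out <- c(ai_out, rep.int(i, sum(ok)))
      bi_out <- c(bi_out, cand[ok])
    }
  }
  cbind(a = ai_out, b = bi_out)
}

#' Protein-scaffold contact probability per residue
#'
#' A protein residue is "in contact" in a frame iff any of its atoms lies
#' within `cutoff_A` (inclusive) of any scaffold atom. The probability is
#' the fraction of analysed frames in contact, computed over the trailing
#' window. Residues exceeding the strict `> high_contact_threshold` rule
#' are flagged (the display rule for high-contact residues).
#'
#' @param series a `frame_series`
#' @param protein_sel,scaffold_sel disjoint non-empty `atom_selection`s
#' @param cutoff_A contact distance cutoff, Angstrom (default 4.5)
#' @param window_ns trailing window, ns (NULL = all frames)
#' @param sample_every_ps sampling interval, ps (NULL = every frame)
#' @param high_contact_threshold display threshold (default 0.25; strict >)
#' @return a `contact_profile` data frame: chain, resid, resname,
#'   probability, is_high_contact; attributes carry the frame events used
#'   by [partner_type_ratio()]
#' @export
contact_probability <- function(series, protein_sel, scaffold_sel,
                                cutoff_A = 4.5, window_ns = NULL,
                                sample_every_ps = NULL,
                                high_contact_threshold = 0.25) {
  top <- series$topology
  pi_ <- selection_indices(protein_sel)
  si <- selection_indices(scaffold_sel)
  if (!length(pi_) || !length(si))
    stop("contact_probability: empty selection")
  if (length(intersect(pi_, si)))
    stop("contact_probability: protein and scaffold selections overlap")
  fr <- window_frames(series, window_ns, sample_every_ps)
  pres <- residue_key(top, pi_)
  res_levels <- unique(pres)
  pres_i <- match(pres, res_levels)
  sres <- residue_key(top, si)
  sres_levels <- unique(sres)
  sres_i <- match(sres, sres_levels)
  n_in_contact <- integer(length(res_levels))
  # events[[f]]: 2-column matrix of (protein residue, scaffold residue)
  # pairs in contact in analysed frame f
  events <- vector("list", length(fr))
  for (fi in seq_along(fr)) {
    xyz <- frame_coords(series, fr[fi])
    pr <- close_pairs(xyz[pi_, , drop = FALSE], xyz[si, , drop = FALSE],
                      cutoff_A)
    if (nrow(pr)) {
      rp <- pres_i[pr[, "a"]]
      rs <- sres_i[pr[, "b"]]
      uniq <- !duplicated(rp * (length(sres_levels) + 1) + rs)
      events[[fi]] <- cbind(p = rp[uniq], s = rs[uniq])
      touched <- unique(rp)
      n_in_contact[touched] <- n_in_contact[touched] + 1L
    } else events[[fi]] <- cbind(p = integer(0), s = integer(0))
  }
  prob <- n_in_contact / length(fr)
  first_atom <- pi_[match(res_levels, pres)]
  out <- data.frame(chain = top$chain[first_atom],
                    resid = top$resid[first_atom],
                    resname = top$resname[first_atom],
                    probability = prob,
                    is_high_contact = prob > high_contact_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "events") <- events
  attr(out, "residue_levels") <- res_levels
  attr(out, "scaffold_levels") <- sres_levels
  attr(out, "scaffold_resname") <- top$resname[si[match(sres_levels, sres)]]
  attr(out, "frames_used") <- length(fr)
  attr(out, "cutoff_A") <- cutoff_A
  attr(out, "high_contact_threshold") <- high_contact_threshold
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Residue-type ratios of scaffold contact partners
#'
#' For each protein residue above the high-contact threshold, counts
#' (frame, scaffold residue) contact events — each scaffold residue counts
#' once per frame however many atom pairs qualify — and reports the
#' fractions of events by scaffold residue class. Fractions sum to 1 for
#' every reported residue.
#'
#' @param contact_profile result of [contact_probability()]
#' @param classes residue-class partition (named list of 3-letter codes)
#' @return a `partner_type_ratio` data frame: chain, resid, resname,
#'   n_events, then one fraction column per class
#' @export
partner_type_ratio <- function(contact_profile,
                               classes = RESIDUE_CLASSES) {
  stopifnot(inherits(contact_profile, "contact_profile"))
  events <- attr(contact_profile, "events")
  sres_class <- residue_class_of(attr(contact_profile, "scaffold_resname"),
                                 classes)
  hi <- which(contact_profile$is_high_contact)
  ev <- do.call(rbind, events)
  rows <- lapply(hi, function(ri) {
    mine <- ev[ev[, "p"] == ri, "s"]
    if (!length(mine))
      stop("partner_type_ratio: high-contact residue with zero events (",
           contact_profile$resid[ri], "); contract violation")
    cls <- sres_class[mine]
    tab <- vapply(names(classes),
                  function(cl) sum(cls == cl, na.rm = TRUE), numeric(1))
    c(n_events = length(mine), tab / sum(tab))
  })
  mat <- do.call(rbind, rows)
  out <- cbind(contact_profile[hi, c("chain", "resid", "resname")],
               as.data.frame(mat))
  rownames(out) <- NULL
  class(out) <- c("partner_type_ratio", "data.frame")
  out
}
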