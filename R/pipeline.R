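#' Analysis configuration
#'
#' Builds the configuration record consumed by the `run_*` pipeline
#' commands, filling protocol defaults: transmembrane residue range
#' 201-322, contact cutoff 4.5 A, radial thickness bins of 3 A, polar
#' bins of 5 A and pi/15 rad, trailing analysis window 250 ns sampled
#' every 200 ps, 8 A low-pass filtering and a 1-sigma contour. A config
#' can come from a YAML file (flat keys) or a named list; unknown keys
#' are an error so typos do not pass silently.
#'
#' @param ... configuration keys (see Details), or a single `file`
#'   argument naming a YAML file
#' @param file optional YAML file path
#' @return an `analysis_config` (named list)
#' @details Keys: `structure`, `reference_structure`, `trajectory`,
#'   `map`, `dt_ps`, `tmd_sel`, `ecd_sel`, `m2_sel`, `m4_sel`,
#'   `pore_lining_sel`, `protein_sel`, `scaffold_sel`, `msp_backbone_sel`,
#'   `lipid_sel`, `cutoff_A`, `bin_width_A`, `r_max_A`, `r_bin_A`,
#'   `theta_bin_rad`, `window_ns`, `sample_every_ps`, `lowpass_A`,
#'   `contour_sigma`, `out_dir`, `seed`.
#' @export
analysis_config <- function(..., file = NULL) {
  defaults <- list(
    structure = NULL, reference_structure = NULL, trajectory = NULL,
    map = NULL, dt_ps = 200,
    tmd_sel = "calpha and resid 201:322",
    ecd_sel = "calpha and resid -999:200",
    m2_sel = "calpha and resid 230:247",
    m4_sel = "calpha and resid 305:322",
    pore_lining_sel = "calpha and resid 230:247",
    protein_sel = "chain P", scaffold_sel = "chain M N S",
    msp_backbone_sel = "chain M N",
    lipid_sel = "resname POPC POPE POPG",
    tmd_backbone_sel = "backbone and resid 201:322",
    cutoff_A = 4.5, bin_width_A = 3, r_max_A = 45,
    r_bin_A = 5, theta_bin_rad = pi / 15,
    window_ns = NULL, sample_every_ps = 200,
    lowpass_A = 8, contour_sigma = 1,
    out_dir = ".", seed = 1)
  user <- list(...)
  if (!is.null(file)) user <- utils::modifyList(yaml::read_yaml(file), user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("analysis_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  class(cfg) <- "analysis_config"
  cfg
}

# stable CSV writer: 6 significant digits, no row names, '.' decimal,
# NA written as empty field; byte-stable across runs
write_csv_stable <- function(df, path) {
  fm <- df
  for (j in seq_along(fm))
    if (is.numeric(fm[[j]]) && !is.integer(fm[[j]]))
      fm[[j]] <- ifelse(is.na(fm[[j]]), "",
                        trimws(formatC(fm[[j]], format = "g", digits = 6)))
  utils::write.csv(fm, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

run_report <- function(cfg, outputs, warnings = character()) {
  for (f in outputs)
    if (!file.exists(f) || file.info(f)$size == 0)
      stop("run report: output missing or empty: ", f)
  list(outputs = outputs,
       version = as.character(utils::packageVersion("discmetrics")),
       config_hash = config_hash(cfg),
       warnings = warnings)
}

config_hash <- function(cfg) {
  ser <- jsonlite::toJSON(cfg[order(names(unclass(cfg)))],
                          auto_unbox = TRUE, null = "null", digits = NA,
                          force = TRUE)
  # small stable polynomial hash; avoids external digest dependencies
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

echo_config <- function(cfg, out_dir) {
  path <- file.path(out_dir, "config.yaml")
  cfg2 <- unclass(cfg)
  cfg2 <- cfg2[!vapply(cfg2, is.null, logical(1))]
  yaml::write_yaml(cfg2, path)
  path
}

#' Structure geometry report
#'
#' Runs the single-structure geometry analyses on `cfg$structure`:
#' per-residue M2 C-alpha distance to the pore axis, M4 tilt table, pore
#' radius profile, and — when `cfg$reference_structure` is given — the
#' extracellular-domain rotation angle of structure vs reference. Writes
#' `m2_distance.csv`, `m4_tilt.csv`, `pore_profile.csv`,
#' `ecd_rotation.json` and a verbatim config echo to `cfg$out_dir`.
#'
#' @param cfg an `analysis_config` with `structure` set
#' @return a run report (list of outputs, version, config hash, warnings)
#' @export
run_structure_metrics <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"), !is.null(cfg$structure))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  model <- read_structure(cfg$structure)
  axis <- compute_pore_axis(model, select_atoms(model,
                                                cfg$pore_lining_sel))
  outputs <- character()
  dp <- residue_axis_distance(model, axis,
                              select_atoms(model, cfg$m2_sel))
  s <- attr(dp, "summary")
  outputs <- c(outputs, write_csv_stable(
    data.frame(resid = s$resid, mean_A = s$mean, sd_A = s$sd, n = s$n),
    file.path(cfg$out_dir, "m2_distance.csv")))
  m4_tab <- tryCatch({
    ht <- helix_tilt_angle(model, select_atoms(model, cfg$m4_sel), axis)
    data.frame(chain = ht$per_subunit$chain,
               tilt_deg = ht$per_subunit$tilt_deg,
               mean_deg = ht$mean_deg, sd_deg = ht$sd_deg)
  }, error = function(e) {
    warnings <<- c(warnings, paste("M4 tilt unavailable:",
                                   conditionMessage(e)))
    data.frame(chain = NA_character_, tilt_deg = NA_real_,
               mean_deg = NA_real_, sd_deg = NA_real_)
  })
  outputs <- c(outputs, write_csv_stable(
    m4_tab, file.path(cfg$out_dir, "m4_tilt.csv")))
  pp <- pore_radius_profile(model, axis, step = 1)
  outputs <- c(outputs, write_csv_stable(
    as.data.frame(pp), file.path(cfg$out_dir, "pore_profile.csv")))
  if (!is.null(cfg$reference_structure)) {
    ref <- read_structure(cfg$reference_structure)
    er <- ecd_rotation_angle(ref, model, cfg$tmd_sel, cfg$ecd_sel)
    ej <- file.path(cfg$out_dir, "ecd_rotation.json")
    jsonlite::write_json(list(twist_deg = er$twist_deg,
                              total_deg = er$total_deg,
                              tmd_rmsd = er$tmd_rmsd),
                         ej, auto_unbox = TRUE, digits = 6)
    outputs <- c(outputs, ej)
  }
  outputs <- c(outputs, echo_config(cfg, cfg$out_dir))
  run_report(cfg, outputs, warnings)
}

#' Membrane thickness report
#'
#' Runs the bilayer analyses on `cfg$trajectory` (multi-model PDB):
#' radial thickness profiles with both markers and the polar thickness
#' map, writing `thickness_phosphorus.csv`, `thickness_glycerol.csv`,
#' `polar_thickness.csv` plus a config echo.
#'
#' @param cfg an `analysis_config` with `trajectory` set
#' @return a run report
#' @export
run_membrane_metrics <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"), !is.null(cfg$trajectory))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_frames(cfg$trajectory, dt_ps = cfg$dt_ps)
  top <- series$topology
  bb <- select_atoms(top, cfg$tmd_backbone_sel)
  lip <- select_atoms(top, cfg$lipid_sel)
  outputs <- character()
  for (mk in c("phosphorus", "glycerol_center")) {
    pr <- thickness_vs_distance(series, bb, lip, marker = mk,
                                bin_width = cfg$bin_width_A,
                                r_max = cfg$r_max_A,
                                window_ns = cfg$window_ns,
                                sample_every_ps = NULL)
    nm <- if (mk == "phosphorus") "thickness_phosphorus.csv" else
      "thickness_glycerol.csv"
    outputs <- c(outputs, write_csv_stable(
      as.data.frame(pr), file.path(cfg$out_dir, nm)))
  }
  axis <- pore_axis()
  pm <- polar_thickness_map(series, axis, lip,
                            r_bin = cfg$r_bin_A,
                            theta_bin = cfg$theta_bin_rad,
                            r_max = cfg$r_max_A,
                            window_ns = cfg$window_ns)
  outputs <- c(outputs, write_csv_stable(
    as.data.frame(pm), file.path(cfg$out_dir, "polar_thickness.csv")))
  outputs <- c(outputs, echo_config(cfg, cfg$out_dir))
  run_report(cfg, outputs)
}

#' Scaffold contact and shape report
#'
#' Runs the protein-scaffold analyses on `cfg$trajectory`: per-residue
#' contact probabilities, partner residue-type ratios for high-contact
#' residues, and the nanodisc diameter time series from ellipse fits of
#' the scaffold belt. Writes `contacts.csv`, `partner_ratios.csv`,
#' `diameter_series.csv` plus a config echo.
#'
#' @param cfg an `analysis_config` with `trajectory` set
#' @return a run report
#' @export
run_scaffold_metrics <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"), !is.null(cfg$trajectory))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_frames(cfg$trajectory, dt_ps = cfg$dt_ps)
  top <- series$topology
  cp <- contact_probability(series,
                            select_atoms(top, cfg$protein_sel),
                            select_atoms(top, cfg$scaffold_sel),
                            cutoff_A = cfg$cutoff_A,
                            window_ns = cfg$window_ns)
  outputs <- write_csv_stable(as.data.frame(cp),
                              file.path(cfg$out_dir, "contacts.csv"))
  if (any(cp$is_high_contact)) {
    pr <- partner_type_ratio(cp)
    outputs <- c(outputs, write_csv_stable(
      as.data.frame(pr), file.path(cfg$out_dir, "partner_ratios.csv")))
  }
  ds <- nanodisc_diameter_series(series,
                                 select_atoms(top, cfg$msp_backbone_sel),
                                 window_ns = cfg$window_ns)
  outputs <- c(outputs, write_csv_stable(
    as.data.frame(ds), file.path(cfg$out_dir, "diameter_series.csv")))
  dj <- file.path(cfg$out_dir, "diameter_summary.json")
  jsonlite::write_json(list(mean_major_A = attr(ds, "mean_major_A"),
                            sd_major_A = attr(ds, "sd_major_A"),
                            mean_minor_A = attr(ds, "mean_minor_A"),
                            sd_minor_A = attr(ds, "sd_minor_A"),
                            n_window = attr(ds, "n_window")),
                       dj, auto_unbox = TRUE, digits = 6)
  outputs <- c(outputs, dj, echo_config(cfg, cfg$out_dir))
  run_report(cfg, outputs)
}

#' Map diameter report
#'
#' Low-pass filters the density map in `cfg$map` at `cfg$lowpass_A` and
#' measures the nanodisc diameter at the `cfg$contour_sigma` contour.
#' Writes `map_diameter.json` plus a config echo.
#'
#' @param cfg an `analysis_config` with `map` set
#' @return a run report
#' @export
run_map_diameter <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"), !is.null(cfg$map))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- read_density_map(cfg$map)
  fm <- lowpass_filter(map, cfg$lowpass_A)
  dd <- measure_disc_diameter(fm, contour_sigma = cfg$contour_sigma)
  dj <- file.path(cfg$out_dir, "map_diameter.json")
  jsonlite::write_json(list(resolution_A = cfg$lowpass_A,
                            contour_sigma = dd$contour_sigma,
                            threshold = dd$threshold,
                            diameter_nm = dd$diameter_nm,
                            slab_z = dd$slab_z),
                       dj, auto_unbox = TRUE, digits = 6)
  outputs <- c(dj, echo_config(cfg, cfg$out_dir))
  run_report(cfg, outputs)
}
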