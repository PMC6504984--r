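#' Study configuration
#'
#' Schema-validated configuration of a full phantom study: number of
#' cases, phantom geometry, device presets, threshold sweep, crop and
#' ICP settings, and one master seed from which every per-case,
#' per-device and per-registration seed is derived deterministically.
#' Unknown keys are rejected.
#'
#' The default geometry is a reduced arch sized for desk-scale
#' runtime; the design sizes (10 cases, 3 modalities, 13 thresholds,
#' 0.150 mm voxels) follow the bench protocol.
#'
#' @param config named list (e.g. from a YAML file) overriding the
#'   defaults below.
#' @return validated config list of class `study_config`.
#' @export
study_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    n_cases = 10L,
    n_teeth = 4L,
    arch_radius_mm = 6.5,
    tooth_height_mm = 3.5,
    gingiva_band_mm = 4,
    surface_resolution_mm = 0.12,
    devices = c("Planmeca80", "Planmeca90", "NewtomVG"),
    levels = "1425:2625:100",
    crop = "default",
    icp = list(n_sample_pairs = 2000L, max_iterations = 25L,
               convergence_tol_mm = 1e-5)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    mf_stop("mf_schema_error", "unknown config keys: %s",
            paste(unknown, collapse = ", "))
  if (!is.null(config$icp)) {
    bad <- setdiff(names(config$icp), names(defaults$icp))
    if (length(bad))
      mf_stop("mf_schema_error", "unknown icp config keys: %s",
              paste(bad, collapse = ", "))
    config$icp <- utils::modifyList(defaults$icp, config$icp)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed) || !is.finite(as.numeric(cfg$seed)))
    mf_stop("mf_schema_error", "config must carry an explicit numeric seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_cases <- as.integer(cfg$n_cases)
  if (cfg$n_cases < 1L) mf_stop("mf_schema_error", "n_cases must be >= 1")
  presets <- device_presets()
  bad <- setdiff(cfg$devices, names(presets))
  if (length(bad))
    mf_stop("mf_schema_error", "unknown device presets: %s",
            paste(bad, collapse = ", "))
  structure(cfg, class = "study_config")
}

#' Parse a "from:to:step" level specification
#' @param x numeric vector or a "from:to:step" string.
#' @keywords internal
parse_levels <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 3L || anyNA(p))
    mf_stop("mf_schema_error", "levels must be numeric or 'from:to:step'")
  seq(p[1], p[2], by = p[3])
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 1000003
  for (i in idx) s <- (s * 7919 + i) %% 1000003
  as.integer(s + 1)
}

#' Run the full phantom study
#'
#' Generates `n_cases` ground-truth phantoms (alternating maxilla and
#' mandible), simulates one CBCT volume per device preset, runs the
#' per-case sweep pipeline ([run_case()]) and assembles the per-case
#' best-threshold table and the descriptive summary.
#'
#' @param config a [study_config()] (or a plain list passed to it).
#' @param progress print per-case progress to stderr.
#' @return list with `table2` (per-case best rows, [study_table()]),
#'   `table4` ([summarize_study()] output), `results` (per-case
#'   [run_case()] outputs), `config`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  levels <- parse_levels(config$levels)
  sweep <- threshold_sweep(levels)
  presets <- device_presets()[config$devices]
  results <- vector("list", config$n_cases)
  for (ci in seq_len(config$n_cases)) {
    if (progress)
      message(sprintf("[meshfidelity] case %d/%d", ci, config$n_cases))
    spec <- phantom_spec(
      case_id = sprintf("case%02d", ci),
      arch_kind = if (ci %% 2L == 1L) "maxilla" else "mandible",
      n_teeth = config$n_teeth,
      arch_radius_mm = config$arch_radius_mm,
      tooth_height_mm = config$tooth_height_mm,
      gingiva_band_mm = config$gingiva_band_mm,
      rng_seed = derive_seed(config$seed, 1L, ci),
      surface_resolution_mm = config$surface_resolution_mm)
    gt <- generate_ground_truth(spec)
    vols <- lapply(seq_along(presets), function(di)
      voxelize(gt, presets[[di]], seed = derive_seed(config$seed, 2L, ci, di)))
    names(vols) <- names(presets)
    crop <- if (identical(config$crop, "default")) default_crop_region(spec)
            else crop_region("box", lo = config$crop$lo, hi = config$crop$hi)
    icp <- icp_config(n_sample_pairs = config$icp$n_sample_pairs,
                      max_iterations = config$icp$max_iterations,
                      convergence_tol_mm = config$icp$convergence_tol_mm,
                      rng_seed = derive_seed(config$seed, 3L, ci))
    results[[ci]] <- run_case(gt, vols, sweep, crop, icp,
                              case_id = spec$case_id)
  }
  tab2 <- study_table(results)
  list(table2 = tab2, table4 = summarize_study(tab2),
       results = results, config = config)
}

#' Write study outputs and a reproducibility manifest
#'
#' Writes `table2.csv` (per-case best rows), `table4.csv` (descriptive
#' summary), the per-threshold Dissimilarity-Index curves
#' (`di_curves.csv`) and `manifest.json` holding the config, its hash,
#' the master seed and package/R versions -- enough to re-run
#' bit-identically.
#'
#' @param study a [run_study()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(study$table2, file.path(out_dir, "table2.csv"), row.names = FALSE)
  write.csv(study$table4, file.path(out_dir, "table4.csv"), row.names = FALSE)
  curves <- do.call(rbind, lapply(study$results, function(cr)
    do.call(rbind, lapply(cr, function(sr) data.frame(
      case_id = sr$case_id, device_id = sr$device_id,
      threshold = as.numeric(names(sr$per_threshold)),
      di = vapply(sr$per_threshold, function(s) s$di, numeric(1)),
      median_mm = vapply(sr$per_threshold, function(s) s$median_mm,
                         numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)))))
  write.csv(curves, file.path(out_dir, "di_curves.csv"), row.names = FALSE)
  cfg <- unclass(study$config)
  manifest <- list(
    config = cfg,
    config_sha1 = digest::digest(cfg, algo = "sha1"),
    seed = cfg$seed,
    package_version = as.character(packageVersion("meshfidelity")),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
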