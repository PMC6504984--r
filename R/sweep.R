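#' Run the full per-case pipeline
#'
#' For one stone-model case: extract a mesh from every device volume at
#' every sweep level (13 x devices meshes), finely register the group
#' to a hub mesh (the mid-sweep extraction of the first device),
#' simultaneously crop all of them, then register each cropped mesh to
#' the reference surface, compute per-face deviations and summarize.
#' The best threshold per device is the one minimizing the
#' Dissimilarity Index; ties break toward the lower HU.
#'
#' @param reference the gold-standard [tri_mesh()].
#' @param volumes named list of [voxel_volume()] objects, one per
#'   device.
#' @param sweep a [threshold_sweep()].
#' @param crop a [crop_region()] applied to all meshes in one call.
#' @param icp an [icp_config()]; per-registration seeds are derived
#'   from `icp$rng_seed` deterministically.
#' @param case_id label for error context and output rows.
#' @return named list (per device) of `sweep_result` objects with
#'   `per_threshold` (list of [summarize_deviations()] results keyed by
#'   level), `best_threshold`, `best_summary`.
#' @export
run_case <- function(reference, volumes, sweep = threshold_sweep(),
                     crop = NULL, icp = icp_config(), case_id = "case") {
  if (nrow(reference$faces) < 1L)
    mf_stop("mf_empty_mesh", "reference mesh is empty")
  if (length(volumes) < 1L)
    mf_stop("mf_invalid_spec", "need at least one device volume")
  if (is.null(names(volumes)) || any(!nzchar(names(volumes))))
    mf_stop("mf_invalid_spec", "volumes must be a named list (device ids)")
  levels <- sweep$levels
  devices <- names(volumes)

  ctx <- function(device, level, expr) {
    tryCatch(expr, mf_error = function(e) {
      mf_stop("mf_pipeline_error", "[case %s, device %s, level %g] %s",
              case_id, device, level, conditionMessage(e))
    })
  }

  # 1) extraction sweep
  meshes <- list()
  for (dv in devices) for (li in seq_along(levels)) {
    lv <- levels[li]
    m <- ctx(dv, lv, extract_mesh(volumes[[dv]], lv))
    m$provenance <- sprintf("%s/%s/level=%g", case_id, dv, lv)
    meshes[[paste(dv, li, sep = ".")]] <- m
  }

  # 2) group registration to the hub (mid-sweep mesh of the first device)
  hub_level <- levels[ceiling(length(levels) / 2)]
  hub_key <- paste(devices[1], which(levels == hub_level), sep = ".")
  hub_tree <- surface_tree(meshes[[hub_key]])
  # sampling seeds depend on the sweep level only, so devices presenting
  # identical volumes yield bit-identical results
  for (dv in devices) for (li in seq_along(levels)) {
    key <- paste(dv, li, sep = ".")
    if (key == hub_key) next
    cfg <- icp
    cfg$rng_seed <- icp$rng_seed + li
    reg <- icp_register(meshes[[key]], meshes[[hub_key]], cfg,
                        fixed_tree = hub_tree)
    meshes[[key]] <- rt_apply_mesh(reg$transform, meshes[[key]])
  }

  # 3) simultaneous crop
  if (!is.null(crop)) meshes <- stats::setNames(
    crop_meshes(meshes, crop), names(meshes))

  # 4) per-mesh registration to the reference + deviation summary
  ref_tree <- surface_tree(reference)
  results <- list()
  for (dv in devices) {
    per <- vector("list", length(levels))
    names(per) <- as.character(levels)
    for (li in seq_along(levels)) {
      key <- paste(dv, li, sep = ".")
      cfg <- icp
      cfg$rng_seed <- icp$rng_seed + 1000L + li
      m <- meshes[[key]]
      reg <- ctx(dv, levels[li],
                 icp_register(m, reference, cfg, fixed_tree = ref_tree))
      m <- rt_apply_mesh(reg$transform, m)
      dev <- ctx(dv, levels[li], face_deviations(m, ref_tree))
      per[[li]] <- summarize_deviations(dev)
    }
    di <- vapply(per, function(s) s$di, numeric(1))
    best <- which.min(di) # first minimum = lowest HU on ties
    results[[dv]] <- structure(
      list(case_id = case_id, device_id = dv, per_threshold = per,
           best_threshold = levels[best], best_summary = per[[best]]),
      class = "sweep_result")
  }
  results
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s / %s: best threshold %g HU, DI %.2f\n",
              x$case_id, x$device_id, x$best_threshold, x$best_summary$di))
  invisible(x)
}

#' Assemble best-threshold rows into a study table
#'
#' One row per case x device, holding the best-DI summary -- the shape
#' of the bench study's per-case results table.
#'
#' @param case_results list over cases of [run_case()] outputs.
#' @return data.frame with columns `case_id`, `device_id`, `threshold`,
#'   `p95_mm`, `median_mm`, `iqr_mm`, `di`.
#' @export
study_table <- function(case_results) {
  rows <- list()
  for (cr in case_results) for (sr in cr) {
    s <- sr$best_summary
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = sr$case_id, device_id = sr$device_id,
      threshold = sr$best_threshold, p95_mm = s$p95_mm,
      median_mm = s$median_mm, iqr_mm = s$iqr_mm, di = s$di,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Descriptive statistics per device and pooled
#'
#' Per device and pooled ("Total"): mean, SD, min, max and 95% CI
#' half-width (`t(n-1, 0.975) * SD / sqrt(n)`) of the best thresholds
#' and of the median deviations, plus means of the p95 bound, IQR and
#' Dissimilarity Index. With a single row per group the SD and CI are
#' undefined and returned as `NA`.
#'
#' @param tab a [study_table()]-shaped data.frame (columns
#'   `device_id`, `threshold`, `median_mm`, `iqr_mm`, `di`, `p95_mm`).
#' @return data.frame, one row per device plus a pooled `Total` row.
#' @export
summarize_study <- function(tab) {
  need <- c("device_id", "threshold", "median_mm", "iqr_mm", "di", "p95_mm")
  if (!all(need %in% names(tab)))
    mf_stop("mf_invalid_spec", "study table lacks columns: %s",
            paste(setdiff(need, names(tab)), collapse = ", "))
  counts <- table(factor(tab$device_id))
  if (length(unique(counts)) != 1L)
    mf_stop("mf_unbalanced_design",
            "unbalanced study table: per-device counts %s",
            paste(counts, collapse = ", "))
  one <- function(df, label) {
    n <- nrow(df)
    ci <- function(x) if (n > 1L) qt(0.975, n - 1L) * sd(x) / sqrt(n) else NA_real_
    s <- function(x) if (n > 1L) sd(x) else NA_real_
    data.frame(
      group = label, n = n,
      mean_threshold = mean(df$threshold), sd_threshold = s(df$threshold),
      min_threshold = min(df$threshold), max_threshold = max(df$threshold),
      ci_threshold = ci(df$threshold),
      mean_median_mm = mean(df$median_mm), sd_median_mm = s(df$median_mm),
      min_median_mm = min(df$median_mm), max_median_mm = max(df$median_mm),
      ci_median_mm = ci(df$median_mm),
      mean_p95_mm = mean(df$p95_mm), min_p95_mm = min(df$p95_mm),
      max_p95_mm = max(df$p95_mm),
      mean_iqr_mm = mean(df$iqr_mm), mean_di = mean(df$di),
      stringsAsFactors = FALSE)
  }
  out <- rbind(
    one(tab, "Total"),
    do.call(rbind, lapply(split(tab, tab$device_id),
                          function(df) one(df, df$device_id[1]))))
  rownames(out) <- NULL
  out
}
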