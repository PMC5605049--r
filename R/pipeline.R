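# End-to-end runs: measurement of a four-scan set into profiles,
# topography and PCT summary; cohort statistics mirroring the published
# table layout.  A thin command-line wrapper over these functions ships
# in inst/cli/pctopo.R.

#' Pipeline configuration
#'
#' Defaults are the published analysis constants: 1 um perpendicular
#' sampling, 2.80 mm common trim extent, 2.50 mm statistical extent, 10%
#' observer-disagreement threshold, 1.10 disc-swelling boundary and 0.05
#' univariate screening alpha.
#'
#' @param interval_um Perpendicular sampling interval (um).
#' @param degree Reference-curve smoothing polynomial degree.
#' @param common_extent_mm Common trim extent (mm).
#' @param stat_extent_mm Statistical extent (mm).
#' @param disagreement_threshold Observer disagreement fraction.
#' @param swelling_threshold OP/RN RNFL-ratio boundary.
#' @param screening_alpha Univariate screening threshold.
#' @param angular_resolution_deg,radial_resolution_mm Topography grid.
#' @param seed RNG seed recorded in run manifests.
#' @return A `run_config` list.
#' @export
run_config <- function(interval_um = 1, degree = 4L,
                       common_extent_mm = 2.80, stat_extent_mm = 2.50,
                       disagreement_threshold = 0.10,
                       swelling_threshold = 1.10,
                       screening_alpha = 0.05,
                       angular_resolution_deg = 1,
                       radial_resolution_mm = 0.01,
                       seed = 1L) {
  cfg <- list(interval_um = interval_um, degree = as.integer(degree),
              common_extent_mm = common_extent_mm,
              stat_extent_mm = stat_extent_mm,
              disagreement_threshold = disagreement_threshold,
              swelling_threshold = swelling_threshold,
              screening_alpha = screening_alpha,
              angular_resolution_deg = angular_resolution_deg,
              radial_resolution_mm = radial_resolution_mm,
              seed = seed)
  num <- c("interval_um", "common_extent_mm", "stat_extent_mm",
           "disagreement_threshold", "swelling_threshold",
           "screening_alpha", "angular_resolution_deg",
           "radial_resolution_mm")
  bad <- num[!vapply(cfg[num], function(v) is_number(v) && v > 0,
                     logical(1L))]
  if (length(bad)) {
    pct_stop("pctopo_spec_error", "config value(s) must be positive: %s",
             paste(bad, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Measure a four-scan directory into profiles, topography and summary
#'
#' Expects `<axis>.tiff` / `<axis>.json` pairs (axes 0, 45, 90, 135) in
#' `scan_dir`, each sidecar carrying the boundary annotation.  Writes
#' `profiles.csv`, `topography.csv`, `topography.png`, `summary.json` and
#' a `manifest.json` (config, package version, per-file QC flags) into
#' `out_dir`.
#'
#' @param scan_dir Input directory.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with `profiles`, `map`, `summary` and the
#'   manifest.
#' @export
run_measure <- function(scan_dir, out_dir, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pct_stop("pctopo_stage_error", "[%s] %s", name, conditionMessage(e))
    })
  }
  scans <- stage("read", {
    pairs <- lapply(VALID_AXES, function(ax) {
      img <- file.path(scan_dir, sprintf("%d.tiff", ax))
      if (!file.exists(img)) img <- file.path(scan_dir, sprintf("%d.png", ax))
      meta <- file.path(scan_dir, sprintf("%d.json", ax))
      if (!file.exists(img) || !file.exists(meta)) {
        pct_stop("pctopo_io_error", "missing scan files for axis %d: %s / %s",
                 ax, img, meta)
      }
      read_bscan(img, meta)
    })
    pairs
  })
  set <- stage("validate", validate_scan_set(scans))
  profiles <- stage("measure", {
    out <- list()
    for (s in set$scans) {
      ann <- attr(s, "annotation")
      if (is.null(ann)) {
        pct_stop("pctopo_io_error",
                 "axis %g sidecar lacks a boundary annotation",
                 s$direction_axis_deg)
      }
      out <- c(out, build_direction_profiles(
        s, ann, interval_um = config$interval_um, degree = config$degree))
    }
    out
  })
  disc <- stage("disc", {
    ds <- lapply(set$scans, function(s) {
      ann <- annotation_to_um(attr(s, "annotation"), s)
      locate_disc_center(ann$termini[1L, ], ann$termini[2L, ], s$eye)
    })
    mean(vapply(ds, function(d) d$diameter_mm, numeric(1L)))
  })
  trimmed <- stage("trim", trim_profiles(profiles, config$common_extent_mm))
  map <- stage("interpolate", interpolate_full_circle(
    trimmed, config$angular_resolution_deg, config$radial_resolution_mm,
    laterality = set$eye, disc_radius_mm = disc / 2))
  summ <- stage("summarize", summarize_map(map, config$stat_extent_mm))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_csv(profiles, file.path(out_dir, "profiles.csv"))
  write_topography(map, file.path(out_dir, "topography.csv"))
  render_map(map, file.path(out_dir, "topography.png"))
  summary_json <- list(pct_avg_um = summ$pct_avg_um,
                       tem_pct_um = summ$tem_pct_um,
                       sector_means_um = as.list(summ$sector_means_um),
                       stat_extent_mm = summ$stat_extent_mm,
                       laterality = summ$laterality,
                       disc_diameter_mm = disc)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("pctopo")),
    inputs = normalizePath(scan_dir),
    qc = list(low_signal_axes = vapply(
      set$scans[vapply(set$scans, function(s) isTRUE(s$low_signal),
                       logical(1L))],
      function(s) s$direction_axis_deg, numeric(1L))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(list(profiles = profiles, map = map, summary = summ,
                 manifest = manifest))
}

#' Run the cohort statistical battery
#'
#' Produces the group-comparison table, the univariate screen, the
#' multivariate PCT-ratio model and prediction-equation diagnostics
#' (observed vs predicted ratio residuals), mirroring the published
#' table layout.  Writes `group_comparisons.csv`, `regression_pct.json`,
#' `regression_bcva.json` and `report.txt` when `out_dir` is given.
#'
#' @param cohort Cohort data.frame (from [read_cohort_csv()] or
#'   [generate_cohort()]).
#' @param out_dir Optional output directory.
#' @param config A [run_config()].
#' @return List with `comparisons`, `pct_model`, `bcva_model`,
#'   `prediction_rmse`.
#' @export
run_cohort <- function(cohort, out_dir = NULL, config = run_config()) {
  d <- augment_cohort(cohort)
  cont <- c("age", "duration_to_treatment", "vf_defect",
            "pct_ratio", "tem_pct_ratio", "rnfl_ratio", "tem_rnfl_ratio")
  comparisons <- do.call(rbind, lapply(cont, function(v) {
    ht <- compare_groups(d, v, kind = "t_test")
    data.frame(variable = v,
               mean_op = mean(d[[v]][d$group == "OP"]),
               mean_rn = mean(d[[v]][d$group == "RN"]),
               statistic = ht$statistic, p_value = ht$p_value)
  }))
  for (v in c("gender", "autoimmune_flag", "brain_mri_flag")) {
    ht <- compare_groups(d, v, kind = "exact")
    comparisons <- rbind(comparisons, data.frame(
      variable = v, mean_op = NA, mean_rn = NA,
      statistic = NA, p_value = ht$p_value))
  }
  candidates <- c("age", "gender", "lesion_eye", "duration_to_treatment",
                  "disc_swelling", "autoimmune_flag", "brain_mri_flag",
                  "refraction_lesion", "refraction_diff", "vf_defect",
                  "rnfl_ratio", "pct_lesion")
  pct_model <- screen_then_fit(d, "pct_ratio", candidates,
                               alpha = config$screening_alpha)
  bcva_candidates <- c("disc_swelling", "age", "gender", "lesion_eye",
                       "autoimmune_flag", "brain_mri_flag",
                       "refraction_lesion", "duration_to_treatment",
                       "vf_defect", "rnfl_ratio", "pct_lesion", "pct_ratio",
                       "tem_pct_ratio")
  bcva_model <- screen_then_fit(d, "bcva_initial_trough", bcva_candidates,
                                alpha = config$screening_alpha)
  pred <- predict_pct_ratio(d$rnfl_ratio, d$disc_swelling,
                            d$refraction_lesion, d$age, d$male)
  prediction_rmse <- sqrt(mean((d$pct_ratio - pred)^2))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparisons,
                     file.path(out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
    dump_model <- function(m, path) {
      jsonlite::write_json(list(outcome = m$outcome,
                                intercept = m$intercept,
                                r_square = m$r_square, n_used = m$n_used,
                                terms = m$terms, screen = m$screen),
                           path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
    dump_model(pct_model, file.path(out_dir, "regression_pct.json"))
    dump_model(bcva_model, file.path(out_dir, "regression_bcva.json"))
    con <- file(file.path(out_dir, "report.txt"), "w")
    sink(con)
    cat("Group comparisons (OP vs RN)\n")
    print(comparisons, row.names = FALSE)
    cat("\nPCT lesion/fellow ratio model\n"); print(pct_model)
    cat("\nTrough BCVA model\n"); print(bcva_model)
    cat(sprintf("\nPrediction-equation RMSE: %.4f\n", prediction_rmse))
    sink(); close(con)
  }
  list(comparisons = comparisons, pct_model = pct_model,
       bcva_model = bcva_model, prediction_rmse = prediction_rmse)
}
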