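#' Run the end-to-end gel verification workflow
#'
#' Chains every stage of the dosimetric verification of a lattice delivery:
#' scan averaging, background subtraction, adaptive mean filtering, remnant
#' artefact removal, tanh self-calibration on the widest-dose-range slice,
#' inversion to dose, and the comparison suite (per-vertex equivalent
#' diameters at the prescription dose, profile peak/valley metrics, and the
#' 12-criteria global gamma sweep). The run is a pure function of its
#' inputs: repeated runs write identical reports.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{plan}{planned dose: a [scalar_volume()] or NRRD/NIfTI path.}
#'     \item{pre_scans, post_scans}{lists of CBCT scans ([scalar_volume()]s
#'       or paths).}
#'     \item{phantom}{gel container mask ([structure_mask()] or path);
#'       used to restrict calibration and gamma evaluation.}
#'     \item{vertices}{planned [vertex_set()] or vertex JSON path.}
#'     \item{prescription}{prescription dose in Gy (> 0).}
#'     \item{filter}{optional list with `mean_window` (default 3) and
#'       `artefact_span` (default 7).}
#'     \item{gamma}{optional list with `dose_percents` (default 1,2,3,5),
#'       `dta_mms` (default 1,2,3), `threshold_percent` (default 10),
#'       `refine` (default 3), `restrict` (`"phantom"` or `"all"`).}
#'     \item{calibration_slice}{`"auto"` (default) or 1-based slice index.}
#'     \item{outdir}{output directory; created if missing. `NULL` skips all
#'       file output.}
#'     \item{write_volumes}{if `TRUE`, also write the calibrated gel dose
#'       volume as NRRD (default `FALSE`).}
#'   }
#' @return The report as a list (also written as `report.json`, `gamma.csv`,
#'   `vertices.csv`, `profile.csv` and `curve.json` under `outdir`).
#' @export
run_verify <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$prescription) || config$prescription <= 0)
    stop("config$prescription must be a positive dose in Gy")

  # resolve and pre-validate file inputs before any computation
  need_file <- function(x, what) {
    if (is.character(x) && !file.exists(x))
      stop(sprintf("[inputs] missing %s file: %s", what, x), call. = FALSE)
    x
  }
  need_file(config$plan, "plan")
  for (p in config$pre_scans) need_file(p, "pre-irradiation scan")
  for (p in config$post_scans) need_file(p, "post-irradiation scan")
  need_file(config$phantom, "phantom mask")
  need_file(config$vertices, "vertices")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  as_vol <- function(x, quantity)
    if (is.character(x)) read_volume(x, quantity = quantity) else x
  fc <- do.call(filter_config, config$filter %||% list())
  gcfg <- config$gamma %||% list()
  dose_percents <- gcfg$dose_percents %||% c(1, 2, 3, 5)
  dta_mms <- gcfg$dta_mms %||% c(1, 2, 3)
  threshold <- gcfg$threshold_percent %||% 10
  refine <- gcfg$refine %||% 3L
  restrict <- gcfg$restrict %||% "phantom"

  plan <- stage("load", as_vol(config$plan, "dose_Gy"))
  phantom <- stage("load", if (is.character(config$phantom))
    read_mask(config$phantom, name = "phantom") else config$phantom)
  vset <- stage("load", if (is.character(config$vertices))
    read_vertices_json(config$vertices) else config$vertices)
  pre <- stage("load", lapply(config$pre_scans, as_vol, quantity = "cbct_number"))
  post <- stage("load", lapply(config$post_scans, as_vol, quantity = "cbct_number"))

  message(sprintf("verify: averaging %d + %d scans", length(pre), length(post)))
  pre_mean <- stage("average", average_volumes(pre))
  post_mean <- stage("average", average_volumes(post))
  delta <- stage("subtract", subtract_background(post_mean, pre_mean))
  message("verify: filtering")
  delta <- stage("filter", adaptive_mean_filter(delta, fc$mean_window))
  delta <- stage("artefact", remove_remnant_artifacts(delta, fc$artefact_span))

  slice <- config$calibration_slice %||% "auto"
  if (identical(slice, "auto")) slice <- select_calibration_slice(plan)
  message(sprintf("verify: self-calibration on slice %d", slice))
  curve <- stage("calibrate", fit_calibration(
    delta$values[, , slice], plan$values[, , slice],
    mask = if (!is.null(phantom)) phantom$values[, , slice] else NULL))
  gel <- stage("dose", apply_calibration(delta, curve))

  message("verify: comparison suite")
  vrep <- stage("diameters",
                vertex_report(plan, gel, vset, level = config$prescription))
  prof_cfg <- config$profile
  if (is.null(prof_cfg)) {
    # default profile: through the closest pair of vertices, extended by a
    # sphere radius at each end so both peaks are interior
    ctr <- vset$centers
    dd <- as.matrix(stats::dist(ctr))
    diag(dd) <- Inf
    ij <- arrayInd(which.min(dd), dim(dd))
    a <- ctr[ij[1], ]; b <- ctr[ij[2], ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    prof_cfg <- list(start = a - u * vset$diameter / 2,
                     end = b + u * vset$diameter / 2, step = 0.5)
  }
  prof <- stage("profile", line_profile(plan, gel,
                                        prof_cfg$start, prof_cfg$end,
                                        prof_cfg$step %||% 0.5))
  valleys <- stage("valleys", list(
    plan = valley_metrics(prof, "volume_max", norm_dose = max(plan$values),
                          rx_gy = config$prescription, which = "ref"),
    gel = valley_metrics(prof, "volume_max", norm_dose = max(gel$values),
                         rx_gy = config$prescription, which = "eval")))
  message("verify: gamma sweep")
  gtab <- stage("gamma", gamma_sweep(
    plan, gel, dose_percents = dose_percents, dta_mms = dta_mms,
    threshold_percent = threshold,
    mask = if (identical(restrict, "phantom")) phantom else NULL,
    refine = refine))

  report <- list(
    parameters = list(prescription_gy = config$prescription,
                      filter = unclass(fc),
                      gamma = list(dose_percents = dose_percents,
                                   dta_mms = dta_mms,
                                   threshold_percent = threshold,
                                   refine = refine, restrict = restrict),
                      calibration_slice = slice,
                      n_pre_scans = length(pre), n_post_scans = length(post),
                      software = paste0("latticeqa ",
                                        as.character(utils::packageVersion("latticeqa")))),
    calibration = list(alpha = curve$alpha, beta = curve$beta,
                       gamma = curve$gamma_, phi = curve$phi,
                       rmse = curve$rmse, dose_range_gy = curve$dose_range,
                       clamped_fraction = attr(gel, "clamped_fraction"),
                       negative_fraction = attr(gel, "negative_fraction")),
    vertices = vrep,
    valleys = list(
      plan_percent = valleys$plan$valleys$percent,
      gel_percent = valleys$gel$valleys$percent,
      plan_widths_mm = valleys$plan$widths_mm,
      gel_widths_mm = valleys$gel$widths_mm),
    gamma = gtab)

  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    utils::write.csv(gtab, file.path(outdir, "gamma.csv"), row.names = FALSE)
    utils::write.csv(vrep$table, file.path(outdir, "vertices.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(position_mm = prof$positions,
                                ref_Gy = prof$ref_values,
                                eval_Gy = prof$eval_values),
                     file.path(outdir, "profile.csv"), row.names = FALSE)
    write_calibration_json(curve, file.path(outdir, "curve.json"))
    if (isTRUE(config$write_volumes))
      write_volume(gel, file.path(outdir, "gel_dose.nrrd"))
  }
  invisible(report)
}
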