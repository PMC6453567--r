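# allowed configuration schema: names and (recursively) sub-names
pipeline_schema <- function() {
  list(
    seed = NULL,
    stages = NULL,
    units = list(pressure = NULL),
    log_level = NULL,
    synth = list(lambda = NULL, R_f = NULL, size = NULL, pixel_size = NULL,
                 amplitude = NULL, noise_sd = NULL,
                 gr_true = NULL, ratios = NULL, noise_sigma = NULL),
    theory = list(ratios = NULL, gr_over_gf = NULL, hr_over_hf = NULL,
                  slope_window = NULL),
    fit = list(bracket = NULL, hr_over_hf = NULL),
    fem = list(gf_over_gs = NULL, gr_over_gf = NULL, g_max = NULL,
               steps_after_onset = NULL, elements_per_hf = NULL,
               aspect = NULL, L = NULL)
  )
}

check_keys <- function(cfg, schema, path = "") {
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    abort(sprintf("Unknown configuration key%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")),
          class = "biofilmorph_config_error")
  for (nm in names(cfg)) {
    if (is.list(schema[[nm]]) && is.list(cfg[[nm]]))
      check_keys(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Checks a (possibly nested) configuration list against the pipeline
#' schema; unknown keys are rejected by name. Configurations round-trip
#' unchanged through YAML serialisation.
#'
#' @param config A named list, e.g. from [yaml::read_yaml()].
#' @return The validated config (with defaults filled), invisibly classed as
#'   `pipeline_config`.
#' @export
validate_config <- function(config) {
  check_keys(config, pipeline_schema())
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("synth", "metrics", "theory")
  known <- c("synth", "metrics", "theory", "fem")
  if (!all(config$stages %in% known))
    abort(sprintf("Unknown stage: %s",
                  paste(setdiff(config$stages, known), collapse = ", ")),
          class = "biofilmorph_config_error")
  config$units <- config$units %||% list(pressure = "Pa")
  structure(config, class = c("pipeline_config", "list"))
}

#' Default demonstration configuration
#'
#' @param seed Root seed for all stages.
#' @return A validated `pipeline_config` running the synthetic, metrics and
#'   theory stages at small problem sizes.
#' @export
demo_config <- function(seed = 1L) {
  validate_config(list(
    seed = seed,
    stages = c("synth", "metrics", "theory"),
    synth = list(lambda = 1, R_f = 5, size = 384L, pixel_size = 0.03,
                 amplitude = 0.12, noise_sd = 0.03,
                 gr_true = 0.1, ratios = 10^seq(-1.5, 1, length.out = 8),
                 noise_sigma = 0.05),
    theory = list(ratios = 10^seq(-1.5, 3, length.out = 12),
                  gr_over_gf = 0.1, hr_over_hf = 0.3,
                  slope_window = c(10, 1000)),
    fit = list(bracket = c(1e-3, 1))
  ))
}

#' Write a pipeline table
#'
#' CSV writer with the pipeline conventions: fixed column order as given,
#' numeric columns rounded to 6 significant digits, no quoting. Writing an
#' empty table produces a headers-only file.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param pressure_unit `"Pa"` (default) or `"kPa"`: columns whose names end
#'   in `_Pa` are rescaled and renamed to `_kPa`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, pressure_unit = "Pa") {
  df <- as.data.frame(df)
  if (pressure_unit == "kPa") {
    pa <- grep("_Pa$", names(df))
    for (j in pa) df[[j]] <- df[[j]] / 1000
    names(df)[pa] <- sub("_Pa$", "_kPa", names(df)[pa])
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on seeded synthetic inputs:
#' `synth` generates a striped colony image and a noisy
#' wavelength-versus-stiffness dataset; `metrics` runs segmentation, ring
#' counting and the wavelength fit on the image; `theory` computes a
#' wavelength scan, its log-log slope, and fits the residual-layer stiffness
#' to the synthetic dataset; `fem` (off by default) runs a reduced growth
#' simulation. All outputs are written to `out_dir` as CSV/JSON plus a
#' Markdown report; rerunning with the same seed gives byte-identical
#' tables.
#'
#' @param config A `pipeline_config` (see [validate_config()],
#'   [demo_config()]).
#' @param out_dir Output directory, created if needed.
#' @return A list (invisible): `report` (named results) and `files` written.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  report <- list(package_version = as.character(utils::packageVersion("biofilmorph")),
                 seed = config$seed,
                 config_hash = rlang::hash(unclass(config)),
                 stages = config$stages)
  punit <- config$units$pressure %||% "Pa"

  scene <- NULL
  stiff <- NULL
  if ("synth" %in% config$stages) {
    sy <- config$synth
    scene <- gen_radial_pattern_image(
      lambda = sy$lambda, R_f = sy$R_f, size = sy$size %||% 384L,
      pixel_size = sy$pixel_size, amplitude = sy$amplitude %||% 0.1,
      noise_sd = sy$noise_sd %||% 0, seed = config$seed)
    stiff <- gen_stiffness_dataset(
      gr_true = sy$gr_true %||% 0.1, ratios = sy$ratios,
      noise_sigma = sy$noise_sigma %||% 0, seed = config$seed + 1L)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(image = scene$truth, stiffness = stiff$truth),
                         truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  }

  if ("metrics" %in% config$stages) {
    if (is.null(scene)) abort("`metrics` stage requires the `synth` stage.",
                              class = "biofilmorph_config_error")
    frame <- normalize_and_segment(scene$image,
                                   pixel_size = scene$truth$pixel_size,
                                   timestamp = 12)
    ctr <- colony_center(list(frame))
    ps <- scene$truth$pixel_size
    radii <- seq(0.4, 0.85, length.out = 6) * scene$truth$R_f
    counts <- purrr::map(radii, function(r)
      count_ring_features(frame$image, ctr, r, pixel_size = ps))
    wl_samples <- tibble(
      r = radii, t = 12,
      N = vapply(counts, function(cc) if (is.na(cc$N)) 0L else cc$N, 0L),
      flagged = vapply(counts, `[[`, TRUE, "flagged"))
    wfit <- fit_wavelength(wl_samples)
    cm <- mask_metrics(frame$mask, pixel_size = ps)
    f1 <- write_table(wl_samples, file.path(out_dir, "wavelength.csv"))
    f2 <- write_table(dplyr::mutate(cm, t_hr = 12, .before = 1),
                      file.path(out_dir, "contour_metrics.csv"))
    files <- c(files, f1, f2)
    report$metrics <- list(lambda_fitted = wfit$lambda, alpha = cm$alpha,
                           R_f = cm$R_f)
  }

  if ("theory" %in% config$stages) {
    th <- config$theory
    scan <- wrinkle_scan(th$ratios, gr_over_gf = th$gr_over_gf %||% 0.1,
                         hr_over_hf = th$hr_over_hf %||% 0.3)
    f1 <- write_table(scan, file.path(out_dir, "scan.csv"))
    files <- c(files, f1)
    sw <- th$slope_window %||% c(10, 1000)
    in_win <- sum(scan$converged & scan$gf_over_gs >= sw[1] &
                    scan$gf_over_gs <= sw[2])
    report$theory <- list(
      slope = if (in_win >= 5) scan_slope(scan, sw)$slope else NA_real_)
    if (!is.null(stiff)) {
      fit <- fit_residual_stiffness(stiff$data,
                                    hr_over_hf = config$fit$hr_over_hf %||% 0.3,
                                    bracket = config$fit$bracket %||% c(1e-3, 1))
      fit_path <- file.path(out_dir, "fit.json")
      jsonlite::write_json(list(gr_over_gf = fit$gr_over_gf, sse = fit$sse,
                                boundary = fit$boundary, method = fit$method),
                           fit_path, auto_unbox = TRUE, digits = NA)
      files <- c(files, fit_path)
      report$fit <- list(gr_over_gf = fit$gr_over_gf)
    }
  }

  if ("fem" %in% config$stages) {
    fm <- config$fem %||% list()
    cfg <- fem_config(gf_over_gs = fm$gf_over_gs %||% 10,
                      gr_over_gf = fm$gr_over_gf %||% 0.1,
                      g_max = fm$g_max %||% 0.3,
                      steps_after_onset = fm$steps_after_onset %||% 12,
                      elements_per_hf = fm$elements_per_hf %||% 4L,
                      aspect = fm$aspect %||% 16, L = fm$L,
                      seed = config$seed)
    sim <- run_growth(cfg)
    f1 <- write_table(sim$trajectory, file.path(out_dir, "trajectory.csv"))
    f2 <- write_table(surface_profile(sim), file.path(out_dir, "final_surface.csv"))
    files <- c(files, f1, f2)
    report$fem <- list(onset_strain = sim$onset_strain,
                       lambda = measure_surface_wavelength(sim)$lambda)
  }

  report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA)
  md <- c("# biofilmorph pipeline report", "",
          sprintf("- package version: %s", report$package_version),
          sprintf("- seed: %d", report$seed),
          sprintf("- config hash: %s", report$config_hash),
          sprintf("- stages: %s", paste(report$stages, collapse = ", ")),
          sprintf("- outputs: %s", paste(basename(files), collapse = ", ")))
  report_md <- file.path(out_dir, "report.md")
  writeLines(md, report_md)
  invisible(list(report = report, files = c(files, report_json, report_md)))
}
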