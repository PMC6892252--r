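#' Write a fitted encoding scheme to JSON
#'
#' Serializes an [oes()] fit (or a single solution) with units carried in the
#' key names: spatial frequency in cycles/mm, phases in rad, blip areas in
#' mT ms/m.
#'
#' @param fit an [oes()] fit or an `"encoding_solution"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(fit, path) {
  sol_to_list <- function(s, vessels) {
    list(k_cycles_per_mm = s$k, phi0_rad = s$phi0,
         blip_area_mT_ms_per_m = s$blip_area,
         rf_increment_rad = s$rf_increment, score = s$score,
         phase_error_rad = as.list(stats::setNames(s$phase_error,
                                                   vessels$name)))
  }
  obj <- if (inherits(fit, "oes")) {
    list(scheme = fit$scheme_kind,
         vessels = as.data.frame(unclass(fit$vessels)),
         psi_rad = fit$psi,
         config = list(pad_size = fit$config$pad_size,
                       base_resolution_mm = fit$config$base_resolution,
                       max_motion_mm = fit$config$max_motion,
                       weighting = fit$config$weighting),
         cycles = lapply(fit$solutions, sol_to_list, vessels = fit$vessels))
  } else if (inherits(fit, "encoding_solution")) {
    list(cycles = list(sol_to_list(fit, fit$vessels)))
  } else stop("fit must be an 'oes' fit or an 'encoding_solution'")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a solution JSON back into solution objects
#'
#' @param path JSON path written by [write_solution()].
#' @return A list with `scheme`, `vessels` ([vessel_set()] when present),
#'   `psi_rad` and `cycles` (each with `k`, `phi0`, `blip_area`,
#'   `rf_increment`, `score`).
#' @export
read_solution <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cycles <- lapply(obj$cycles, function(s)
    list(k = as.numeric(s$k_cycles_per_mm), phi0 = s$phi0_rad,
         blip_area = as.numeric(s$blip_area_mT_ms_per_m),
         rf_increment = s$rf_increment_rad, score = s$score))
  vessels <- if (!is.null(obj$vessels))
    vessel_set(obj$vessels$name, obj$vessels$x_mm, obj$vessels$y_mm,
               obj$vessels$psi_rad)
  list(scheme = obj$scheme, vessels = vessels, psi_rad = obj$psi_rad,
       cycles = cycles)
}

# rebuild a minimal encoding_solution from a deserialized cycle
solution_from_list <- function(cycle, vessels = NULL,
                               config = oes_config()) {
  structure(list(k = cycle$k, phi0 = cycle$phi0, score = cycle$score,
                 theta = NULL, phase_error = NULL,
                 blip_area = cycle$blip_area,
                 rf_increment = cycle$rf_increment,
                 vessels = vessels, config = config, method = "direct"),
            class = "encoding_solution")
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [study_config()]
#' arguments (`n_arrangements`, `perturb_sd`, `scale_levels`,
#' `base_max_offset`, `seed`, `schemes`, `linear_frac`); a `vessels` key may
#' hold an inline table with `name`, `x_mm`, `y_mm` fields.
#'
#' @param path YAML path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("n_arrangements", "perturb_sd", "scale_levels",
                        "base_max_offset", "seed", "schemes", "linear_frac"))]
  if (!is.null(y$vessels)) {
    vdf <- as.data.frame(do.call(rbind, lapply(y$vessels, as.data.frame)))
    args$base_vessels <- vessel_set(vdf$name, vdf$x_mm, vdf$y_mm,
                                    if (is.null(vdf$psi_rad)) 0 else vdf$psi_rad)
  }
  if (!is.null(args$scale_levels)) args$scale_levels <- unlist(args$scale_levels)
  if (!is.null(args$schemes)) args$schemes <- unlist(args$schemes)
  do.call(study_config, args)
}

#' Write study results to CSV
#'
#' @param study an `"oes_study"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_results <- function(study, path) {
  stopifnot(inherits(study, "oes_study"))
  utils::write.csv(study$results, path, row.names = FALSE)
  invisible(path)
}

#' Write an inversion response to JSON
#'
#' @param response an [inversion_response()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_response <- function(response, path) {
  stopifnot(inherits(response, "inversion_response"))
  p <- response$params
  jsonlite::write_json(list(
    phases_rad = response$phases, mz = response$mz,
    velocities_m_per_s = response$velocities, weights = response$weights,
    params = list(flip_angle_deg = p$flip_angle,
                  rf_duration_s = p$rf_duration,
                  rf_interval_s = p$rf_interval,
                  g_select_mT_per_m = p$g_select,
                  g_mean_mT_per_m = p$g_mean,
                  gyromagnetic_ratio_Hz_per_mT = p$gyromagnetic_ratio)),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
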