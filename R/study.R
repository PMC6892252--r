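#' Simulation-study configuration
#'
#' Conditions of the Monte-Carlo efficiency study: perturbed four-vessel
#' arrangements in synthetic linear+quadratic fieldmaps whose offsets are
#' swept over increasing scale multipliers, with three scenarios per
#' arrangement and scale — no offsets, offsets present but ignored in the
#' design, and offsets corrected in the design.
#'
#' @param n_arrangements number of randomly perturbed vessel arrangements.
#' @param perturb_sd per-coordinate perturbation SD, mm.
#' @param scale_levels fieldmap scale multipliers.
#' @param base_max_offset max |psi| at the base vessels at scale 1, rad.
#' @param seed RNG seed for the arrangements.
#' @param base_vessels base vessel geometry.
#' @param schemes schemes to simulate.
#' @param linear_frac fieldmap linear/quadratic split, see [synth_fieldmap()].
#' @param fieldmap_shape,fieldmap_voxel fieldmap grid geometry.
#' @param config an [oes_config()].
#' @param params a [pulse_train()].
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_arrangements = 20, perturb_sd = 2,
                         scale_levels = 1:20, base_max_offset = 1.2,
                         seed = 1, base_vessels = neck_vessels(),
                         schemes = c("pcasl", "vepcasl"),
                         linear_frac = 0.5,
                         fieldmap_shape = c(161, 161), fieldmap_voxel = 1,
                         config = oes_config(), params = pulse_train()) {
  stopifnot(n_arrangements >= 1, perturb_sd >= 0, length(scale_levels) >= 1)
  schemes <- match.arg(schemes, several.ok = TRUE)
  structure(list(n_arrangements = as.integer(n_arrangements),
                 perturb_sd = perturb_sd, scale_levels = scale_levels,
                 base_max_offset = base_max_offset, seed = as.integer(seed),
                 base_vessels = base_vessels, schemes = schemes,
                 linear_frac = linear_frac, fieldmap_shape = fieldmap_shape,
                 fieldmap_voxel = fieldmap_voxel, config = config,
                 params = params),
            class = "study_config")
}

#' Run the off-resonance efficiency study
#'
#' For every arrangement and fieldmap scale, designs encodings under the
#' three scenarios and evaluates the achieved SNR-efficiency against the
#' *true* offsets:
#' \describe{
#'   \item{no_offsets}{psi = 0 in design and evaluation. Independent of the
#'     fieldmap scale, so recorded once per arrangement (scale `NA`).}
#'   \item{uncorrected}{design assumes psi = 0, evaluation uses the true
#'     sampled psi.}
#'   \item{corrected}{the true psi enters the desired phases of the design,
#'     and evaluation uses the same true psi.}
#' }
#' The fieldmap coefficients are normalized against the base (unperturbed)
#' vessel geometry, so the perturbed arrangements see offsets up to
#' approximately `base_max_offset * scale`.
#'
#' @param config a [study_config()].
#' @param response an [inversion_response()] (computed, and cached, from
#'   `config$params` when `NULL`).
#' @param progress print progress.
#' @return An object of class `"oes_study"`: list with `results` (long data
#'   frame: scheme, scenario, scale, arrangement, vessel, efficiency),
#'   `config`, `response`. See [summary.oes_study()].
#' @export
run_scenarios <- function(config = study_config(), response = NULL,
                          progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(response)) response <- inversion_response(config$params)
  set.seed(config$seed)
  arrangements <- lapply(seq_len(config$n_arrangements), function(i)
    perturb_vessels(config$base_vessels, config$perturb_sd))
  maps <- lapply(config$scale_levels, function(s)
    synth_fieldmap(config$base_vessels, shape = config$fieldmap_shape,
                   voxel_size = config$fieldmap_voxel, scale = s,
                   base_max_offset = config$base_max_offset,
                   linear_frac = config$linear_frac))
  vnames <- config$base_vessels$name
  rows <- list()
  add <- function(scheme, scenario, scale, arr, eff) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scheme = scheme, scenario = scenario, scale = scale, arrangement = arr,
      vessel = vnames, efficiency = unname(eff$per_vessel),
      stringsAsFactors = FALSE)
  }
  eff_of <- function(fit, psi_true) {
    snr_efficiency(fit, response, psi = psi_true)
  }
  for (a in seq_len(config$n_arrangements)) {
    va <- arrangements[[a]]
    pos <- vessel_positions(va)
    for (scheme in config$schemes) {
      fit0 <- oes(va, scheme, psi = 0, config = config$config,
                  params = config$params)
      add(scheme, "no_offsets", NA_real_, a, eff_of(fit0, rep(0, nrow(va))))
      for (s in seq_along(config$scale_levels)) {
        psi_true <- sample_psi(maps[[s]], pos)
        add(scheme, "uncorrected", config$scale_levels[s], a,
            eff_of(fit0, psi_true))
        fitc <- oes(va, scheme, psi = psi_true, config = config$config,
                    params = config$params)
        add(scheme, "corrected", config$scale_levels[s], a,
            eff_of(fitc, psi_true))
      }
    }
    if (progress)
      message(sprintf("arrangement %d/%d done", a, config$n_arrangements))
  }
  structure(list(results = do.call(rbind, rows), config = config,
                 response = response),
            class = "oes_study")
}

#' @export
print.oes_study <- function(x, ...) {
  cat(sprintf("Off-resonance efficiency study: %d arrangements x %d scales, schemes %s\n",
              x$config$n_arrangements, length(x$config$scale_levels),
              paste(x$config$schemes, collapse = ", ")))
  print(summary(x)$table)
  invisible(x)
}

# per (scheme, scenario, scale, arrangement) mean efficiency across vessels
cell_means <- function(results) {
  stats::aggregate(efficiency ~ scheme + scenario + arrangement + scale,
                   data = transform(results,
                                    scale = ifelse(is.na(scale), 0, scale)),
                   FUN = mean)
}

#' Summarize an efficiency study
#'
#' Pools the vessel-averaged efficiencies across all fieldmap scales and
#' arrangements per scheme and scenario (mean and SD), and reports paired
#' two-sided t-tests between scenarios, pairing by arrangement (scenario
#' means are averaged over scales first, since the no-offset scenario has no
#' scale axis).
#'
#' @param object an [run_scenarios()] result.
#' @param ... unused.
#' @return A list of class `"summary.oes_study"` with `table` (scheme x
#'   scenario means +/- SD) and `tests` (paired t-test p-values).
#' @export
summary.oes_study <- function(object, ...) {
  cm <- cell_means(object$results)
  tab <- stats::aggregate(efficiency ~ scheme + scenario, data = cm,
                          FUN = function(z) c(mean = mean(z), sd = stats::sd(z),
                                              n = length(z)))
  tab <- cbind(tab[c("scheme", "scenario")], as.data.frame(tab$efficiency))
  tab$sd[is.na(tab$sd)] <- 0
  # pair scenarios by arrangement (average over scales within arrangement)
  bya <- stats::aggregate(efficiency ~ scheme + scenario + arrangement,
                          data = cm, FUN = mean)
  tests <- list()
  for (scheme in unique(bya$scheme)) {
    sub <- bya[bya$scheme == scheme, ]
    sc <- unique(sub$scenario)
    for (i in seq_along(sc)) for (j in seq_along(sc)) {
      if (i >= j) next
      a <- sub$efficiency[sub$scenario == sc[i]][order(sub$arrangement[sub$scenario == sc[i]])]
      b <- sub$efficiency[sub$scenario == sc[j]][order(sub$arrangement[sub$scenario == sc[j]])]
      p <- if (stats::sd(a - b) == 0) NA_real_
           else stats::t.test(a, b, paired = TRUE)$p.value
      tests[[paste(scheme, sc[i], "vs", sc[j])]] <- p
    }
  }
  structure(list(table = tab, tests = unlist(tests)),
            class = "summary.oes_study")
}

#' @export
print.summary.oes_study <- function(x, ...) {
  cat("Pooled SNR-efficiency (mean +/- SD across arrangements and scales):\n")
  df <- x$table
  df$summary <- sprintf("%.3f +/- %.3f (n=%d)", df$mean, df$sd, df$n)
  print(df[c("scheme", "scenario", "summary")], row.names = FALSE)
  if (length(x$tests)) {
    cat("\nPaired t-tests (by arrangement):\n")
    for (nm in names(x$tests))
      cat(sprintf("  %s: p = %s\n", nm,
                  if (is.na(x$tests[[nm]])) "NA (zero variance)"
                  else format.pval(x$tests[[nm]], digits = 3)))
  }
  invisible(x)
}

#' Bar chart of study results
#'
#' Mean SNR-efficiency per scheme and scenario with SD error bars, the
#' standard summary figure of the study.
#'
#' @param x an `"oes_study"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.oes_study <- function(x, ...) {
  tab <- summary(x)$table
  scen <- c("no_offsets", "uncorrected", "corrected")
  schemes <- unique(tab$scheme)
  m <- sapply(schemes, function(s)
    tab$mean[match(paste(s, scen), paste(tab$scheme, tab$scenario))])
  sds <- sapply(schemes, function(s)
    tab$sd[match(paste(s, scen), paste(tab$scheme, tab$scenario))])
  bp <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1.05),
                          names.arg = toupper(schemes),
                          legend.text = c("no offsets", "uncorrected",
                                          "corrected"),
                          ylab = "SNR-efficiency",
                          args.legend = list(x = "topright", bty = "n"), ...)
  nz <- sds > 0  # zero-length error bars (the no-offset PCASL case) drawn as none
  if (any(nz))
    graphics::arrows(bp[nz], (m - sds)[nz], bp[nz], (m + sds)[nz],
                     angle = 90, code = 3, length = 0.04)
  invisible(bp)
}
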