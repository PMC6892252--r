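#' Fit an optimized encoding scheme
#'
#' The main entry point: given vessel locations in the labeling plane and
#' per-vessel phase offsets (from a fieldmap of the plane, or zero), designs
#' the full set of encoding cycles for conventional PCASL or Hadamard
#' vessel-encoded PCASL. For every cycle of the ideal scheme the desired
#' per-vessel phases (ideal condition phase minus the local offset psi) are
#' matched by the Fourier-space search of [optimize_encoding()], and the
#' winning spatial frequency and phase are converted to unipolar transverse
#' gradient blip areas and an RF phase increment by [to_hardware()].
#'
#' Phase offsets are resolved in priority order: `psi` argument, then
#' `fieldmap` (sampled at the vessel centres), then the `psi_rad` column of
#' `vessels`.
#'
#' @param vessels a [vessel_set()].
#' @param scheme `"pcasl"` (2 cycles) or `"vepcasl"` (Hadamard).
#' @param psi optional per-vessel phase offsets, rad per RF interval.
#' @param fieldmap optional [phase_offset_map()] to sample psi from.
#' @param config an [oes_config()].
#' @param params a [pulse_train()] (for the hardware conversion).
#' @param method optimizer evaluation path, see [optimize_encoding()].
#' @return An object of class `"oes"`: list with `vessels`, `psi` (the
#'   offsets used in the design), `scheme` (the ideal +/-1 matrix),
#'   `solutions` (one [optimize_encoding()]/[to_hardware()] solution per
#'   cycle), `config`, `params`, `call`. Methods: `print`, `summary`, `coef`
#'   (hardware parameters per cycle), `residuals` (per-cycle, per-vessel
#'   phase errors), `fitted` (achieved magnetization), `predict`, `plot`.
#' @examples
#' \donttest{
#' v <- neck_vessels()
#' fit <- oes(v, "vepcasl", psi = c(0.5, -0.2, 0.1, 0.8))
#' coef(fit)
#' residuals(fit)
#' }
#' @export
oes <- function(vessels, scheme = c("pcasl", "vepcasl"), psi = NULL,
                fieldmap = NULL, config = oes_config(),
                params = pulse_train(), method = "direct") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(vessels, "vessel_set"))
  n <- nrow(vessels)
  if (is.null(psi)) {
    psi <- if (!is.null(fieldmap))
      sample_psi(fieldmap, vessel_positions(vessels))
    else vessels$psi_rad
  }
  if (length(psi) == 1) psi <- rep(psi, n)
  stopifnot(length(psi) == n)
  sch <- ideal_scheme(scheme, n)
  solutions <- lapply(seq_len(nrow(sch)), function(c) {
    theta <- desired_phases(sch[c, ], vessels, psi = psi)
    to_hardware(optimize_encoding(vessels, theta, config, method = method),
                params)
  })
  names(solutions) <- rownames(sch)
  structure(list(vessels = vessels, psi = psi, scheme_kind = scheme,
                 scheme = sch, solutions = solutions, config = config,
                 params = params, call = match.call()),
            class = "oes")
}

#' @export
print.oes <- function(x, ...) {
  cat(sprintf("Optimized encoding scheme: %s, %d vessels, %d cycles\n",
              toupper(x$scheme_kind), nrow(x$vessels), length(x$solutions)))
  cat(sprintf("  design phase offsets (rad): %s\n",
              paste(sprintf("%s %+.3f", x$vessels$name, wrap_phase(x$psi)),
                    collapse = ", ")))
  cat(sprintf("  max |phase error| over cycles and vessels: %.4f rad\n",
              max(abs(residuals(x)))))
  invisible(x)
}

#' @export
coef.oes <- function(object, ...) {
  t(vapply(object$solutions, function(s)
    c(kx = s$k[1], ky = s$k[2], phi0 = s$phi0,
      blip_x = s$blip_area[1], blip_y = s$blip_area[2],
      rf_increment = s$rf_increment, score = s$score),
    numeric(7)))
}

#' @export
residuals.oes <- function(object, ...) {
  r <- t(vapply(object$solutions, function(s) s$phase_error,
                numeric(nrow(object$vessels))))
  dimnames(r) <- list(names(object$solutions), object$vessels$name)
  r
}

#' Achieved magnetization of a fitted scheme
#'
#' @param object an [oes()] fit.
#' @param response an [inversion_response()] (defaults to the response of the
#'   fit's pulse train).
#' @param psi true phase offsets to evaluate under (defaults to the design
#'   offsets).
#' @param ... unused.
#' @return Cycles x vessels Mz/M0 matrix.
#' @export
fitted.oes <- function(object, response = NULL, psi = NULL, ...) {
  if (is.null(response)) response <- inversion_response(object$params)
  achieved_magnetization(object$solutions, object$vessels, response,
                         psi = if (is.null(psi)) object$psi else psi)
}

#' Predict encoding phase or magnetization at plane positions
#'
#' @param object an [oes()] fit.
#' @param newdata data frame or matrix with columns/cols `x_mm`, `y_mm`
#'   (defaults to the fitted vessel positions).
#' @param cycle cycle index (default 1).
#' @param type `"phase"` for the applied per-interval phase (rad, wrapped) or
#'   `"mz"` for the magnetization state (requires `response`).
#' @param response an [inversion_response()] for `type = "mz"`.
#' @param psi phase offsets at the queried positions added before the
#'   response lookup (default 0: the applied encoding alone).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.oes <- function(object, newdata = NULL, cycle = 1,
                        type = c("phase", "mz"), response = NULL, psi = 0,
                        ...) {
  type <- match.arg(type)
  pos <- if (is.null(newdata)) vessel_positions(object$vessels)
         else if (is.data.frame(newdata)) cbind(newdata$x_mm, newdata$y_mm)
         else rbind(newdata)
  s <- object$solutions[[cycle]]
  phase <- 2 * pi * as.vector(pos %*% s$k) + s$phi0 + psi
  if (type == "phase") return(wrap_phase(phase))
  if (is.null(response)) response <- inversion_response(object$params)
  eval_response(response, phase)
}

#' Summarize a fitted encoding scheme
#'
#' @param object an [oes()] fit.
#' @param response optional [inversion_response()]; when supplied (or
#'   computable from the fit's pulse train) the achieved magnetization and
#'   SNR-efficiency under the design offsets are reported.
#' @param ... unused.
#' @return An object of class `"summary.oes"`.
#' @export
summary.oes <- function(object, response = NULL, ...) {
  if (is.null(response)) response <- inversion_response(object$params)
  m <- fitted(object, response = response)
  eff <- if (object$scheme_kind == "pcasl") snr_efficiency_pcasl(m)
         else snr_efficiency_vepcasl(m)
  structure(list(fit = object, coef = coef(object),
                 residuals = residuals(object), magnetization = m,
                 efficiency = eff),
            class = "summary.oes")
}

#' @export
print.summary.oes <- function(x, ...) {
  print(x$fit)
  cat("\nPer-cycle hardware parameters:\n")
  print(round(x$coef, 5))
  cat("\nPhase errors at vessels (rad):\n")
  print(round(x$residuals, 4))
  cat("\nAchieved magnetization (Mz/M0):\n")
  print(round(x$magnetization, 3))
  cat("\n")
  print(x$efficiency)
  invisible(x)
}

#' Plot the encoding map of one cycle
#'
#' @param x an [oes()] fit.
#' @param cycle cycle index.
#' @param response optional [inversion_response()].
#' @param psi_map optional [phase_offset_map()] of true offsets to fold into
#'   the map.
#' @param ... passed to [plot.encoding_map()].
#' @export
plot.oes <- function(x, cycle = 1, response = NULL, psi_map = NULL, ...) {
  if (is.null(response)) response <- inversion_response(x$params)
  em <- encoding_map(x$solutions[[cycle]], response, psi_map = psi_map)
  plot(em, vessels = x$vessels,
       main = sprintf("%s %s", toupper(x$scheme_kind),
                      names(x$solutions)[cycle]), ...)
  invisible(em)
}

#' SNR-efficiency of a fitted scheme
#'
#' Convenience wrapper: evaluates the achieved magnetization under given true
#' offsets and applies the scheme-appropriate SNR-efficiency formula.
#'
#' @param object an [oes()] fit.
#' @param response an [inversion_response()].
#' @param psi true phase offsets at the vessels (defaults to design offsets).
#' @param scenario optional label.
#' @return An `"efficiency_report"`.
#' @export
snr_efficiency <- function(object, response, psi = NULL, scenario = NULL) {
  stopifnot(inherits(object, "oes"))
  m <- achieved_magnetization(object$solutions, object$vessels, response,
                              psi = if (is.null(psi)) object$psi else psi)
  if (object$scheme_kind == "pcasl") snr_efficiency_pcasl(m, scenario)
  else snr_efficiency_vepcasl(m, scenario = scenario)
}
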