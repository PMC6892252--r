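#' Achieved magnetization at the vessels
#'
#' Predicts the longitudinal magnetization state of blood in each vessel after
#' each encoding cycle: the net per-interval phase at vessel j under cycle c
#' is the applied encoding phase `2 pi k_c . r_j + phi0_c` plus the true
#' off-resonance offset `psi_j`, looked up in the Bloch-simulated inversion
#' response.
#'
#' @param solutions a list of [optimize_encoding()] solutions (one per cycle)
#'   or an [oes()] fit.
#' @param vessels a [vessel_set()] giving the true vessel positions.
#' @param response an [inversion_response()].
#' @param psi true phase offsets at the vessels, rad (defaults to
#'   `vessels$psi_rad`).
#' @return A cycles x vessels matrix of Mz/M0 values in \[-1, 1\].
#' @export
achieved_magnetization <- function(solutions, vessels, response, psi = NULL) {
  if (inherits(solutions, "oes")) solutions <- solutions$solutions
  if (inherits(solutions, "encoding_solution")) solutions <- list(solutions)
  stopifnot(inherits(vessels, "vessel_set"),
            inherits(response, "inversion_response"))
  if (is.null(psi)) psi <- vessels$psi_rad
  if (length(psi) == 1) psi <- rep(psi, nrow(vessels))
  stopifnot(length(psi) == nrow(vessels))
  pos <- vessel_positions(vessels)
  m <- t(vapply(solutions, function(s) {
    phase <- 2 * pi * as.vector(pos %*% s$k) + s$phi0 + psi
    eval_response(response, phase)
  }, numeric(nrow(vessels))))
  dimnames(m) <- list(NULL, vessels$name)
  m
}

new_efficiency_report <- function(per_vessel, scenario) {
  if (any(per_vessel > 1 + 1e-9))
    warning("SNR-efficiency above 1 computed; this indicates a formula ",
            "regression")
  structure(list(per_vessel = per_vessel, mean = mean(per_vessel),
                 scenario = scenario),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("SNR-efficiency (%s): mean %.3f\n",
              if (is.null(x$scenario)) "unlabelled" else x$scenario, x$mean))
  print(round(x$per_vessel, 3))
  invisible(x)
}

#' PCASL SNR-efficiency
#'
#' For a conventional 2-cycle (label/control) experiment the SNR-efficiency
#' per vessel is the achieved label-control magnetization difference
#' normalized by the ideal difference of twice the equilibrium magnetization:
#' `(m_control - m_label) / 2`, averaged across vessels.
#'
#' @param m a 2 x vessels magnetization matrix (rows: label, control), e.g.
#'   from [achieved_magnetization()].
#' @param scenario optional scenario label.
#' @return An `"efficiency_report"` with `per_vessel` and `mean`.
#' @export
snr_efficiency_pcasl <- function(m, scenario = NULL) {
  m <- rbind(m)
  if (nrow(m) != 2)
    stop("PCASL efficiency requires exactly 2 cycles (label, control)")
  new_efficiency_report((m[2, ] - m[1, ]) / 2, scenario)
}

#' VEPCASL SNR-efficiency
#'
#' SNR-efficiency of a multi-cycle vessel-encoded experiment, from the
#' least-squares decoding of the cycles x vessels magnetization matrix. The
#' design matrix is augmented with a static-tissue column of ones,
#' `G = [m | 1]`, and the per-vessel efficiency is
#' `1 / (sqrt(N) * sqrt([(G'G)^-1]_jj))` with N the cycle count — the
#' per-unit-time precision of the decoded vessel signal relative to a full
#' label/control experiment on that vessel alone. For the ideal +/-1 Hadamard
#' design this equals 1 for every vessel (vessel-encoding carries no SNR
#' penalty), and for a 2-cycle all-label/all-control design on one vessel it
#' reduces exactly to the PCASL formula `(c - l)/2`.
#'
#' @param m a cycles x vessels magnetization matrix (cycles >= 2).
#' @param static_column include the static-tissue column (default `TRUE`).
#' @param scenario optional scenario label.
#' @return An `"efficiency_report"`. A rank-deficient design (e.g. two
#'   vessels with identical magnetization patterns) yields efficiency 0 with
#'   a warning.
#' @export
snr_efficiency_vepcasl <- function(m, static_column = TRUE, scenario = NULL) {
  m <- rbind(m)
  nv <- ncol(m)
  n <- nrow(m)
  if (n < 2) stop("VEPCASL efficiency requires at least 2 cycles")
  g <- if (static_column) cbind(m, 1) else m
  gtg <- crossprod(g)
  inv <- tryCatch(solve(gtg), error = function(e) NULL)
  if (is.null(inv)) {
    warning("degenerate encoding: normal matrix is singular; efficiency 0")
    return(new_efficiency_report(rep(0, nv), scenario))
  }
  d <- diag(inv)[seq_len(nv)]
  new_efficiency_report(1 / (sqrt(n) * sqrt(d)), scenario)
}

#' Predicted encoding map over the labeling plane
#'
#' Evaluates the magnetization state the encoding function would impose at
#' every point of the plane, `Mz/M0 = response(2 pi k . r + phi0 + psi(r))`,
#' and extracts the zero- and pi-phase contours (the label and control
#' centrelines).
#'
#' @param solution an [optimize_encoding()] solution.
#' @param response an [inversion_response()].
#' @param psi_map optional [phase_offset_map()]; when `NULL` a uniform zero
#'   offset over `xlim`/`ylim` is assumed.
#' @param xlim,ylim plane extent, mm (ignored when `psi_map` is given).
#' @param resolution grid step, mm (ignored when `psi_map` is given).
#' @return An object of class `"encoding_map"`: list with `x`, `y` (mm),
#'   `mz` (matrix, x by y), `phase` (wrapped net phase), and `contours`
#'   (list of contour polylines with `level` `"label"` (phase 0) or
#'   `"control"` (phase pi)).
#' @export
encoding_map <- function(solution, response, psi_map = NULL,
                         xlim = c(-64, 64), ylim = c(-64, 64),
                         resolution = 1) {
  stopifnot(inherits(solution, "encoding_solution"),
            inherits(response, "inversion_response"))
  if (!is.null(psi_map)) {
    stopifnot(inherits(psi_map, "phase_offset_map"))
    cc <- map_coords(psi_map)
    x <- cc$x; y <- cc$y
    psi <- psi_map$psi
  } else {
    x <- seq(xlim[1], xlim[2], by = resolution)
    y <- seq(ylim[1], ylim[2], by = resolution)
    psi <- matrix(0, length(x), length(y))
  }
  phase <- 2 * pi * (outer(x * solution$k[1], y * solution$k[2], `+`)) +
    solution$phi0 + psi
  wrapped <- wrap_phase(phase)
  mz <- matrix(eval_response(response, phase), length(x), length(y))
  # contours of net phase 0 (label centre) and pi (control centre): zero
  # crossings of sin(phase), classified by the sign of cos(phase)
  sn <- sin(phase)
  cs <- cos(phase)
  raw <- grDevices::contourLines(x, y, sn, levels = 0)
  contours <- lapply(raw, function(seg) {
    xi <- pmin(pmax(round((seg$x - x[1]) / (x[2] - x[1])) + 1, 1), length(x))
    yi <- pmin(pmax(round((seg$y - y[1]) / (y[2] - y[1])) + 1, 1), length(y))
    cls <- if (stats::median(cs[cbind(xi, yi)]) >= 0) "label" else "control"
    list(x = seg$x, y = seg$y, level = cls)
  })
  structure(list(x = x, y = y, mz = mz, phase = wrapped,
                 contours = contours, solution = solution),
            class = "encoding_map")
}

#' @export
plot.encoding_map <- function(x, vessels = NULL, main = "Encoding map", ...) {
  graphics::image(x$x, x$y, x$mz, zlim = c(-1, 1), useRaster = TRUE,
                  col = grDevices::hcl.colors(128, "Blue-Red 3"),
                  xlab = "x (mm)", ylab = "y (mm)", main = main, asp = 1, ...)
  for (seg in x$contours)
    graphics::lines(seg$x, seg$y, lty = 2, lwd = 2,
                    col = if (seg$level == "label") "purple" else "orange")
  if (!is.null(vessels))
    graphics::points(vessels$x_mm, vessels$y_mm, pch = 21, bg = "white",
                     cex = 1.3)
  invisible(x)
}
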