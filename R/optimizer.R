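#' Optimizer configuration
#'
#' Settings for the Fourier-space encoding search. The vessel "image" is laid
#' out at `base_resolution` mm/pixel over a field of view covering the vessels
#' with at least a 32 mm margin (or `base_fov` if given), zero-padded to
#' `pad_size` (default 1024, i.e. a 1024 x 1024 spectrum). The circular
#' frequency mask enforces a minimum encoding wavelength of four times the
#' maximum predicted subject motion, so the cutoff is
#' `|k| <= 1/(4 * max_motion)` cycles/mm; remaining magnitudes are multiplied
#' by a radially non-increasing weight favouring low spatial frequencies
#' (robustness to motion).
#'
#' @param pad_size zero-padded matrix size, pixels (power of two recommended).
#' @param base_resolution vessel-image resolution, mm/pixel.
#' @param base_fov optional base field of view, mm (auto-sized otherwise).
#' @param max_motion maximum predicted subject motion, mm.
#' @param weighting `"linear"` for the taper w(|k|) = 1 - slope |k|/k_cut
#'   (default) or `"uniform"` for no up-weighting.
#' @param weight_slope slope of the linear taper at the mask edge. The mask
#'   itself enforces motion robustness (minimum wavelength four times the
#'   predicted motion); the weight only biases the choice among
#'   near-equivalent peaks towards lower spatial frequency, so the default is
#'   a gentle 0.1 — strong enough to strictly order families of equally good
#'   (e.g. aliased) matches, weak enough never to trade appreciable
#'   phase-match quality at the vessels for a lower |k|.
#' @return An object of class `"oes_config"`.
#' @export
oes_config <- function(pad_size = 1024, base_resolution = 1,
                       base_fov = NULL, max_motion = 4,
                       weighting = c("linear", "uniform"),
                       weight_slope = 0.1) {
  weighting <- match.arg(weighting)
  stopifnot(pad_size >= 2, base_resolution > 0, max_motion > 0,
            weight_slope >= 0, weight_slope <= 1)
  structure(list(pad_size = as.integer(pad_size),
                 base_resolution = base_resolution, base_fov = base_fov,
                 max_motion = max_motion, weighting = weighting,
                 weight_slope = weight_slope),
            class = "oes_config")
}

# cutoff spatial frequency, cycles/mm
k_cutoff <- function(config) 1 / (4 * config$max_motion)

# radial weighting w(|k|); non-increasing with w(0) = 1
k_weight <- function(kr, config) {
  slope <- if (is.null(config$weight_slope)) 0.1 else config$weight_slope
  switch(config$weighting,
         linear = 1 - slope * kr / k_cutoff(config),
         uniform = rep(1, length(kr)))
}

# half-width of the base image in pixels for a vessel set
base_half_width <- function(vessels, config) {
  if (!is.null(config$base_fov)) {
    half <- ceiling(config$base_fov / (2 * config$base_resolution))
  } else {
    ext <- max(abs(c(vessels$x_mm, vessels$y_mm, 0))) + 32
    half <- ceiling(ext / config$base_resolution)
  }
  half
}

# snap vessel positions to integer pixel offsets from the origin voxel
snap_pixels <- function(vessels, config) {
  round(vessel_positions(vessels) / config$base_resolution)
}

#' Complex vessel image
#'
#' Renders the desired-phase specification as a complex image: the voxel
#' nearest each vessel carries exp(i * theta), all other voxels are exactly
#' zero. The image centre voxel is the coordinate origin (gradient isocenter
#' projection).
#'
#' @param vessels a [vessel_set()].
#' @param theta desired phases, rad (one per vessel).
#' @param config an [oes_config()].
#' @return A complex matrix (x along rows, y along columns) with attributes
#'   `resolution` (mm/pixel) and `origin` (index of the centre voxel).
#' @export
build_vessel_image <- function(vessels, theta, config = oes_config()) {
  stopifnot(inherits(vessels, "vessel_set"))
  if (length(theta) != nrow(vessels))
    stop("theta must have one value per vessel")
  half <- base_half_width(vessels, config)
  n <- 2L * half + 1L
  if (n > config$pad_size)
    stop("base image (", n, " px) exceeds pad_size; enlarge pad_size or ",
         "coarsen base_resolution")
  px <- snap_pixels(vessels, config)
  if (any(abs(px) > half))
    stop("vessels fall outside the base field of view")
  idx <- cbind(px[, 1] + half + 1L, px[, 2] + half + 1L)
  if (anyDuplicated(idx) > 0)
    stop("two vessels map to the same voxel; base_resolution too coarse")
  img <- matrix(0 + 0i, n, n)
  img[idx] <- exp(1i * theta)
  attr(img, "resolution") <- config$base_resolution
  attr(img, "origin") <- c(half + 1L, half + 1L)
  img
}

# unshifted FFT frequency coordinates for an n-point axis (cycles per sample)
fft_freqs <- function(n) {
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):(-1L)) / n
}

#' Weight and mask a Fourier spectrum
#'
#' Applies the circular low-pass mask (`|k| > 1/(4 max_motion)` zeroed; the
#' mask is fully circular because the spectrum of a complex image carries no
#' conjugate symmetry) and the radial low-frequency up-weighting to a
#' spectrum laid out in standard unshifted FFT order (zero frequency at
#' `[1, 1]`).
#'
#' @param spectrum complex matrix in unshifted FFT layout.
#' @param config an [oes_config()]; `base_resolution` fixes the cycles/mm
#'   scaling of the frequency grid.
#' @return The weighted, masked spectrum (same layout).
#' @export
weight_and_mask <- function(spectrum, config = oes_config()) {
  n1 <- nrow(spectrum); n2 <- ncol(spectrum)
  fx <- fft_freqs(n1) / config$base_resolution
  fy <- fft_freqs(n2) / config$base_resolution
  kr <- sqrt(outer(fx^2, fy^2, `+`))
  kc <- k_cutoff(config)
  w <- matrix(0, n1, n2)
  inside <- kr <= kc
  if (!any(inside)) stop("frequency mask eliminates all bins")
  w[inside] <- k_weight(kr[inside], config)
  spectrum * w
}

# in-mask frequency lattice of the padded spectrum: data.frame of bin
# frequencies (cycles/mm) and weights; memoised per configuration
mask_lattice <- function(config) {
  key <- paste("lattice", config$pad_size, config$base_resolution,
               config$max_motion, config$weighting, config$weight_slope,
               sep = "|")
  cached <- .oesasl_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- config$pad_size
  res <- config$base_resolution
  kc <- k_cutoff(config)
  rmax <- floor(kc * p * res)
  u <- -rmax:rmax
  ku <- u / (p * res)
  g <- expand.grid(kx = ku, ky = ku)
  kr <- sqrt(g$kx^2 + g$ky^2)
  keep <- kr <= kc
  out <- data.frame(kx = g$kx[keep], ky = g$ky[keep], kr = kr[keep],
                    w = k_weight(kr[keep], config))
  .oesasl_cache[[key]] <- out
  out
}

# deterministic arg-max with tie-breaking: among bins within rtol of the peak
# magnitude, lowest |k| wins, then lexicographic (kx, ky)
select_peak <- function(mag, kx, ky, rtol = 1e-9) {
  top <- max(mag)
  cand <- which(mag >= top * (1 - rtol))
  kr <- sqrt(kx[cand]^2 + ky[cand]^2)
  ord <- order(kr, kx[cand], ky[cand])
  cand[ord[1]]
}

#' Optimize one encoding cycle
#'
#' The core Fourier-space search: build the complex vessel image, zero-pad,
#' Fourier transform, weight and mask, and take the spatial frequency and
#' phase of the maximum-magnitude bin. The winning bin defines the encoding
#' function `theta_hat(r) = 2 pi k . r + phi0`, the per-interval phase the
#' gradient blips and RF phase increment will induce at position r; it is the
#' discrete-grid maximizer of `|sum_j exp(i theta_j) exp(-2 pi i k . r_j)| *
#' w(|k|)` over the masked lattice.
#'
#' `method = "direct"` (default) evaluates the spectrum only on the in-mask
#' lattice bins straight from the (voxel-snapped) vessel positions; because
#' the image is nonzero only at the vessels this is algebraically identical,
#' bin for bin, to masking the full zero-padded FFT (`method = "fft"`), and
#' is much faster. Ties are broken deterministically: lowest `|k|`, then
#' lexicographic `(kx, ky)`.
#'
#' A uniform desired phase (all `theta` equal) yields the valid degenerate
#' solution k = 0 with phi0 equal to that phase — conventional PCASL cycles.
#'
#' @param vessels a [vessel_set()] (>= 1 vessel).
#' @param theta desired phases, rad (one per vessel), e.g. from
#'   [desired_phases()].
#' @param config an [oes_config()].
#' @param method `"direct"` or `"fft"`.
#' @return An object of class `"encoding_solution"`: a list with `k`
#'   (cycles/mm, length-2), `phi0` (rad), `score` (peak magnitude times
#'   weight), `theta`, `phase_error` (wrapped theta_hat - theta at the
#'   vessels, rad), `vessels`, `config`, `method`. Gradient blip areas and the
#'   RF phase increment are filled in by [to_hardware()].
#' @examples
#' v <- neck_vessels()
#' optimize_encoding(v, desired_phases(c(-1, -1, -1, -1), v))  # k = 0
#' @export
optimize_encoding <- function(vessels, theta, config = oes_config(),
                              method = c("direct", "fft")) {
  method <- match.arg(method)
  stopifnot(inherits(vessels, "vessel_set"), nrow(vessels) >= 1)
  if (length(theta) != nrow(vessels))
    stop("theta must have one value per vessel")
  res <- config$base_resolution
  px <- snap_pixels(vessels, config)
  if (anyDuplicated(px) > 0)
    stop("two vessels map to the same voxel; base_resolution too coarse")
  rs <- px * res  # snapped positions, mm

  if (method == "direct") {
    lat <- mask_lattice(config)
    ph <- outer(lat$kx, rs[, 1]) + outer(lat$ky, rs[, 2])
    f <- as.vector(exp(-2i * pi * ph) %*% exp(1i * theta))
    mag <- abs(f) * lat$w
    i <- select_peak(mag, lat$kx, lat$ky)
    k <- c(lat$kx[i], lat$ky[i])
    phi0 <- Arg(f[i])
    score <- mag[i]
  } else {
    p <- config$pad_size
    img <- matrix(0 + 0i, p, p)
    idx <- cbind(px[, 1] %% p + 1L, px[, 2] %% p + 1L)
    img[idx] <- exp(1i * theta)
    spec <- stats::fft(img)
    wspec <- weight_and_mask(spec, config)
    mag <- abs(wspec)
    fx <- fft_freqs(p) / res
    kxg <- matrix(fx, p, p)
    kyg <- matrix(fx, p, p, byrow = TRUE)
    i <- select_peak(as.vector(mag), as.vector(kxg), as.vector(kyg))
    k <- c(kxg[i], kyg[i])
    phi0 <- Arg(spec[i])
    score <- mag[i]
  }
  pred <- 2 * pi * as.vector(vessel_positions(vessels) %*% k) + phi0
  structure(list(k = k, phi0 = phi0, score = score, theta = theta,
                 phase_error = wrap_phase(pred - theta),
                 blip_area = NULL, rf_increment = NULL,
                 vessels = vessels, config = config, method = method),
            class = "encoding_solution")
}

#' Convert an encoding solution to hardware parameters
#'
#' Fills in the per-interval transverse gradient blip areas and the RF phase
#' increment realizing the selected encoding function. The blip area per axis
#' satisfies `gamma_bar * A = 1000 * k` (gamma_bar in cycles/(mT ms), A in
#' mT ms/m, k in cycles/mm), so a spin at in-plane position r accrues
#' `2 pi k . r` rad per interval from the blips; `phi0` is realized purely
#' through the RF transmit phase, advanced by `-phi0` per pulse. The blips are
#' applied with the same polarity in every interval (unipolar), which is what
#' allows a static phase offset to be cancelled.
#'
#' @param solution an [optimize_encoding()] result.
#' @param params a [pulse_train()] (supplies the gyromagnetic ratio).
#' @param blip_limit hardware blip-area limit, mT ms/m; exceeding it raises a
#'   warning, not an error.
#' @return The solution with `blip_area` (mT ms/m, per axis) and
#'   `rf_increment` (rad per pulse) filled in.
#' @export
to_hardware <- function(solution, params = pulse_train(), blip_limit = 10) {
  stopifnot(inherits(solution, "encoding_solution"))
  gbar <- params$gyromagnetic_ratio / 1000  # cycles/(mT ms)
  solution$blip_area <- 1000 * solution$k / gbar
  solution$rf_increment <- -solution$phi0
  if (any(abs(solution$blip_area) > blip_limit))
    warning("blip area ", paste(signif(solution$blip_area, 4), collapse = ", "),
            " mT ms/m exceeds the hardware limit of ", blip_limit)
  solution$gyromagnetic_ratio <- params$gyromagnetic_ratio
  solution
}

#' Per-interval phase predicted from hardware parameters
#'
#' Reconstructs the per-interval phase at in-plane positions from the blip
#' areas and RF phase increment of a hardware-converted solution; equals
#' `2 pi k . r + phi0` (mod 2 pi) by construction, so this is the round-trip
#' check on the unit conventions.
#'
#' @param solution a [to_hardware()]-converted solution.
#' @param positions n x 2 matrix of positions, mm.
#' @return Phases, rad (unwrapped).
#' @export
predicted_phase <- function(solution, positions) {
  if (is.null(solution$blip_area))
    stop("solution has no hardware parameters; call to_hardware() first")
  positions <- rbind(positions)
  gbar <- solution$gyromagnetic_ratio / 1000
  2 * pi * gbar / 1000 * as.vector(positions %*% solution$blip_area) -
    solution$rf_increment
}

#' @export
print.encoding_solution <- function(x, ...) {
  cat("Encoding solution\n")
  cat(sprintf("  k = (%.5f, %.5f) cycles/mm  (|k| = %.5f, wavelength %s mm)\n",
              x$k[1], x$k[2], sqrt(sum(x$k^2)),
              if (all(x$k == 0)) "Inf" else sprintf("%.1f", 1 / sqrt(sum(x$k^2)))))
  cat(sprintf("  phi0 = %.4f rad, score = %.3f\n", x$phi0, x$score))
  if (!is.null(x$blip_area))
    cat(sprintf("  blip area = (%.4f, %.4f) mT ms/m, RF increment = %.4f rad\n",
                x$blip_area[1], x$blip_area[2], x$rf_increment))
  cat(sprintf("  max |phase error| at vessels = %.4f rad\n",
              max(abs(x$phase_error))))
  invisible(x)
}
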