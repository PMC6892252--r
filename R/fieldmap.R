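#' Gridded phase-offset map of the labeling plane
#'
#' A 2-D grid of the phase psi (rad) accrued per RF interval due to
#' off-resonance, with voxel geometry. Rows index x, columns y; voxel centres
#' are used throughout, and `origin` is the mm coordinate of the grid centre
#' voxel.
#'
#' @param psi matrix of phase offsets, rad per RF interval.
#' @param voxel_size voxel edge, mm (isotropic in-plane).
#' @param origin mm coordinate (x, y) of the grid centre voxel.
#' @return An object of class `"phase_offset_map"`.
#' @export
phase_offset_map <- function(psi, voxel_size = 1, origin = c(0, 0)) {
  psi <- as.matrix(psi)
  if (!all(is.finite(psi))) stop("psi must be finite everywhere")
  stopifnot(voxel_size > 0, length(origin) == 2)
  structure(list(psi = psi, voxel_size = voxel_size, origin = origin),
            class = "phase_offset_map")
}

# voxel-centre coordinates (mm) of a map
map_coords <- function(map) {
  n1 <- nrow(map$psi); n2 <- ncol(map$psi)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  list(x = (seq_len(n1) - c1) * map$voxel_size + map$origin[1],
       y = (seq_len(n2) - c2) * map$voxel_size + map$origin[2])
}

#' @export
print.phase_offset_map <- function(x, ...) {
  cat(sprintf("Phase-offset map: %d x %d voxels at %g mm, psi in [%.3f, %.3f] rad\n",
              nrow(x$psi), ncol(x$psi), x$voxel_size,
              min(x$psi), max(x$psi)))
  invisible(x)
}

#' Synthetic linear + quadratic fieldmap
#'
#' Generates a smooth phase-offset map from a linear gradient plus a
#' quadratic bowl, the shapes a first-order shim error and a susceptibility
#' focus produce. The two terms are first balanced so each contributes
#' `linear_frac` / `1 - linear_frac` of the maximum vessel offset, then the
#' sum is globally normalized so that the largest |psi| over the supplied
#' vessel positions equals `base_max_offset` at `scale = 1`; psi scales
#' linearly with `scale`.
#'
#' @param vessels a [vessel_set()] used for the normalization.
#' @param shape grid dimensions (voxels).
#' @param voxel_size voxel edge, mm.
#' @param linear_coeffs direction (and relative weight) of the linear term,
#'   rad/mm per axis before normalization.
#' @param quad_coeff sign/weight of the quadratic term before normalization.
#' @param quad_centre centre of the quadratic term, mm.
#' @param scale offset multiplier (0 gives a zero map).
#' @param base_max_offset target max |psi| over vessels at scale 1, rad.
#' @param linear_frac fraction of the maximum offset contributed by the
#'   linear term (default 0.5).
#' @return A [phase_offset_map()].
#' @examples
#' m <- synth_fieldmap(neck_vessels(), scale = 1)
#' max(abs(sample_psi(m, vessel_positions_mm(neck_vessels()))))  # ~1.2
#' @export
synth_fieldmap <- function(vessels, shape = c(129, 129), voxel_size = 1,
                           linear_coeffs = c(1, 0), quad_coeff = 1,
                           quad_centre = c(0, 0), scale = 1,
                           base_max_offset = 1.2, linear_frac = 0.5) {
  stopifnot(inherits(vessels, "vessel_set"))
  if (all(linear_coeffs == 0) && quad_coeff == 0 && base_max_offset != 0)
    stop("all coefficients are zero but a nonzero vessel offset is requested")
  pos <- vessel_positions(vessels)
  lin_at <- function(p) p[, 1] * linear_coeffs[1] + p[, 2] * linear_coeffs[2]
  quad_at <- function(p) quad_coeff *
    ((p[, 1] - quad_centre[1])^2 + (p[, 2] - quad_centre[2])^2)
  lmax <- max(abs(lin_at(pos)))
  qmax <- max(abs(quad_at(pos)))
  a <- if (lmax > 0) linear_frac / lmax else 0
  b <- if (qmax > 0) (1 - linear_frac) / qmax else 0
  raw_at <- function(p) a * lin_at(p) + b * quad_at(p)
  vmax <- max(abs(raw_at(pos)))
  if (vmax == 0) stop("fieldmap is identically zero at the vessels")
  s <- base_max_offset / vmax
  m <- phase_offset_map(matrix(0, shape[1], shape[2]), voxel_size)
  cc <- map_coords(m)
  grid <- cbind(rep(cc$x, times = length(cc$y)),
                rep(cc$y, each = length(cc$x)))
  m$psi <- matrix(scale * s * raw_at(grid), shape[1], shape[2])
  m
}

#' Vessel positions as a matrix
#'
#' @param vessels a [vessel_set()].
#' @return n x 2 matrix of (x, y) positions, mm.
#' @export
vessel_positions_mm <- function(vessels) vessel_positions(vessels)

#' Sample a phase-offset map at points
#'
#' Point estimates of psi at given positions, taken from the nearest voxel
#' centre (the fieldmaps are smooth, so single-voxel point estimates at the
#' vessel centres are normally sufficient). Optionally a 3 x 3 neighbourhood
#' average for robustness to noise in rapid low-SNR fieldmap acquisitions.
#'
#' @param map a [phase_offset_map()].
#' @param positions n x 2 matrix of positions, mm.
#' @param average if `TRUE`, average psi over the 3 x 3 voxel neighbourhood.
#' @return Phase offsets, rad.
#' @export
sample_psi <- function(map, positions, average = FALSE) {
  stopifnot(inherits(map, "phase_offset_map"))
  positions <- rbind(positions)
  cc <- map_coords(map)
  i <- round((positions[, 1] - cc$x[1]) / map$voxel_size) + 1
  j <- round((positions[, 2] - cc$y[1]) / map$voxel_size) + 1
  if (any(i < 1 | i > nrow(map$psi) | j < 1 | j > ncol(map$psi)))
    stop("position outside the fieldmap extent")
  if (!average) return(map$psi[cbind(i, j)])
  vapply(seq_along(i), function(s) {
    ii <- pmin(pmax(i[s] + (-1:1), 1), nrow(map$psi))
    jj <- pmin(pmax(j[s] + (-1:1), 1), ncol(map$psi))
    mean(map$psi[ii, jj])
  }, numeric(1))
}

#' Two-echo gradient-echo fieldmap acquisition
#'
#' Container for the phase images of a dual-echo fieldmap of the labeling
#' plane, used to extract per-interval phase offsets.
#'
#' @param phase1,phase2 phase images at the two echoes, rad in (-pi, pi],
#'   identical geometry.
#' @param te1,te2 echo times, seconds (`te2 > te1`).
#' @param rf_interval PCASL RF pulse spacing, seconds.
#' @param voxel_size voxel edge, mm.
#' @param origin mm coordinate of the grid centre voxel.
#' @param magnitude optional magnitude image (quality guide for unwrapping).
#' @return An object of class `"echo_pair"`.
#' @export
echo_pair <- function(phase1, phase2, te1, te2, rf_interval = 1e-3,
                      voxel_size = 1, origin = c(0, 0), magnitude = NULL) {
  phase1 <- as.matrix(phase1); phase2 <- as.matrix(phase2)
  if (!identical(dim(phase1), dim(phase2)))
    stop("phase image geometries differ")
  if (te2 <= te1) stop("te2 must exceed te1")
  structure(list(phase1 = phase1, phase2 = phase2, te1 = te1, te2 = te2,
                 rf_interval = rf_interval, voxel_size = voxel_size,
                 origin = origin, magnitude = magnitude),
            class = "echo_pair")
}

#' Phase-offset map from a two-echo fieldmap
#'
#' When the echo-time difference equals the PCASL RF spacing, the wrapped
#' phase difference between the echoes *is* the phase accrued between two
#' PCASL pulses, and no unwrapping is needed. Otherwise the phase difference
#' is unwrapped in 2-D, divided by the echo-time difference and multiplied by
#' the RF spacing.
#'
#' @param pair an [echo_pair()].
#' @param tol tolerance on `|te2 - te1 - rf_interval|` for the direct path,
#'   seconds.
#' @return A [phase_offset_map()].
#' @export
psi_from_echoes <- function(pair, tol = 1e-6) {
  stopifnot(inherits(pair, "echo_pair"))
  dte <- pair$te2 - pair$te1
  dphi <- wrap_phase(pair$phase2 - pair$phase1)
  psi <- if (abs(dte - pair$rf_interval) < tol) {
    dphi
  } else {
    unwrap2d(dphi, quality = pair$magnitude) / dte * pair$rf_interval
  }
  phase_offset_map(psi, pair$voxel_size, pair$origin)
}

#' Quality-guided 2-D phase unwrapping
#'
#' Region-growing unwrapper: starting from the highest-quality voxel, voxels
#' are admitted in decreasing quality order from the growing front, each
#' unwrapped against its already-unwrapped neighbour by adding the multiple of
#' 2 pi that minimizes the jump. Quality defaults to the (negative) local
#' wrapped-phase gradient magnitude when no magnitude image is supplied, so
#' smooth regions are unwrapped first.
#'
#' The result is unique up to a global 2 pi multiple; the seed voxel keeps its
#' wrapped value.
#'
#' @param wrapped wrapped phase image, rad.
#' @param quality optional quality image (higher = better), same geometry.
#' @return Unwrapped phase image, rad.
#' @export
unwrap2d <- function(wrapped, quality = NULL) {
  wrapped <- as.matrix(wrapped)
  n1 <- nrow(wrapped); n2 <- ncol(wrapped)
  if (is.null(quality)) {
    gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
    gx[-n1, ] <- abs(wrap_phase(diff(wrapped)))
    gy[, -n2] <- abs(wrap_phase(t(diff(t(wrapped)))))
    quality <- -(gx + gy)
  }
  out <- wrapped
  done <- matrix(FALSE, n1, n2)
  infront <- matrix(FALSE, n1, n2)
  seed <- which.max(quality)
  done[seed] <- TRUE
  qv <- as.vector(quality)
  front <- integer(0)
  push_neighbours <- function(idx, front) {
    i <- (idx - 1L) %% n1 + 1L
    j <- (idx - 1L) %/% n1 + 1L
    for (d in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (d[1] < 1 || d[1] > n1 || d[2] < 1 || d[2] > n2) next
      nb <- (d[2] - 1L) * n1 + d[1]
      if (!done[nb] && !infront[nb]) {
        infront[nb] <<- TRUE
        front <- c(front, nb)
      }
    }
    front
  }
  front <- push_neighbours(seed, front)
  while (length(front) > 0) {
    pick <- which.max(qv[front])
    idx <- front[pick]
    front <- front[-pick]
    i <- (idx - 1L) %% n1 + 1L
    j <- (idx - 1L) %/% n1 + 1L
    ref <- NA_real_
    best <- -Inf
    for (d in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (d[1] < 1 || d[1] > n1 || d[2] < 1 || d[2] > n2) next
      nb <- (d[2] - 1L) * n1 + d[1]
      if (done[nb] && qv[nb] > best) { best <- qv[nb]; ref <- out[nb] }
    }
    out[idx] <- wrapped[idx] + 2 * pi * round((ref - wrapped[idx]) / (2 * pi))
    done[idx] <- TRUE
    front <- push_neighbours(idx, front)
  }
  out
}

#' Read a fieldmap slice from a NIfTI volume
#'
#' Reads a single-slice (or first-slice) image and returns it with its
#' in-plane voxel size taken from the header.
#'
#' @param path NIfTI file path.
#' @return A list with `data` (matrix) and `voxel_size` (mm).
#' @export
read_nifti_slice <- function(path) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) > 2) arr <- arr[, , 1]
  list(data = arr, voxel_size = pix[1])
}

#' Write a map or image to NIfTI
#'
#' @param x a matrix, [phase_offset_map()] or `"encoding_map"`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge, mm (taken from the object when available).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_size = 1) {
  if (inherits(x, "phase_offset_map")) {
    data <- x$psi; voxel_size <- x$voxel_size
  } else if (inherits(x, "encoding_map")) {
    data <- x$mz
    voxel_size <- if (length(x$x) > 1) x$x[2] - x$x[1] else voxel_size
  } else data <- as.matrix(x)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}
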