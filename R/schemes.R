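#' Wrap phase to (-pi, pi]
#'
#' @param x phase(s), rad.
#' @return Wrapped phase(s) in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Sylvester Hadamard matrix, order a power of two
hadamard_matrix <- function(n) {
  if (n < 1 || bitwAnd(n, n - 1L) != 0)
    stop("Hadamard order must be a power of two, got ", n)
  h <- matrix(1, 1, 1)
  while (nrow(h) < n) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

#' Ideal label/control encoding scheme
#'
#' Builds the ideal cycles-by-vessels encoding matrix with entries +1
#' (control) and -1 (label). Conventional PCASL uses two cycles: all vessels
#' labeled, then all vessels controlled. Vessel-encoded PCASL draws its
#' columns from a (Sylvester) Hadamard matrix of the smallest power-of-two
#' order at least `n_vessels + 1`, excluding the constant all-ones column so
#' that every vessel experiences both conditions; for four vessels this gives
#' the standard 8-cycle design. Column selection is deterministic
#' (lowest-index non-constant columns first).
#'
#' @param kind `"pcasl"` or `"vepcasl"`.
#' @param n_vessels number of vessels (>= 1).
#' @return A cycles x vessels matrix of +/-1, class `"ideal_scheme"`, with the
#'   kind stored in `attr(, "kind")`.
#' @examples
#' ideal_scheme("pcasl", 4)
#' ideal_scheme("vepcasl", 4)  # 8 x 4, orthogonal columns
#' @export
ideal_scheme <- function(kind = c("pcasl", "vepcasl"), n_vessels) {
  kind <- match.arg(kind)
  stopifnot(n_vessels >= 1)
  if (kind == "pcasl") {
    m <- rbind(rep(-1, n_vessels), rep(1, n_vessels))
    rownames(m) <- c("label", "control")
  } else {
    ord <- 2^ceiling(log2(n_vessels + 1))
    h <- hadamard_matrix(ord)
    m <- h[, 2:(n_vessels + 1), drop = FALSE]
    rownames(m) <- paste0("cycle", seq_len(nrow(m)))
  }
  colnames(m) <- paste0("v", seq_len(n_vessels))
  structure(m, kind = kind, class = c("ideal_scheme", class(m)))
}

#' Desired per-vessel phases for one encoding cycle
#'
#' Converts one row of an ideal scheme into the per-interval phase that must
#' be induced at each vessel, subtracting the local off-resonance phase offset
#' psi so that the realized condition lands on label (net phase 0) or control
#' (net phase pi): `theta = 0 - psi` at labeled vessels and `theta = pi - psi`
#' at controlled vessels, reported wrapped to (-pi, pi].
#'
#' @param scheme_row vector of +/-1 (+1 control, -1 label).
#' @param vessels a [vessel_set()]; its `psi_rad` column supplies psi, or
#' @param psi optional phase offsets overriding `vessels$psi_rad`, rad.
#' @return Desired phases theta, rad, wrapped to (-pi, pi].
#' @examples
#' v <- neck_vessels()
#' desired_phases(c(-1, -1, -1, -1), v)            # all-label: 0
#' desired_phases(c(1, 1, 1, 1), v, psi = rep(0.3, 4))
#' @export
desired_phases <- function(scheme_row, vessels, psi = NULL) {
  if (!all(scheme_row %in% c(-1, 1)))
    stop("scheme_row entries must be +1 (control) or -1 (label)")
  if (is.null(psi)) {
    psi <- if (inherits(vessels, "vessel_set") &&
               !is.null(vessels$psi_rad)) vessels$psi_rad
           else rep(0, length(scheme_row))
  }
  if (length(psi) == 1) psi <- rep(psi, length(scheme_row))
  if (length(psi) != length(scheme_row))
    stop("psi length (", length(psi), ") does not match scheme_row length (",
         length(scheme_row), ")")
  ideal <- ifelse(scheme_row > 0, pi, 0)
  wrap_phase(ideal - psi)
}
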