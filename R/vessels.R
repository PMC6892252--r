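#' Vessel set in the labeling plane
#'
#' A named set of vessel positions in labeling-plane coordinates (mm, relative
#' to the gradient isocenter projection), optionally with per-vessel phase
#' offsets psi (rad accrued per RF interval due to off-resonance). Stored as a
#' data frame with columns `name`, `x_mm`, `y_mm`, `psi_rad`; psi is kept
#' unwrapped as supplied (wrapping happens at reporting and at the optimizer
#' input).
#'
#' @param name unique vessel names.
#' @param x_mm,y_mm in-plane coordinates, mm.
#' @param psi_rad per-vessel phase offsets, rad per RF interval (default 0).
#' @return A data frame of class `"vessel_set"`.
#' @examples
#' vessel_set(c("RICA", "LICA"), c(25, -25), c(10, 10))
#' @export
vessel_set <- function(name, x_mm, y_mm, psi_rad = 0) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("vessel names must be unique")
  if (length(x_mm) != length(name) || length(y_mm) != length(name))
    stop("x_mm and y_mm must match name in length")
  if (!all(is.finite(x_mm)) || !all(is.finite(y_mm)))
    stop("vessel positions must be finite")
  if (length(psi_rad) == 1) psi_rad <- rep(psi_rad, length(name))
  if (length(psi_rad) != length(name))
    stop("psi_rad must have one value per vessel")
  structure(data.frame(name = name, x_mm = as.numeric(x_mm),
                       y_mm = as.numeric(y_mm), psi_rad = as.numeric(psi_rad),
                       stringsAsFactors = FALSE),
            class = c("vessel_set", "data.frame"))
}

#' Default four-vessel neck geometry
#'
#' A symmetric arrangement of the four main brain-feeding arteries at a neck
#' labeling plane: internal carotids 25 mm lateral / 10 mm anterior,
#' vertebrals 10 mm lateral / 10 mm posterior of the isocenter projection.
#'
#' @return A [vessel_set()] with vessels RICA, LICA, RVA, LVA and psi = 0.
#' @export
neck_vessels <- function() {
  vessel_set(c("RICA", "LICA", "RVA", "LVA"),
             x_mm = c(25, -25, 10, -10),
             y_mm = c(10, 10, -10, -10))
}

# positions as n x 2 matrix (mm)
vessel_positions <- function(vessels) {
  cbind(vessels$x_mm, vessels$y_mm)
}

#' Read a vessel specification file
#'
#' Reads a vessel set from JSON (a list/array of objects) or CSV, both with
#' fields `name`, `x_mm`, `y_mm` and optional `psi_rad`. Missing required
#' fields are reported by name.
#'
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @return A [vessel_set()].
#' @export
read_vessels <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    json = as.data.frame(jsonlite::fromJSON(path)),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    stop("unsupported vessel file extension: .", ext))
  for (field in c("name", "x_mm", "y_mm")) {
    if (is.null(df[[field]]))
      stop("vessel file ", path, " is missing required field '", field, "'")
  }
  vessel_set(df$name, df$x_mm, df$y_mm,
             if (is.null(df$psi_rad)) 0 else df$psi_rad)
}

#' Write a vessel set
#'
#' @param vessels a [vessel_set()].
#' @param path output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_vessels <- function(vessels, path) {
  stopifnot(inherits(vessels, "vessel_set"))
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(unclass(vessels), stringsAsFactors = FALSE)
  switch(ext,
    json = jsonlite::write_json(df, path, digits = NA, pretty = TRUE),
    csv = utils::write.csv(df, path, row.names = FALSE),
    stop("unsupported vessel file extension: .", ext))
  invisible(path)
}

#' Perturb vessel positions
#'
#' Offsets each coordinate of each vessel independently by a draw from
#' Normal(0, sd^2), emulating anatomical variation in vessel arrangements.
#'
#' @param base a [vessel_set()].
#' @param sd perturbation standard deviation, mm (>= 0).
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched.
#' @return A perturbed [vessel_set()] (names and psi retained).
#' @export
perturb_vessels <- function(base, sd = 2, seed = NULL) {
  stopifnot(inherits(base, "vessel_set"), sd >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(base)
  vessel_set(base$name,
             base$x_mm + stats::rnorm(n, 0, sd),
             base$y_mm + stats::rnorm(n, 0, sd),
             base$psi_rad)
}
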