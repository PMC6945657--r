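#' 1D scan curve (depth dose or lateral profile)
#'
#' A uniformly spaced 1D dose curve of the kind a water-tank scanner produces:
#' either a central-axis depth-dose curve (`kind = "pdd"`) or a lateral
#' profile at a fixed depth (`kind = "lateral"`). The constructor applies the
#' requested normalisation: depth-dose curves are scaled to 100 at their
#' maximum, lateral profiles to 100 on the central axis (the position closest
#' to zero; the mean of the two central samples when they straddle zero
#' exactly). `normalization = "none"` stores the raw values, which is useful
#' for constructed comparison cases.
#'
#' @param kind `"pdd"` or `"lateral"`.
#' @param positions Strictly increasing, uniformly spaced positions in cm
#'   (depth for a PDD, off-axis distance for a profile).
#' @param values Non-negative dose values (percent after normalisation).
#' @param depth Scan depth in cm, for lateral profiles.
#' @param normalization `"pdd_max_100"`, `"cax_100"` or `"none"`.
#' @return An object of class `scan_curve`.
#' @export
scan_curve <- function(kind = c("pdd", "lateral"), positions, values,
                       depth = NA_real_,
                       normalization = c("pdd_max_100", "cax_100", "none")) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(positions), is.numeric(values),
            length(positions) == length(values))
  if (length(positions) < 2L) stop("a scan curve needs at least two points")
  if (any(!is.finite(positions)) || any(!is.finite(values)))
    stop("positions and values must be finite")
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  spacing <- d[1]
  if (any(abs(d - spacing) > 1e-9 * max(1, spacing)))
    stop("positions must be uniformly spaced")
  if (any(values < 0)) stop("dose values must be >= 0")
  curve <- structure(
    list(kind = kind, depth = depth, positions = positions,
         values = values, spacing = spacing, normalization = normalization),
    class = "scan_curve"
  )
  if (normalization != "none") curve <- normalize_curve(curve)
  curve
}

# Central-axis value: sample nearest to x = 0, averaging the two central
# samples when they straddle zero at equal distance.
cax_value <- function(curve) {
  a <- abs(curve$positions)
  i <- which.min(a)
  tie <- which(abs(a - a[i]) <= 1e-9 * max(1, curve$spacing))
  mean(curve$values[tie])
}

#' Normalise a scan curve in place
#'
#' Rescales so the maximum (PDD) or the central-axis value (lateral profile)
#' equals 100, per the curve's stored normalisation convention. Idempotent.
#'
#' @param curve A [scan_curve()].
#' @return The normalised `scan_curve`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$normalization == "none") return(curve)
  ref <- switch(curve$normalization,
                pdd_max_100 = max(curve$values),
                cax_100 = cax_value(curve))
  if (!is.finite(ref) || ref <= 0)
    stop("cannot normalise: reference value is not positive")
  curve$values <- curve$values * (100 / ref)
  curve
}

#' @export
print.scan_curve <- function(x, ...) {
  cat(sprintf("<scan_curve> %s%s: %d points, %.3g-%.3g cm, spacing %.3g cm (%s)\n",
              x$kind,
              if (x$kind == "lateral" && is.finite(x$depth))
                sprintf(" @ %.2f cm depth", x$depth) else "",
              length(x$positions), min(x$positions), max(x$positions),
              x$spacing, x$normalization))
  invisible(x)
}

# Index of the depth bin whose centre is nearest to `depth`; equidistant ties
# resolve toward the surface. Centres sit at (k - 1/2) * bin.
depth_to_bin <- function(depth, phantom) {
  centers <- (seq_len(phantom$nz) - 0.5) * phantom$bin
  dist <- abs(centers - depth)
  which(dist <= min(dist) + 1e-12)[1]
}

# Central lateral index / indices (two when the axis has an even bin count).
central_indices <- function(n) {
  if (n %% 2L == 1L) (n + 1L) %/% 2L else c(n %/% 2L, n %/% 2L + 1L)
}

#' Extract the central-axis depth-dose curve from a dose grid
#'
#' Takes the dose along the beam axis (averaging the 2 x 2 central columns
#' when a lateral axis has an even bin count) and normalises the result to
#' 100 at its maximum.
#'
#' @param grid A `dose_grid`.
#' @return A [scan_curve()] of kind `"pdd"` with spacing equal to the bin size.
#' @export
extract_pdd <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  ph <- grid$phantom
  ix <- central_indices(ph$nx)
  iy <- central_indices(ph$ny)
  vals <- apply(grid$dose[ix, iy, , drop = FALSE], 3, mean)
  if (max(vals) <= 0) stop("degenerate grid: central axis has no dose")
  scan_curve("pdd", positions = phantom_axes(ph)$z, values = vals,
             normalization = "pdd_max_100")
}

#' Extract a lateral profile at a given depth from a dose grid
#'
#' Selects the depth bin whose centre is nearest to `depth` (ties toward the
#' surface), takes the dose versus x on the central y axis and normalises to
#' 100 on the central axis.
#'
#' @param grid A `dose_grid`.
#' @param depth Requested depth in cm; must lie inside the phantom.
#' @return A [scan_curve()] of kind `"lateral"`; its `depth` field records the
#'   centre of the selected bin.
#' @export
extract_profile <- function(grid, depth) {
  stopifnot(inherits(grid, "dose_grid"))
  ph <- grid$phantom
  if (depth < 0 || depth > ph$size_z)
    stop("'depth' lies outside the phantom")
  k <- depth_to_bin(depth, ph)
  iy <- central_indices(ph$ny)
  vals <- apply(grid$dose[, iy, k, drop = FALSE], 1, mean)
  curve <- scan_curve("lateral", positions = phantom_axes(ph)$x, values = vals,
                      depth = (k - 0.5) * ph$bin, normalization = "cax_100")
  curve
}

#' Resample a scan curve by linear interpolation
#'
#' Refines the curve onto a grid with `factor` times finer spacing, endpoints
#' preserved — the curve-wise analogue of enhancing a dose grid to one-fifth
#' of the bin size before a gamma comparison (default `factor = 5`).
#'
#' @param curve A [scan_curve()].
#' @param factor Integer refinement factor, >= 1. `factor = 1` returns the
#'   curve unchanged.
#' @return A [scan_curve()] with spacing `curve$spacing / factor`.
#' @export
resample_curve <- function(curve, factor = 5L) {
  stopifnot(inherits(curve, "scan_curve"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      abs(factor - round(factor)) > 1e-9)
    stop("'factor' must be an integer >= 1")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(curve)
  n <- length(curve$positions)
  new_pos <- curve$positions[1] + (seq_len((n - 1L) * factor + 1L) - 1L) *
    (curve$spacing / factor)
  # guard against accumulated rounding pushing the endpoint outside the data
  new_pos[length(new_pos)] <- curve$positions[n]
  new_val <- stats::approx(curve$positions, curve$values, xout = new_pos,
                           method = "linear", rule = 2)$y
  out <- curve
  out$positions <- new_pos
  out$values <- new_val
  out$spacing <- curve$spacing / factor
  out
}
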