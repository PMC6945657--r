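# Parametric stand-in for a Monte-Carlo linac dose calculation: an analytic
# depth-dose / profile model whose shape responds monotonically to the four
# beam parameters, plus multiplicative noise shrinking as 1/sqrt(histories).

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Evaluate `expr` under a private RNG stream; the caller's stream is untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Analytic central-axis depth-dose model
#'
#' Relative dose on the beam axis at depth `z`:
#' `A * (1 - exp(-beta z)) * exp(-mu z)`, a build-up term times exponential
#' attenuation. The attenuation coefficient decreases with beam energy (more
#' penetrating beams) and increases weakly with the energy spread; the
#' build-up coefficient decreases with energy (deeper dose maximum).
#'
#' @param depth Depth(s) in cm, >= 0.
#' @param config A [beam_config()].
#' @param constants A [dose_model_constants()].
#' @return Relative dose (unitless), same length as `depth`.
#' @examples
#' pdd_model(10, beam_config(6.26))
#' @export
pdd_model <- function(depth, config, constants = dose_model_constants()) {
  stopifnot(inherits(config, "beam_config"))
  if (any(depth < 0)) stop("'depth' must be >= 0")
  E <- config$energy
  mu <- constants$mu_coeff / E * (1 + constants$mu_fwhm_coeff * config$energy_fwhm / E)
  beta <- constants$beta_coeff / E
  constants$amplitude * (1 - exp(-beta * depth)) * exp(-mu * depth)
}

# Depth of the dose maximum of the closed-form model.
pdd_depth_of_max <- function(config, constants = dose_model_constants()) {
  E <- config$energy
  mu <- constants$mu_coeff / E * (1 + constants$mu_fwhm_coeff * config$energy_fwhm / E)
  beta <- constants$beta_coeff / E
  log(1 + beta / mu) / beta
}

#' Analytic lateral-profile model
#'
#' Flat-top profile with error-function penumbrae at the projected field edges
#' and a quadratic in-field horn term. The field half-width follows the
#' divergent projection `W = field * (ssd + depth) / ssd`; the penumbra width
#' grows with the focal-spot FWHM and with depth; the horn amplitude grows
#' with beam divergence and shrinks with the energy spread. Each beam
#' parameter therefore has its own signature on the profile.
#'
#' @param x Off-axis position(s) in cm.
#' @param depth Depth in cm, >= 0 (scalar).
#' @param config A [beam_config()].
#' @param phantom A [phantom_spec()] (supplies SSD and field size).
#' @param constants A [dose_model_constants()].
#' @param field Field side in cm along this axis; defaults to `phantom$field_x`.
#' @return Relative dose (unitless), same length as `x`.
#' @export
profile_model <- function(x, depth, config, phantom = phantom_spec(),
                          constants = dose_model_constants(),
                          field = phantom$field_x) {
  stopifnot(inherits(config, "beam_config"), length(depth) == 1L)
  if (depth < 0) stop("'depth' must be >= 0")
  W <- field * (phantom$ssd + depth) / phantom$ssd
  sigma <- constants$sigma0 +
    constants$sigma_spot_coeff * config$focal_spot_fwhm *
      (phantom$ssd + depth) / phantom$ssd +
    constants$sigma_depth_coeff * depth
  h <- constants$horn_base +
    constants$horn_divergence_coeff * config$divergence -
    constants$horn_fwhm_coeff * config$energy_fwhm
  base <- 0.5 * (erf((W / 2 - abs(x)) / (sqrt(2) * sigma)) +
                 erf((W / 2 + abs(x)) / (sqrt(2) * sigma)))
  # In-field flatness modulation, confined to the flat top (smoothly tapered
  # off before the shoulder) so it stays separable from the penumbra channel:
  # the energy spread / divergence signature must not imitate a focal-spot
  # change, otherwise the serial tuning stages cannot identify the parameters.
  r <- abs(2 * x / W)
  taper <- ifelse(r <= 0.7, 1,
                  ifelse(r >= 0.9, 0, cos(pi / 2 * (r - 0.7) / 0.2)^2))
  base * (1 + h * (2 * x / W)^2 * taper)
}

#' Simulate a noisy 3D dose grid
#'
#' Noiseless voxel dose is the separable product of the depth-dose model and
#' the two lateral-profile models evaluated at the voxel centre. Each voxel is
#' assigned a relative 1-sigma uncertainty
#' `u = kappa / sqrt((n_histories/1e6) * max(D/Dmax, dose_floor))` percent and
#' a sampled dose `D * (1 + u/100 * eps)` with independent standard-normal
#' `eps` from a private seeded stream (negative samples are clamped to zero).
#' Identical inputs give bit-identical grids.
#'
#' @param config A [beam_config()].
#' @param phantom A [phantom_spec()].
#' @param n_histories Number of simulated histories (>= 1).
#' @param seed Integer seed for the noise stream.
#' @param constants A [dose_model_constants()]; `kappa = 0` gives the
#'   noiseless dose exactly.
#' @return An object of class `dose_grid` with 3D arrays `dose` and
#'   `rel_uncertainty` (percent) indexed `[ix, iy, iz]`.
#' @export
generate_dose_grid <- function(config, phantom = phantom_spec(),
                               n_histories, seed = 1L,
                               constants = dose_model_constants()) {
  stopifnot(inherits(config, "beam_config"), inherits(phantom, "phantom_spec"))
  if (n_histories < 1) stop("'n_histories' must be >= 1")
  ax <- phantom_axes(phantom)
  pdd <- pdd_model(ax$z, config, constants)
  px <- vapply(ax$z, function(z)
    profile_model(ax$x, z, config, phantom, constants, field = phantom$field_x),
    numeric(phantom$nx))
  py <- vapply(ax$z, function(z)
    profile_model(ax$y, z, config, phantom, constants, field = phantom$field_y),
    numeric(phantom$ny))
  dose <- array(0, dim = c(phantom$nx, phantom$ny, phantom$nz))
  for (k in seq_len(phantom$nz))
    dose[, , k] <- outer(px[, k], py[, k]) * pdd[k]
  dmax <- max(dose)
  if (dmax <= 0) stop("degenerate model dose: maximum is not positive")
  u <- constants$kappa /
    sqrt((n_histories / 1e6) * pmax(dose / dmax, constants$dose_floor))
  expected <- dose
  if (constants$kappa > 0) {
    eps <- with_local_seed(seed, stats::rnorm(length(dose)))
    dose <- pmax(dose * (1 + (u / 100) * array(eps, dim = dim(dose))), 0)
  }
  structure(
    list(dose = dose, rel_uncertainty = u, expected_dose = expected,
         phantom = phantom,
         config = config, constants = constants,
         n_histories = n_histories, seed = as.integer(seed)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>\n")
  cat(sprintf("  %d x %d x %d voxels, bin %.2f cm\n",
              x$phantom$nx, x$phantom$ny, x$phantom$nz, x$phantom$bin))
  cat(sprintf("  %.3g histories, seed %d\n", x$n_histories, x$seed))
  cat(sprintf("  average uncertainty (high-dose voxels): %.2f%%\n",
              tryCatch(average_uncertainty(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Average statistical dose uncertainty of a grid
#'
#' Mean relative 1-sigma uncertainty over the voxels whose dose exceeds a
#' fraction (default one half) of the grid's maximum dose — the usual way of
#' quoting a single uncertainty figure for a Monte-Carlo dose distribution
#' without letting near-zero-dose voxels dominate. The high-dose mask is
#' evaluated on the expected (noiseless) dose, so the reported figure depends
#' on the statistics only through the 1/sqrt(histories) law, not through
#' which voxels happen to fluctuate past the threshold.
#'
#' @param grid A `dose_grid`.
#' @param threshold Fraction of the maximum dose; defaults to the value stored
#'   in the grid's model constants.
#' @return Average uncertainty in percent.
#' @export
average_uncertainty <- function(grid, threshold = grid$constants$uncertainty_threshold) {
  stopifnot(inherits(grid, "dose_grid"))
  mask <- grid$expected_dose > threshold * max(grid$expected_dose)
  if (!any(mask)) stop("degenerate grid: no voxel above the dose threshold")
  mean(grid$rel_uncertainty[mask])
}

#' Generate golden reference scans from a known beam configuration
#'
#' Produces the noiseless depth-dose curve and lateral profiles a water-tank
#' measurement of the modelled machine would yield: curves sampled at the
#' phantom bin pitch, the depth dose normalised to 100 at its maximum and each
#' profile to 100 on the central axis. The generating ("true") configuration
#' is retained so recovery experiments can score themselves.
#'
#' @param true_config The hidden generating [beam_config()].
#' @param phantom A [phantom_spec()].
#' @param scan_depths Strictly increasing profile scan depths in cm.
#' @param constants A [dose_model_constants()].
#' @param label Free-text label, e.g. `"6MV-like"`.
#' @return An object of class `reference_scans` with elements `pdd`
#'   (a [scan_curve()]), `profiles` (list of `list(depth, curve)`), `label`
#'   and `true_config`.
#' @export
generate_reference_scans <- function(true_config, phantom = phantom_spec(),
                                     scan_depths = c(1.6, 5, 10, 20, 30),
                                     constants = dose_model_constants(),
                                     label = "synthetic") {
  stopifnot(inherits(true_config, "beam_config"))
  if (length(scan_depths) < 1 || any(diff(scan_depths) <= 0))
    stop("'scan_depths' must be nonempty and strictly increasing")
  if (any(scan_depths < 0 | scan_depths > phantom$size_z))
    stop("'scan_depths' must lie inside the phantom")
  ax <- phantom_axes(phantom)
  # central-axis dose of the full model: depth dose times the on-axis value of
  # each lateral factor (a depth-dose scan is measured on the axis of a finite
  # field, so the off-axis envelope at x = y = 0 belongs in it)
  axis_dose <- pdd_model(ax$z, true_config, constants) *
    vapply(ax$z, function(z)
      profile_model(0, z, true_config, phantom, constants,
                    field = phantom$field_x) *
      profile_model(0, z, true_config, phantom, constants,
                    field = phantom$field_y), numeric(1))
  pdd <- scan_curve("pdd", positions = ax$z, values = axis_dose,
                    normalization = "pdd_max_100")
  profiles <- lapply(scan_depths, function(d) {
    vals <- profile_model(ax$x, d, true_config, phantom,
                          constants, field = phantom$field_x)
    list(depth = d,
         curve = scan_curve("lateral", positions = ax$x, values = vals,
                            depth = d, normalization = "cax_100"))
  })
  structure(
    list(pdd = pdd, profiles = profiles, label = label,
         true_config = true_config, phantom = phantom, constants = constants),
    class = "reference_scans"
  )
}

#' @export
print.reference_scans <- function(x, ...) {
  cat(sprintf("<reference_scans> '%s'\n", x$label))
  cat(sprintf("  PDD: %d points, 0-%.1f cm\n", length(x$pdd$positions),
              max(x$pdd$positions)))
  cat(sprintf("  profiles at depths: %s cm\n",
              paste(vapply(x$profiles, function(p) format(p$depth), ""),
                    collapse = ", ")))
  invisible(x)
}
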