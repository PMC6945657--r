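#' Initial electron-beam configuration
#'
#' Bundle of the four tunable parameters of the primary electron beam striking
#' the target: the mean energy, the FWHM of the primary energy distribution,
#' the focal-spot FWHM and the beam divergence. These are the quantities a
#' commissioning workflow adjusts until simulated depth-dose and lateral
#' profiles reproduce the measured scans.
#'
#' @param energy Initial electron-beam energy in MeV. Must be positive.
#' @param energy_fwhm FWHM of the primary energy distribution in MeV (>= 0).
#' @param focal_spot_fwhm Focal-spot FWHM in cm (>= 0).
#' @param divergence Beam divergence in degrees, in [0, 90).
#'
#' @return An object of class `beam_config`.
#' @examples
#' beam_config(6.26, energy_fwhm = 0.150, focal_spot_fwhm = 0.15, divergence = 3)
#' @export
beam_config <- function(energy, energy_fwhm = 0, focal_spot_fwhm = 0,
                        divergence = 0) {
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
  if (energy <= 0) stop("'energy' must be positive (MeV)")
  if (energy_fwhm < 0) stop("'energy_fwhm' must be >= 0 (MeV)")
  if (focal_spot_fwhm < 0) stop("'focal_spot_fwhm' must be >= 0 (cm)")
  if (divergence < 0 || divergence >= 90)
    stop("'divergence' must lie in [0, 90) degrees")
  structure(
    list(energy = energy, energy_fwhm = energy_fwhm,
         focal_spot_fwhm = focal_spot_fwhm, divergence = divergence),
    class = "beam_config"
  )
}

#' @export
print.beam_config <- function(x, ...) {
  cat("<beam_config>\n")
  cat(sprintf("  energy:          %g MeV\n", x$energy))
  cat(sprintf("  energy FWHM:     %g MeV\n", x$energy_fwhm))
  cat(sprintf("  focal spot FWHM: %g cm\n", x$focal_spot_fwhm))
  cat(sprintf("  divergence:      %g deg\n", x$divergence))
  invisible(x)
}

#' Water-phantom and field geometry
#'
#' Describes the binned water phantom on which dose is tallied and the single
#' rectangular field irradiating it. Defaults correspond to a 16.2 x 16.2 x
#' 31.0 cm^3 phantom with 0.2 cm cubic bins at 100 cm source-to-surface
#' distance and a 10 x 10 cm^2 field.
#'
#' @param size_x,size_y,size_z Phantom dimensions in cm.
#' @param bin Cubic bin side in cm; each size must be an integer multiple.
#' @param ssd Source-to-surface distance in cm.
#' @param field_x,field_y Field sides in cm, defined at the surface.
#'
#' @return An object of class `phantom_spec` with bin counts `nx`, `ny`, `nz`.
#' @export
phantom_spec <- function(size_x = 16.2, size_y = 16.2, size_z = 31.0,
                         bin = 0.2, ssd = 100.0,
                         field_x = 10, field_y = 10) {
  vals <- c(size_x = size_x, size_y = size_y, size_z = size_z, bin = bin,
            ssd = ssd, field_x = field_x, field_y = field_y)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all phantom dimensions must be positive and finite")
  n <- c(size_x, size_y, size_z) / bin
  if (any(abs(n - round(n)) > 1e-9))
    stop("each phantom size must be an integer multiple of 'bin'")
  structure(
    list(size_x = size_x, size_y = size_y, size_z = size_z, bin = bin,
         ssd = ssd, field_x = field_x, field_y = field_y,
         nx = as.integer(round(n[1])), ny = as.integer(round(n[2])),
         nz = as.integer(round(n[3]))),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  phantom: %.1f x %.1f x %.1f cm^3, bin %.2f cm (%d x %d x %d)\n",
              x$size_x, x$size_y, x$size_z, x$bin, x$nx, x$ny, x$nz))
  cat(sprintf("  SSD %.1f cm, field %.1f x %.1f cm^2\n",
              x$ssd, x$field_x, x$field_y))
  invisible(x)
}

# Voxel-centre coordinates. Lateral axes are centred on the beam axis; depth z
# runs from the surface downward. Centres sit at (i - 1/2) * bin.
phantom_axes <- function(phantom) {
  list(
    x = (seq_len(phantom$nx) - 0.5) * phantom$bin - phantom$size_x / 2,
    y = (seq_len(phantom$ny) - 0.5) * phantom$bin - phantom$size_y / 2,
    z = (seq_len(phantom$nz) - 0.5) * phantom$bin
  )
}

#' Constants of the parametric dose and noise model
#'
#' All coefficients of the analytic depth-dose / lateral-profile model and of
#' the statistical-noise law, collected in one configurable object. The depth
#' dose is A (1 - exp(-beta z)) exp(-mu z) with mu(E) = mu_coeff / E *
#' (1 + mu_fwhm_coeff * energy_fwhm / E) and beta(E) = beta_coeff / E.
#' Lateral profiles are an error-function flat-top of projected width W with
#' penumbra sigma = sigma0 + sigma_spot_coeff * focal_spot_fwhm * (ssd + z)/ssd
#' + sigma_depth_coeff * z and an in-field horn multiplier 1 + h (2x/W)^2
#' (smoothly tapered off over the outer fifth of the flat top, so the horn
#' channel stays separable from the penumbra channel), with
#' h = horn_base + horn_divergence_coeff * divergence - horn_fwhm_coeff *
#' energy_fwhm. Per-voxel relative 1-sigma uncertainty follows
#' u = kappa / sqrt((n_histories / 1e6) * max(D / Dmax, dose_floor)) percent.
#'
#' @param mu_coeff,mu_fwhm_coeff Attenuation-law coefficients (cm^-1 MeV, unitless).
#' @param beta_coeff Build-up coefficient (cm^-1 MeV).
#' @param amplitude Overall dose amplitude (arbitrary units).
#' @param sigma0 Penumbra width at the surface for a point source, cm.
#' @param sigma_spot_coeff Focal-spot contribution to the penumbra (unitless).
#' @param sigma_depth_coeff In-water penumbra growth, cm per cm depth.
#' @param horn_base,horn_divergence_coeff,horn_fwhm_coeff Horn-amplitude law.
#' @param kappa Noise constant, percent at 1e6 histories for the maximum-dose voxel.
#' @param dose_floor Relative-dose floor in the uncertainty law (avoids blow-up
#'   outside the field).
#' @param uncertainty_threshold Fraction of the maximum dose above which voxels
#'   enter the average-uncertainty report.
#'
#' @return An object of class `dose_model_constants`.
#' @export
dose_model_constants <- function(mu_coeff = 0.28, mu_fwhm_coeff = 0.05,
                                 beta_coeff = 13.6, amplitude = 1,
                                 sigma0 = 0.3, sigma_spot_coeff = 0.5,
                                 sigma_depth_coeff = 0.02,
                                 horn_base = 0.01,
                                 horn_divergence_coeff = 0.02,
                                 horn_fwhm_coeff = 0.3,
                                 kappa = 25,
                                 dose_floor = 0.01,
                                 uncertainty_threshold = 0.5) {
  out <- list(mu_coeff = mu_coeff, mu_fwhm_coeff = mu_fwhm_coeff,
              beta_coeff = beta_coeff, amplitude = amplitude,
              sigma0 = sigma0, sigma_spot_coeff = sigma_spot_coeff,
              sigma_depth_coeff = sigma_depth_coeff,
              horn_base = horn_base,
              horn_divergence_coeff = horn_divergence_coeff,
              horn_fwhm_coeff = horn_fwhm_coeff,
              kappa = kappa, dose_floor = dose_floor,
              uncertainty_threshold = uncertainty_threshold)
  if (any(!vapply(out, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("all model constants must be finite scalars")
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (dose_floor <= 0) stop("'dose_floor' must be positive")
  if (uncertainty_threshold <= 0 || uncertainty_threshold >= 1)
    stop("'uncertainty_threshold' must lie in (0, 1)")
  structure(out, class = "dose_model_constants")
}

#' Read or write a model configuration file
#'
#' The model constants and phantom geometry round-trip through a plain YAML
#' file, so a whole study setup can be kept under version control.
#'
#' @param path File path.
#' @param constants A `dose_model_constants` object.
#' @param phantom A `phantom_spec` object.
#' @return `read_model_config()` returns `list(constants, phantom)`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(path, constants = dose_model_constants(),
                               phantom = phantom_spec()) {
  cfg <- list(
    constants = unclass(constants),
    phantom = unclass(phantom)[c("size_x", "size_y", "size_z", "bin",
                                 "ssd", "field_x", "field_y")]
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constants) || is.null(cfg$phantom))
    stop("model config must contain 'constants' and 'phantom' blocks")
  list(
    constants = do.call(dose_model_constants, cfg$constants),
    phantom = do.call(phantom_spec, cfg$phantom)
  )
}
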