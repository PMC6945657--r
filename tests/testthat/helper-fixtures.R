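# Shared helpers: a small fast phantom, raw-curve builders and independent
# brute-force gamma oracles used to cross-check the engine.

tiny_phantom <- function() {
  phantom_spec(size_x = 6.2, size_y = 6.2, size_z = 15, bin = 0.2,
               ssd = 100, field_x = 4, field_y = 4)
}

raw_curve <- function(positions, values, kind = "pdd") {
  scan_curve(kind, positions = positions, values = values,
             normalization = "none")
}

# Independent 1D gamma oracle: dense exhaustive search on a refine-fold finer
# lattice, straight transcription of the definition.
brute_gamma_1d <- function(reference, evaluated, criteria, refine = 50) {
  window <- min(5 * criteria$dta_mm / 10, criteria$search_cap_cm)
  step <- evaluated$spacing / refine
  ref_max <- max(reference$values)
  vapply(seq_along(reference$positions), function(i) {
    p <- reference$positions[i]
    lo <- max(p - window, min(evaluated$positions))
    hi <- min(p + window, max(evaluated$positions))
    if (lo > hi) return(NA_real_)
    xs <- seq(lo, hi, by = step)
    vals <- stats::approx(evaluated$positions, evaluated$values, xout = xs)$y
    min(sqrt(((vals - reference$values[i]) /
                (criteria$dose_pct / 100 * ref_max))^2 +
             ((xs - p) / (criteria$dta_mm / 10))^2))
  }, numeric(1))
}

brute_rate_1d <- function(reference, evaluated, criteria, refine = 50) {
  gam <- brute_gamma_1d(reference, evaluated, criteria, refine)
  100 * sum(gam <= 1, na.rm = TRUE) / sum(!is.na(gam))
}

# Independent 3D gamma oracle: exhaustive search over a 1/refine-bin lattice
# inside the search window, trilinear interpolation done long-hand per point.
brute_gamma_3d <- function(reference_points, grid, criteria, refine = 50) {
  window <- min(5 * criteria$dta_mm / 10, criteria$search_cap_cm)
  ph <- grid$phantom
  ax <- list(x = (seq_len(ph$nx) - 0.5) * ph$bin - ph$size_x / 2,
             y = (seq_len(ph$ny) - 0.5) * ph$bin - ph$size_y / 2,
             z = (seq_len(ph$nz) - 0.5) * ph$bin)
  step <- ph$bin / refine
  lin1 <- function(coord, centers) {
    i <- pmin(pmax(findInterval(coord, centers), 1L), length(centers) - 1L)
    w <- (coord - centers[i]) / (centers[i + 1] - centers[i])
    list(i = i, w = w)
  }
  ref_max <- max(reference_points$dose)
  vapply(seq_len(nrow(reference_points)), function(r) {
    p <- reference_points[r, ]
    axis_pts <- function(c0, centers) {
      lo <- max(c0 - window, centers[1]); hi <- min(c0 + window, centers[length(centers)])
      seq(lo, hi, by = step)
    }
    fx <- axis_pts(p$x, ax$x); fy <- axis_pts(p$y, ax$y); fz <- axis_pts(p$z, ax$z)
    cand <- expand.grid(x = fx, y = fy, z = fz, KEEP.OUT.ATTRS = FALSE)
    d2 <- (cand$x - p$x)^2 + (cand$y - p$y)^2 + (cand$z - p$z)^2
    cand <- cand[d2 <= window^2, ]; d2 <- d2[d2 <= window^2]
    gx <- lin1(cand$x, ax$x); gy <- lin1(cand$y, ax$y); gz <- lin1(cand$z, ax$z)
    g <- function(dx, dy, dz) grid$dose[cbind(gx$i + dx, gy$i + dy, gz$i + dz)]
    v <- (1 - gx$w) * ((1 - gy$w) * ((1 - gz$w) * g(0,0,0) + gz$w * g(0,0,1)) +
                       gy$w * ((1 - gz$w) * g(0,1,0) + gz$w * g(0,1,1))) +
         gx$w * ((1 - gy$w) * ((1 - gz$w) * g(1,0,0) + gz$w * g(1,0,1)) +
                 gy$w * ((1 - gz$w) * g(1,1,0) + gz$w * g(1,1,1)))
    min(sqrt(((v - p$dose) / (criteria$dose_pct / 100 * ref_max))^2 +
             d2 / (criteria$dta_mm / 10)^2))
  }, numeric(1))
}

# 80-20% penumbra width of the analytic profile on one side, by root finding.
penumbra_width <- function(config, depth, phantom = phantom_spec(),
                           constants = dose_model_constants()) {
  cax <- profile_model(0, depth, config, phantom, constants)
  level_x <- function(frac) {
    stats::uniroot(function(x)
      profile_model(x, depth, config, phantom, constants) - frac * cax,
      lower = 0, upper = phantom$size_x / 2, tol = 1e-10)$root
  }
  level_x(0.2) - level_x(0.8)
}

cax_value_for_test <- function(curve) curve$values[which.min(abs(curve$positions))]
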