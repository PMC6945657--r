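# Gamma-index engine: dose-difference / distance-to-agreement comparison of a
# reference (measured) distribution with an evaluated (simulated) one.

#' Gamma acceptance criteria
#'
#' The (dose difference, distance-to-agreement) pair of a gamma comparison,
#' e.g. 3%/3 mm. The dose tolerance is interpreted globally, as a percentage
#' of the maximum of the reference distribution (a local mode is available in
#' [gamma_curve()]). Candidate points are searched within
#' `min(5 * dta, search_cap_cm)` of each reference point, on the evaluated
#' distribution refined `resample_factor`-fold by linear interpolation.
#'
#' @param dose_pct Dose-difference tolerance in percent of the global
#'   reference maximum (> 0).
#' @param dta_mm Distance-to-agreement tolerance in mm (> 0).
#' @param search_cap_cm Hard cap on the candidate search radius, cm.
#' @param resample_factor Refinement factor for the evaluated distribution.
#' @return An object of class `gamma_criteria`.
#' @examples
#' gamma_criteria(1, 1)   # the strict 1%/1 mm criteria
#' @export
gamma_criteria <- function(dose_pct, dta_mm, search_cap_cm = 1.5,
                           resample_factor = 5L) {
  if (dose_pct <= 0) stop("'dose_pct' must be > 0")
  if (dta_mm <= 0) stop("'dta_mm' must be > 0")
  if (search_cap_cm <= 0) stop("'search_cap_cm' must be > 0")
  if (resample_factor < 1) stop("'resample_factor' must be >= 1")
  structure(
    list(dose_pct = dose_pct, dta_mm = dta_mm,
         search_cap_cm = search_cap_cm,
         resample_factor = as.integer(resample_factor)),
    class = "gamma_criteria"
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm (search cap %g cm, x%d refinement)\n",
              x$dose_pct, x$dta_mm, x$search_cap_cm, x$resample_factor))
  invisible(x)
}

#' Candidate search window of a gamma comparison
#'
#' The search for the best-agreeing evaluated point extends to five times the
#' distance-to-agreement tolerance, hard-capped (by default at 1.5 cm).
#'
#' @param criteria A [gamma_criteria()].
#' @return Search half-width in cm.
#' @export
gamma_search_window <- function(criteria) {
  min(5 * criteria$dta_mm / 10, criteria$search_cap_cm)
}

#' Gamma index at a single reference point
#'
#' `Gamma = min_i sqrt((dd_i / DD)^2 + (ds_i / DS)^2)` over the evaluated
#' points within the search window of the reference position, where `dd_i` is
#' the evaluated-minus-reference dose difference and `ds_i` the spatial
#' separation. The evaluated curve should already be refined (see
#' [resample_curve()]); [gamma_curve()] does this for you.
#'
#' @param ref_position Reference position in cm.
#' @param ref_dose Reference dose in percent.
#' @param evaluated A [scan_curve()], typically resampled.
#' @param criteria A [gamma_criteria()].
#' @param ref_max Global maximum of the reference distribution (percent);
#'   sets the absolute dose tolerance `dose_pct/100 * ref_max`.
#' @param local If `TRUE`, the dose tolerance is `dose_pct`% of the local
#'   reference dose instead.
#' @return The gamma value (>= 0), or `NA` when no evaluated point lies
#'   within the search window (an uncovered reference point).
#' @export
gamma_point <- function(ref_position, ref_dose, evaluated, criteria,
                        ref_max = 100, local = FALSE) {
  stopifnot(inherits(evaluated, "scan_curve"), inherits(criteria, "gamma_criteria"))
  window <- gamma_search_window(criteria)
  sel <- which(abs(evaluated$positions - ref_position) <= window + 1e-12)
  if (length(sel) == 0L) return(NA_real_)
  tol_dose <- if (local) criteria$dose_pct / 100 * ref_dose
              else criteria$dose_pct / 100 * ref_max
  if (tol_dose <= 0) return(NA_real_)
  dd <- (evaluated$values[sel] - ref_dose) / tol_dose
  ds <- (evaluated$positions[sel] - ref_position) / (criteria$dta_mm / 10)
  sqrt(min(dd^2 + ds^2))
}

#' Gamma comparison of two scan curves
#'
#' Refines the evaluated curve by the criteria's resample factor, computes the
#' gamma index at every reference point and summarises the passing rate under
#' the rule that a point passes when its gamma is less than or equal to 1.
#' Reference points whose search window contains no evaluated point are
#' tallied as uncovered and excluded from the denominator.
#'
#' @param reference,evaluated [scan_curve()]s of the same kind and
#'   normalisation convention; the evaluated curve must overlap at least half
#'   of the reference positions.
#' @param criteria A [gamma_criteria()].
#' @param local Use local instead of global dose normalisation.
#' @return An object of class `gamma_result` with `gamma_values` (NA for
#'   uncovered points), `n_points`, `n_pass`, `n_uncovered` and
#'   `passing_rate` (percent).
#' @export
gamma_curve <- function(reference, evaluated, criteria, local = FALSE) {
  stopifnot(inherits(reference, "scan_curve"), inherits(evaluated, "scan_curve"))
  if (reference$kind != evaluated$kind)
    stop("reference and evaluated curves must be of the same kind")
  if (reference$normalization != evaluated$normalization)
    stop("reference and evaluated curves must share a normalisation convention")
  covered <- reference$positions >= min(evaluated$positions) &
             reference$positions <= max(evaluated$positions)
  if (mean(covered) < 0.5)
    stop("evaluated curve overlaps less than half of the reference positions")
  ev <- resample_curve(evaluated, criteria$resample_factor)
  ref_max <- max(reference$values)
  gam <- vapply(seq_along(reference$positions), function(i)
    gamma_point(reference$positions[i], reference$values[i], ev, criteria,
                ref_max = ref_max, local = local),
    numeric(1))
  summarize_gamma(gam, criteria)
}

summarize_gamma <- function(gam, criteria) {
  n_unc <- sum(is.na(gam))
  n_points <- length(gam) - n_unc
  n_pass <- sum(gam <= 1, na.rm = TRUE)
  structure(
    list(gamma_values = gam, criteria = criteria,
         n_points = n_points, n_pass = n_pass, n_uncovered = n_unc,
         passing_rate = if (n_points > 0) 100 * n_pass / n_points else NA_real_),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: %d/%d pass (%.1f%%)",
              x$criteria$dose_pct, x$criteria$dta_mm,
              x$n_pass, x$n_points, x$passing_rate))
  if (x$n_uncovered > 0) cat(sprintf(", %d uncovered", x$n_uncovered))
  cat("\n")
  invisible(x)
}

#' Passing rates under the three standard criteria
#'
#' Runs [gamma_curve()] at 3%/3 mm, 2%/2 mm and 1%/1 mm and returns the three
#' passing rates, the layout used throughout beam-commissioning comparisons.
#' By criteria nesting the rates are non-increasing from loosest to strictest.
#'
#' @inheritParams gamma_curve
#' @return Named numeric vector `c(rate_3_3, rate_2_2, rate_1_1)` in percent.
#' @export
multi_criteria_report <- function(reference, evaluated, local = FALSE) {
  rates <- vapply(list(gamma_criteria(3, 3), gamma_criteria(2, 2),
                       gamma_criteria(1, 1)),
                  function(cr) gamma_curve(reference, evaluated, cr,
                                           local = local)$passing_rate,
                  numeric(1))
  names(rates) <- c("rate_3_3", "rate_2_2", "rate_1_1")
  rates
}

# Trilinear interpolation of a dose grid at arbitrary points (voxel-centre
# coordinates). Points outside the centre lattice return NA.
interp_grid <- function(grid, x, y, z) {
  ax <- phantom_axes(grid$phantom)
  tri1 <- function(coord, centers) {
    i <- findInterval(coord, centers)
    bad <- i < 1L | i >= length(centers)
    exact_hi <- coord == centers[length(centers)]
    i[exact_hi] <- length(centers) - 1L
    bad <- bad & !exact_hi
    i[bad] <- 1L
    w <- (coord - centers[i]) / (centers[i + 1L] - centers[i])
    list(i = i, w = w, bad = bad)
  }
  gx <- tri1(x, ax$x); gy <- tri1(y, ax$y); gz <- tri1(z, ax$z)
  d <- grid$dose
  idx <- function(dx, dy, dz)
    d[cbind(gx$i + dx, gy$i + dy, gz$i + dz)]
  v <- (1 - gx$w) * ((1 - gy$w) * ((1 - gz$w) * idx(0, 0, 0) + gz$w * idx(0, 0, 1)) +
                     gy$w       * ((1 - gz$w) * idx(0, 1, 0) + gz$w * idx(0, 1, 1))) +
       gx$w       * ((1 - gy$w) * ((1 - gz$w) * idx(1, 0, 0) + gz$w * idx(1, 0, 1)) +
                     gy$w       * ((1 - gz$w) * idx(1, 1, 0) + gz$w * idx(1, 1, 1)))
  v[gx$bad | gy$bad | gz$bad] <- NA_real_
  v
}

#' Gamma comparison of reference points against a 3D dose grid
#'
#' 3D analogue of [gamma_curve()]: the evaluated grid is virtually refined to
#' `1/resample_factor` of the bin size in each direction by trilinear
#' interpolation, and for each reference point the gamma minimum is taken
#' over the refined points within Euclidean distance `min(5 dta, cap)`.
#'
#' @param reference_points A data frame with columns `x`, `y`, `z` (cm, in
#'   voxel-centre coordinates) and `dose` (percent).
#' @param evaluated A `dose_grid` whose dose is on the same percent scale as
#'   the reference points.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result`.
#' @export
gamma_grid <- function(reference_points, evaluated, criteria) {
  stopifnot(is.data.frame(reference_points),
            all(c("x", "y", "z", "dose") %in% names(reference_points)),
            inherits(evaluated, "dose_grid"))
  window <- gamma_search_window(criteria)
  step <- evaluated$phantom$bin / criteria$resample_factor
  ax <- phantom_axes(evaluated$phantom)
  rng <- lapply(ax, range)
  fine_axis <- function(center, lim) {
    lo <- max(center - window, lim[1])
    hi <- min(center + window, lim[2])
    if (lo > hi) return(numeric(0))
    # fine lattice anchored on the voxel-centre grid
    k <- seq(ceiling((lo - lim[1]) / step - 1e-9),
             floor((hi - lim[1]) / step + 1e-9))
    lim[1] + k * step
  }
  ref_max <- max(reference_points$dose)
  tol_dose <- criteria$dose_pct / 100 * ref_max
  dta_cm <- criteria$dta_mm / 10
  gam <- vapply(seq_len(nrow(reference_points)), function(r) {
    p <- reference_points[r, ]
    fx <- fine_axis(p$x, rng$x); fy <- fine_axis(p$y, rng$y); fz <- fine_axis(p$z, rng$z)
    if (!length(fx) || !length(fy) || !length(fz)) return(NA_real_)
    cand <- expand.grid(x = fx, y = fy, z = fz, KEEP.OUT.ATTRS = FALSE)
    dist2 <- (cand$x - p$x)^2 + (cand$y - p$y)^2 + (cand$z - p$z)^2
    keep <- dist2 <= window^2 + 1e-12
    if (!any(keep)) return(NA_real_)
    cand <- cand[keep, ]
    dist2 <- dist2[keep]
    dv <- interp_grid(evaluated, cand$x, cand$y, cand$z)
    ok <- !is.na(dv)
    if (!any(ok)) return(NA_real_)
    sqrt(min(((dv[ok] - p$dose) / tol_dose)^2 + dist2[ok] / dta_cm^2))
  }, numeric(1))
  summarize_gamma(gam, criteria)
}
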