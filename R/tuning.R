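# Decision procedures of the truncated fine-tuning workflow: Pearson-trend
# selection of the initial electron-beam energy from low-statistics history
# sweeps, and the three-stage serial grid search over the remaining beam
# parameters.

#' Pearson correlation with the contracts a trend analysis needs
#'
#' Sample product-moment correlation between two equal-length vectors, with
#' explicit errors for the degenerate cases (fewer than three points, zero
#' variance) instead of `NA` propagation. The trend rule correlates the
#' average dose uncertainty of a history sweep with its 1%/1 mm passing rate.
#'
#' @param xs,ys Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient in [-1, 1].
#' @examples
#' pearson(c(36.4, 18.0, 12.1, 7.9, 4.1), c(17.5, 24.7, 38.0, 74.7, 84.1))
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("'xs' and 'ys' must have equal length")
  if (length(xs) < 3L) stop("need at least 3 points for a correlation")
  if (any(!is.finite(xs)) || any(!is.finite(ys)))
    stop("inputs must be finite")
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("undefined correlation: an input has zero variance")
  stats::cor(xs, ys)
}

#' Assemble a history-sweep trend record for one energy candidate
#'
#' Collects the per-rung results of a history sweep (number of histories,
#' average dose uncertainty, passing rates at 3%/3 mm, 2%/2 mm and 1%/1 mm)
#' and computes the Pearson correlation between the uncertainty and the
#' 1%/1 mm rate — the signature that distinguishes a matching energy
#' configuration (strong negative correlation) from a mismatched one.
#'
#' @param candidate_label Label for the candidate, e.g. `"6.26 MeV"`.
#' @param sweep Data frame with columns `n_histories`, `avg_uncertainty`,
#'   `rate_3_3`, `rate_2_2`, `rate_1_1`; at least 3 rows, `n_histories`
#'   strictly increasing.
#' @param energy Candidate energy in MeV (optional metadata).
#' @return An object of class `trend_record` with `pearson_r` and
#'   `final_rate_1_1` (the 1%/1 mm rate of the last, highest-statistics rung).
#' @export
build_trend <- function(candidate_label, sweep, energy = NA_real_) {
  need <- c("n_histories", "avg_uncertainty", "rate_3_3", "rate_2_2", "rate_1_1")
  if (!is.data.frame(sweep) || !all(need %in% names(sweep)))
    stop("'sweep' must be a data frame with columns: ",
         paste(need, collapse = ", "))
  if (nrow(sweep) < 3L) stop("a trend needs at least 3 sweep rows")
  if (any(diff(sweep$n_histories) <= 0))
    stop("'n_histories' must be strictly increasing")
  structure(
    list(candidate_label = as.character(candidate_label), energy = energy,
         rows = sweep[, need],
         pearson_r = pearson(sweep$avg_uncertainty, sweep$rate_1_1),
         final_rate_1_1 = sweep$rate_1_1[nrow(sweep)]),
    class = "trend_record"
  )
}

#' @export
print.trend_record <- function(x, ...) {
  cat(sprintf("<trend_record> %s: %d rungs, r = %+.2f, final 1%%/1 mm rate %.1f%%\n",
              x$candidate_label, nrow(x$rows), x$pearson_r, x$final_rate_1_1))
  invisible(x)
}

#' Select the initial electron-beam energy from trend records
#'
#' A candidate qualifies when its uncertainty-vs-rate correlation is at least
#' as negative as `r_threshold` and its final 1%/1 mm passing rate reaches
#' `rate_threshold` — i.e. the passing rate climbs as statistics improve and
#' ends high. Among qualifiers the most negative correlation wins, ties going
#' to the higher final rate. When no candidate qualifies the function returns
#' a no-selection result with per-candidate diagnostics (the practical advice
#' then being to extend the sweep to more histories).
#'
#' @param trends List of [build_trend()] records.
#' @param r_threshold Qualification threshold on the Pearson correlation
#'   (default -0.80).
#' @param rate_threshold Qualification threshold on the final 1%/1 mm passing
#'   rate in percent (default 80).
#' @return An object of class `energy_selection` with `selected` (label or
#'   `NA`), `energy`, and a `diagnostics` data frame.
#' @export
select_energy <- function(trends, r_threshold = -0.80, rate_threshold = 80) {
  if (length(trends) < 1L) stop("'trends' must contain at least one record")
  stopifnot(all(vapply(trends, inherits, TRUE, "trend_record")))
  diag <- data.frame(
    candidate = vapply(trends, `[[`, "", "candidate_label"),
    energy = vapply(trends, `[[`, 0, "energy"),
    pearson_r = vapply(trends, `[[`, 0, "pearson_r"),
    final_rate_1_1 = vapply(trends, `[[`, 0, "final_rate_1_1")
  )
  diag$qualifies <- diag$pearson_r <= r_threshold &
                    diag$final_rate_1_1 >= rate_threshold
  sel <- NA_character_
  sel_energy <- NA_real_
  if (any(diag$qualifies)) {
    q <- diag[diag$qualifies, ]
    q <- q[order(q$pearson_r, -q$final_rate_1_1), ]
    sel <- q$candidate[1]
    sel_energy <- q$energy[1]
  }
  structure(
    list(selected = sel, energy = sel_energy, diagnostics = diag,
         r_threshold = r_threshold, rate_threshold = rate_threshold),
    class = "energy_selection"
  )
}

#' @export
print.energy_selection <- function(x, ...) {
  cat("<energy_selection>\n")
  print(x$diagnostics, row.names = FALSE)
  if (is.na(x$selected))
    cat(sprintf("  no candidate qualifies (need r <= %.2f and final rate >= %g%%);\n  extend the history sweep\n",
                x$r_threshold, x$rate_threshold))
  else cat(sprintf("  selected: %s\n", x$selected))
  invisible(x)
}

#' Arg-max stage of the serial profile optimisation
#'
#' For one tuning stage, each candidate value of a beam parameter carries its
#' 1%/1 mm passing rates against the measured profiles at every scan depth.
#' Each candidate is scored by its best depth (the depth where the comparison
#' is most favourable) and the candidate with the highest score is chosen,
#' ties breaking toward the smaller parameter value.
#'
#' @param parameter_name One of `"energy_fwhm"`, `"focal_spot_fwhm"`,
#'   `"divergence"`.
#' @param candidates Numeric candidate values of the parameter.
#' @param rates Either a numeric vector of per-candidate best-depth rates or a
#'   matrix with one row per candidate and one column per scan depth.
#' @return An object of class `stage_result` with `chosen_value`,
#'   `chosen_rate` and `best_depth_rates`.
#' @export
stage_argmax <- function(parameter_name = c("energy_fwhm", "focal_spot_fwhm",
                                            "divergence"),
                         candidates, rates) {
  parameter_name <- match.arg(parameter_name)
  if (length(candidates) < 1L) stop("need at least one candidate")
  if (is.matrix(rates)) {
    if (nrow(rates) != length(candidates))
      stop("'rates' must have one row per candidate")
    best <- apply(rates, 1, max)
  } else {
    if (length(rates) != length(candidates))
      stop("'rates' must have one value per candidate")
    best <- as.numeric(rates)
    rates <- NULL
  }
  top <- which(best >= max(best) - 1e-12)
  pick <- top[which.min(candidates[top])]
  structure(
    list(parameter_name = parameter_name, candidates = candidates,
         best_depth_rates = best, per_depth_rates = rates,
         chosen_value = candidates[pick], chosen_rate = best[pick]),
    class = "stage_result"
  )
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result> %s: chose %g (1%%/1 mm rate %.1f%%) of {%s}\n",
              x$parameter_name, x$chosen_value, x$chosen_rate,
              paste(x$candidates, collapse = ", ")))
  invisible(x)
}

#' Depth-by-depth comparison of two candidate configurations
#'
#' Counts, over the scan depths, how often each configuration strictly beats
#' the other on the 1%/1 mm passing rate. The majority wins; an equal count
#' is broken by the higher best single-depth rate, and a complete tie goes to
#' the first-declared candidate. This is the safeguard applied when a stage
#' arg-max is suspected of riding a single favourable depth.
#'
#' @param label_a,label_b Candidate labels.
#' @param rates_a,rates_b Equal-length per-depth 1%/1 mm rates in percent.
#' @param depths Optional scan depths in cm (metadata).
#' @return An object of class `depth_comparison` with `wins_a`, `wins_b`,
#'   `ties` and `winner`.
#' @export
cross_depth_compare <- function(label_a, rates_a, label_b, rates_b,
                                depths = NULL) {
  if (length(rates_a) != length(rates_b))
    stop("per-depth rate lists must have equal length")
  wins_a <- sum(rates_a > rates_b)
  wins_b <- sum(rates_b > rates_a)
  ties <- sum(rates_a == rates_b)
  winner <- if (wins_a > wins_b) label_a
            else if (wins_b > wins_a) label_b
            else if (max(rates_a) > max(rates_b)) label_a
            else if (max(rates_b) > max(rates_a)) label_b
            else label_a
  structure(
    list(label_a = label_a, label_b = label_b, depths = depths,
         rates_a = rates_a, rates_b = rates_b,
         wins_a = wins_a, wins_b = wins_b, ties = ties, winner = winner),
    class = "depth_comparison"
  )
}

#' @export
print.depth_comparison <- function(x, ...) {
  cat(sprintf("<depth_comparison> %s wins %d, %s wins %d, %d tie(s) -> winner %s\n",
              x$label_a, x$wins_a, x$label_b, x$wins_b, x$ties, x$winner))
  invisible(x)
}

# Deterministic 31-bit sub-seed for (stage/rung, candidate) under a master seed.
derive_seed <- function(master, stage, candidate) {
  as.integer((as.numeric(master) %% 65521 * 32452843 +
              stage * 104729 + candidate * 1299709) %% 2147483647) + 1L
}

default_simulator <- function(phantom, constants) {
  function(config, n_histories, seed)
    generate_dose_grid(config, phantom, n_histories, seed, constants)
}

#' History sweep of candidate initial energies against a reference PDD
#'
#' For each candidate energy and each rung of the history ladder, simulates a
#' dose grid (all other beam parameters at their default of zero), extracts
#' the central-axis depth-dose curve, compares it with the reference PDD under
#' the three standard criteria and records the average dose uncertainty. One
#' simulation is run per (candidate, rung) with a seed derived
#' deterministically from the master seed.
#'
#' @param reference A `reference_scans` object (or any list with a `$pdd`
#'   [scan_curve()]).
#' @param candidates Numeric candidate energies in MeV (names, if any, become
#'   the candidate labels).
#' @param history_ladder Strictly increasing history counts, >= 3 rungs
#'   (default 2e6, 1e7, 5e7).
#' @param phantom,constants Simulation geometry and model constants.
#' @param seed Master seed.
#' @param simulator Optional `function(config, n_histories, seed)` returning a
#'   `dose_grid`; defaults to [generate_dose_grid()].
#' @return A list of [build_trend()] records, one per candidate.
#' @export
run_energy_sweep <- function(reference, candidates,
                             history_ladder = c(2e6, 1e7, 5e7),
                             phantom = phantom_spec(),
                             constants = dose_model_constants(),
                             seed = 1L, simulator = NULL) {
  if (length(history_ladder) < 3L || any(diff(history_ladder) <= 0))
    stop("'history_ladder' must be strictly increasing with >= 3 rungs")
  if (is.null(simulator)) simulator <- default_simulator(phantom, constants)
  labels <- if (!is.null(names(candidates))) names(candidates)
            else sprintf("%.2f MeV", candidates)
  trends <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    rows <- lapply(seq_along(history_ladder), function(j) {
      grid <- simulator(beam_config(candidates[i]), history_ladder[j],
                        derive_seed(seed, j, i))
      rates <- multi_criteria_report(reference$pdd, extract_pdd(grid))
      data.frame(n_histories = history_ladder[j],
                 avg_uncertainty = average_uncertainty(grid),
                 rate_3_3 = rates[["rate_3_3"]],
                 rate_2_2 = rates[["rate_2_2"]],
                 rate_1_1 = rates[["rate_1_1"]])
    })
    trends[[i]] <- build_trend(labels[i], do.call(rbind, rows),
                               energy = candidates[i])
  }
  trends
}

#' Three-stage serial fine-tuning of the remaining beam parameters
#'
#' With the initial electron-beam energy fixed, optimises the energy FWHM,
#' then the focal-spot FWHM, then the beam divergence, each stage holding the
#' not-yet-tuned parameters at their default of zero and carrying the winners
#' forward. At every stage each candidate is simulated once at a fixed number
#' of histories, its lateral profiles are extracted at the reference scan
#' depths and compared at 1%/1 mm, and [stage_argmax()] picks the winner by
#' best-depth rate. Optionally the two leading stage-1 candidates are
#' re-examined depth by depth ([cross_depth_compare()]); if that overturns
#' the arg-max, stages 2-3 are restarted from the cross-depth winner.
#'
#' Within a stage all candidates share one noise seed (paired, common-random-
#' numbers comparison); different stages and different master seeds use
#' different streams. Set `seed_policy = "per-candidate"` for fully
#' independent simulations.
#'
#' @param reference A `reference_scans` object.
#' @param energy Fixed initial electron-beam energy in MeV.
#' @param grids Named list with numeric candidate vectors `energy_fwhm`,
#'   `focal_spot_fwhm` and `divergence`.
#' @param n_histories Histories per stage simulation (default 2.5e7).
#' @param criteria Gamma criteria used for stage scoring (default 1%/1 mm).
#' @param phantom,constants Simulation geometry and model constants.
#' @param seed Master seed.
#' @param seed_policy `"common"` (default) or `"per-candidate"`.
#' @param cross_depth_check Apply the depth-by-depth safeguard to the top two
#'   stage-1 candidates (default `FALSE`).
#' @param simulator Optional `function(config, n_histories, seed)` returning a
#'   `dose_grid`.
#' @return An object of class `tuning_audit` with `final_config`, the three
#'   `stages`, and `depth_comparison` (or `NULL`).
#' @export
run_staged_tuning <- function(reference, energy, grids,
                              n_histories = 2.5e7,
                              criteria = gamma_criteria(1, 1),
                              phantom = phantom_spec(),
                              constants = dose_model_constants(),
                              seed = 1L,
                              seed_policy = c("common", "per-candidate"),
                              cross_depth_check = FALSE,
                              simulator = NULL) {
  seed_policy <- match.arg(seed_policy)
  need <- c("energy_fwhm", "focal_spot_fwhm", "divergence")
  if (!all(need %in% names(grids)) ||
      any(vapply(grids[need], length, 0L) < 1L))
    stop("'grids' must contain nonempty candidate vectors: ",
         paste(need, collapse = ", "))
  if (is.null(simulator)) simulator <- default_simulator(phantom, constants)
  depths <- vapply(reference$profiles, `[[`, 0, "depth")

  run_stage <- function(stage_idx, parameter_name, candidates, fixed) {
    per_depth <- matrix(NA_real_, nrow = length(candidates),
                        ncol = length(depths))
    for (i in seq_along(candidates)) {
      cfg_args <- fixed
      cfg_args[[parameter_name]] <- candidates[i]
      cfg <- do.call(beam_config, c(list(energy = energy), cfg_args))
      s <- derive_seed(seed, stage_idx,
                       if (seed_policy == "common") 0L else i)
      grid <- tryCatch(simulator(cfg, n_histories, s), error = function(e)
        stop(sprintf("simulator failed in stage %d (%s = %g): %s",
                     stage_idx, parameter_name, candidates[i],
                     conditionMessage(e)), call. = FALSE))
      for (j in seq_along(depths)) {
        prof <- extract_profile(grid, depths[j])
        per_depth[i, j] <- gamma_curve(reference$profiles[[j]]$curve, prof,
                                       criteria)$passing_rate
      }
    }
    stage_argmax(parameter_name, candidates, per_depth)
  }

  run_from_stage1 <- function(efwhm_winner, stage1) {
    stage2 <- run_stage(2L, "focal_spot_fwhm", grids$focal_spot_fwhm,
                        list(energy_fwhm = efwhm_winner, divergence = 0))
    stage3 <- run_stage(3L, "divergence", grids$divergence,
                        list(energy_fwhm = efwhm_winner,
                             focal_spot_fwhm = stage2$chosen_value))
    list(stages = list(stage1, stage2, stage3),
         final = beam_config(energy, efwhm_winner, stage2$chosen_value,
                             stage3$chosen_value))
  }

  stage1 <- run_stage(1L, "energy_fwhm", grids$energy_fwhm,
                      list(focal_spot_fwhm = 0, divergence = 0))
  comparison <- NULL
  winner1 <- stage1$chosen_value
  if (cross_depth_check && length(grids$energy_fwhm) >= 2L) {
    ord <- order(stage1$best_depth_rates, decreasing = TRUE)
    a <- ord[1]; b <- ord[2]
    comparison <- cross_depth_compare(
      sprintf("%g", stage1$candidates[a]), stage1$per_depth_rates[a, ],
      sprintf("%g", stage1$candidates[b]), stage1$per_depth_rates[b, ],
      depths = depths)
    if (comparison$winner != sprintf("%g", stage1$candidates[a]))
      winner1 <- stage1$candidates[b]
  }
  res <- run_from_stage1(winner1, stage1)
  structure(
    list(final_config = res$final, stages = res$stages,
         depth_comparison = comparison, energy = energy,
         n_histories = n_histories, seed = seed, seed_policy = seed_policy),
    class = "tuning_audit"
  )
}

#' @export
print.tuning_audit <- function(x, ...) {
  cat("<tuning_audit>\n")
  for (s in x$stages) {
    cat("  "); print(s)
  }
  if (!is.null(x$depth_comparison)) { cat("  "); print(x$depth_comparison) }
  cat("  final configuration:\n")
  print(x$final_config)
  invisible(x)
}
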