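#!/usr/bin/env Rscript
# Thin command-line front end over the linactune package.
#
#   Rscript scripts/linactune.R simulate --energy 6.26 [--energy-fwhm F]
#       [--focal-spot F] [--divergence D] [--histories N] [--seed S]
#       [--model CONFIG.yml] --out-prefix PREFIX
#   Rscript scripts/linactune.R gamma --reference REF.csv --evaluated EV.csv
#       [--dose-pct P] [--dta-mm M] --out REPORT.json
#   Rscript scripts/linactune.R tune-energy --config SESSION.yml --out PREFIX
#   Rscript scripts/linactune.R tune-profiles --config SESSION.yml --out PREFIX
#   Rscript scripts/linactune.R reproduce-paper
#
# A session config (YAML) may contain: energy_candidates, history_ladder,
# energy (fixed, for tune-profiles), grids {energy_fwhm, focal_spot_fwhm,
# divergence}, n_histories, true_config {energy, energy_fwhm,
# focal_spot_fwhm, divergence}, scan_depths, seed.

suppressPackageStartupMessages(library(linactune))

args <- commandArgs(trailingOnly = TRUE)
fail <- function(...) { message(...); quit(status = 1L) }
if (length(args) < 1) fail("usage: linactune.R <subcommand> [options]")
cmd <- args[1]; args <- args[-1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
num <- function(flag, default) as.numeric(opt(flag, default))

run <- function(expr) {
  tryCatch(expr, error = function(e) fail("error: ", conditionMessage(e)))
}

load_session <- function(path) {
  if (is.null(path)) fail("--config is required")
  yaml::read_yaml(path)
}
session_reference <- function(cfg, phantom, constants) {
  tc <- cfg$true_config
  if (is.null(tc)) fail("session config needs a 'true_config' block")
  generate_reference_scans(
    do.call(beam_config, tc), phantom,
    scan_depths = if (is.null(cfg$scan_depths)) c(1.6, 5, 10, 20, 30)
                  else as.numeric(cfg$scan_depths),
    constants = constants)
}

if (cmd == "simulate") run({
  model <- if (!is.null(opt("--model"))) read_model_config(opt("--model"))
           else list(constants = dose_model_constants(), phantom = phantom_spec())
  cfg <- beam_config(num("--energy", NA), num("--energy-fwhm", 0),
                     num("--focal-spot", 0), num("--divergence", 0))
  seed <- as.integer(num("--seed", 1))
  grid <- generate_dose_grid(cfg, model$phantom, num("--histories", 2.5e7),
                             seed = seed, constants = model$constants)
  prefix <- opt("--out-prefix"); if (is.null(prefix)) fail("--out-prefix is required")
  write_scan(extract_pdd(grid), paste0(prefix, "_pdd.csv"))
  for (d in c(1.6, 5, 10, 20, 30))
    write_scan(extract_profile(grid, d),
               sprintf("%s_profile_%04.1fcm.csv", prefix, d))
  jsonlite::write_json(
    list(config = unclass(cfg), n_histories = grid$n_histories, seed = seed,
         avg_uncertainty_pct = average_uncertainty(grid)),
    paste0(prefix, "_grid.json"), auto_unbox = TRUE, digits = NA)
  message("master seed: ", seed)
}) else if (cmd == "gamma") run({
  ref <- read_scan(opt("--reference")); ev <- read_scan(opt("--evaluated"))
  cr <- gamma_criteria(num("--dose-pct", 1), num("--dta-mm", 1))
  res <- gamma_curve(ref, ev, cr)
  out <- opt("--out"); if (is.null(out)) fail("--out is required")
  write_gamma_report(res, out, format = "json", include_gamma = TRUE)
  print(res)
}) else if (cmd == "tune-energy") run({
  cfg <- load_session(opt("--config"))
  constants <- dose_model_constants(); phantom <- phantom_spec()
  ref <- session_reference(cfg, phantom, constants)
  seed <- as.integer(if (is.null(cfg$seed)) 1 else cfg$seed)
  trends <- run_energy_sweep(
    ref, as.numeric(cfg$energy_candidates),
    history_ladder = if (is.null(cfg$history_ladder)) c(2e6, 1e7, 5e7)
                     else as.numeric(cfg$history_ladder),
    phantom = phantom, constants = constants, seed = seed)
  sel <- select_energy(trends)
  prefix <- opt("--out", "tune_energy")
  utils::write.csv(do.call(rbind, lapply(trends, function(tr)
    cbind(candidate = tr$candidate_label, tr$rows))),
    paste0(prefix, "_trends.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, selected = sel$selected,
                            energy = sel$energy, diagnostics = sel$diagnostics),
                       paste0(prefix, "_selection.json"),
                       auto_unbox = TRUE, digits = NA)
  message("master seed: ", seed)
  print(sel)
}) else if (cmd == "tune-profiles") run({
  cfg <- load_session(opt("--config"))
  constants <- dose_model_constants(); phantom <- phantom_spec()
  ref <- session_reference(cfg, phantom, constants)
  seed <- as.integer(if (is.null(cfg$seed)) 1 else cfg$seed)
  audit <- run_staged_tuning(
    ref, as.numeric(cfg$energy), lapply(cfg$grids, as.numeric),
    n_histories = if (is.null(cfg$n_histories)) 2.5e7 else cfg$n_histories,
    phantom = phantom, constants = constants, seed = seed)
  prefix <- opt("--out", "tune_profiles")
  jsonlite::write_json(
    list(seed = seed, final_config = unclass(audit$final_config),
         stages = lapply(audit$stages, function(s)
           s[c("parameter_name", "candidates", "best_depth_rates",
               "chosen_value", "chosen_rate")])),
    paste0(prefix, "_audit.json"), auto_unbox = TRUE, digits = NA)
  message("master seed: ", seed)
  print(audit)
}) else if (cmd == "reproduce-paper") run({
  rep <- reproduce_paper()
  print(rep, row.names = FALSE)
  if (!all(rep$pass)) fail("some fixture checks FAILED")
  message("all fixture checks pass")
}) else fail("unknown subcommand: ", cmd)
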