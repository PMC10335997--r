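# Config-driven pipeline chaining the modules into the model experiments:
# synthetic-response generation, ratio-function sweeps with propagation
# variants, and the reproduction run that recomputes the headline quantities.

default_config <- function() {
  list(
    apical = list(cf_ref = 9000, gain_max = 41.1, q_sharpness = 1,
                  phase_cycles_at_cf = 2.45, peak_shift_octaves = 0.15,
                  middle_ear_delay = 36e-6, cf_mag_30_nm = 1.24,
                  structure_tag = "BM"),
    middle_turn = list(cf_ref = 20000, gain_max = 40.5, q_sharpness = 1.65,
                       phase_cycles_at_cf = 2.45, peak_shift_octaves = 0.15 / 1.65,
                       middle_ear_delay = 36e-6, cf_mag_30_nm = 0.52,
                       structure_tag = "BM"),
    map = list(length_mm = 5.13, coef_a = 156.5, coef_b = 82.5),
    stimulus = list(f2 = 9000, ratio_min = 1.02, ratio_max = 1.87,
                    ratio_step = 0.025, levels = c(40, 50, 60, 70)),
    boltzmann = list(a1 = 0.28, x1 = 2.6),
    lowpass = list(octaves_below_cf = 2.36, enabled = TRUE),
    propagation = list(mode = "slow_wave", weighting = "displacement",
                       weight_level = 40, zero_phase_control = FALSE,
                       apical_limit_mm = NULL),
    simulation = list(fs = 4e5, duration = 0.1, position_step_mm = 0.01,
                      levels_generated = seq(10, 90, by = 5)),
    seed = 1
  )
}

check_keys <- function(user, ref, path = "") {
  extra <- setdiff(names(user), names(ref))
  if (length(extra)) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(user[[k]])) stop(sprintf("config key %s%s must be a section", path, k))
      check_keys(user[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Build a validated pipeline configuration
#'
#' Merges user overrides into the default configuration (which carries the
#' model's standard parameter set: Boltzmann a1 = 0.28 /nm and x1 = 2.6 nm,
#' membrane low-pass corner 2.36 octaves below CF, 40 dB SPL weighting level,
#' 0-5.13 mm position grid in 0.01 mm steps, f2/f1 ratios 1.02-1.87 in 0.025
#' steps, 36 us middle-ear delay). Unknown keys are rejected with their name.
#'
#' @param config A named list of overrides, or a path to a YAML or JSON
#'   config file (YAML requires the `yaml` package).
#' @return The merged configuration list (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  ref <- default_config()
  check_keys(config, ref)
  out <- utils::modifyList(ref, config)
  class(out) <- c("run_config", "list")
  out
}

config_profile <- function(cfg_section) {
  do.call(site_profile, cfg_section)
}

config_map <- function(config) {
  do.call(place_map, config$map)
}

config_ratios <- function(config) {
  seq(config$stimulus$ratio_min, config$stimulus$ratio_max,
      by = config$stimulus$ratio_step)
}

config_positions <- function(config) {
  seq(0, config$map$length_mm, by = config$simulation$position_step_mm)
}

write_manifest <- function(config, path, extra = list()) {
  jsonlite::write_json(c(unclass(config), extra), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Generate synthetic response tables and a calibration report
#'
#' Writes the apical and middle-turn frequency-response tables (CSV), a
#' calibration report (JSON) and a manifest of every resolved parameter.
#'
#' @param config A [run_config()] (or overrides accepted by it).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the two `calibration_metrics`, the
#'   middle-turn/apical Q10dB ratio by level, and the written paths.
#' @export
pipeline_generate <- function(config = list(), dir = ".") {
  config <- run_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lev <- config$simulation$levels_generated

  fr_api <- generate_frequency_response(config_profile(config$apical),
                                        levels = lev)
  fr_mid <- generate_frequency_response(config_profile(config$middle_turn),
                                        levels = lev)
  p_api <- file.path(dir, "response_apical.csv")
  p_mid <- file.path(dir, "response_middle_turn.csv")
  write_response_table(fr_api, p_api)
  write_response_table(fr_mid, p_mid)

  cal_api <- calibration_report(fr_api)
  cal_mid <- calibration_report(fr_mid)
  match_lev <- intersect(c(40, 50, 60, 70), lev)
  qr <- cal_mid$q10_by_level[as.character(match_lev)] /
    cal_api$q10_by_level[as.character(match_lev)]

  report <- list(
    apical = unclass(cal_api),
    middle_turn = unclass(cal_mid),
    middle_vs_apical_q10 = as.list(qr),
    middle_vs_apical_q10_min = min(qr)
  )
  p_rep <- file.path(dir, "calibration_report.json")
  jsonlite::write_json(report, p_rep, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_manifest(config, file.path(dir, "manifest_generate.json"))
  invisible(list(apical = cal_api, middle_turn = cal_mid,
                 middle_vs_apical_q10 = qr,
                 paths = c(p_api, p_mid, p_rep)))
}

# Run the interference model for one site over the configured levels and the
# requested propagation variants. Returns nested list: result[[variant]] is a
# list of ratio_function objects indexed by level.
run_model_sweeps <- function(fr_free, config, f2, variants, levels,
                             apical_limit_mm = NULL) {
  map <- config_map(config)
  p <- do.call(boltzmann_params, config$boltzmann)
  lp <- do.call(lowpass_params, config$lowpass)
  positions <- config_positions(config)
  ratios <- config_ratios(config)
  opts <- lapply(variants, function(v) {
    switch(v,
      slow_wave = propagation_options("slow_wave",
                                      weighting = config$propagation$weighting,
                                      weight_level = config$propagation$weight_level,
                                      apical_limit_mm = apical_limit_mm),
      fast_wave = propagation_options("fast_wave",
                                      apical_limit_mm = apical_limit_mm),
      zero_phase = propagation_options("slow_wave",
                                       weighting = config$propagation$weighting,
                                       weight_level = config$propagation$weight_level,
                                       zero_phase_control = TRUE,
                                       apical_limit_mm = apical_limit_mm),
      stop("unknown variant: ", v)
    )
  })
  out <- stats::setNames(
    lapply(variants, function(v) stats::setNames(vector("list", length(levels)),
                                                 levels)),
    variants)
  for (l in levels) {
    rfs <- ratio_functions(fr_free, map, f2, ratios, level1 = l, level2 = l,
                           p = p, lp = lp, opts = opts, positions = positions)
    for (i in seq_along(variants)) {
      out[[variants[i]]][[as.character(l)]] <- rfs[[i]]
    }
  }
  out
}

# Is an amplitude-vs-ratio curve bandpass on its grid: interior maximum with
# at least `edge_drop_db` of attenuation at both grid ends?
is_bandpass <- function(rf, edge_drop_db = 10) {
  a_db <- dpoae_db_re_max(rf)
  i <- which.max(a_db)
  i != 1 && i != length(a_db) &&
    a_db[1] <= -edge_drop_db && a_db[length(a_db)] <= -edge_drop_db
}

#' Run the ratio-function experiments
#'
#' Runs the wave-interference model at the configured levels for the
#' requested propagation variants (`"slow_wave"`, `"fast_wave"`,
#' `"zero_phase"`), writing per-level ratio-function tables, a tuning report
#' and a phase-spread-vs-ratio table, plus a manifest.
#'
#' @param config A [run_config()] (or overrides).
#' @param dir Output directory.
#' @param variants Character vector of variants to run.
#' @return Invisibly, a list with the `ratio_function` objects (nested by
#'   variant then level) and the tuning report.
#' @export
pipeline_ratio_functions <- function(config = list(), dir = ".",
                                     variants = c("slow_wave", "fast_wave",
                                                  "zero_phase")) {
  config <- run_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profile <- config_profile(config$apical)
  fr <- generate_frequency_response(profile,
                                    levels = config$simulation$levels_generated)
  fr_free <- remove_middle_ear_delay(fr)
  sweeps <- run_model_sweeps(fr_free, config, config$stimulus$f2, variants,
                             config$stimulus$levels,
                             apical_limit_mm = config$propagation$apical_limit_mm)

  tuning <- list()
  for (v in variants) {
    for (l in names(sweeps[[v]])) {
      rf <- sweeps[[v]][[l]]
      tab <- data.frame(ratio = rf$ratios, f1_hz = rf$f1, fdp_hz = rf$f_dp,
                        dpoae_mag = Mod(rf$dpoae),
                        dpoae_db_re_max = dpoae_db_re_max(rf),
                        dpoae_phase_cycles = Arg(rf$dpoae) / (2 * pi),
                        spread_cycles = rf$spread_cycles)
      utils::write.csv(tab, file.path(dir, sprintf("ratiofn_%s_%sdB.csv", v, l)),
                       row.names = FALSE)
      tr <- ratio_function_tuning(rf)
      tuning[[v]][[l]] <- list(
        f_max_hz = tr$f_max, bw10_hz = tr$bw10, q10 = tr$q10,
        erb_hz = tr$erb, q_erb = tr$q_erb,
        optimal_ratio = tr$optimal_ratio,
        bandpass = is_bandpass(rf),
        note = if (!is_bandpass(rf)) "no bandpass" else ""
      )
    }
  }
  jsonlite::write_json(tuning, file.path(dir, "tuning_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, file.path(dir, "manifest_ratiofn.json"),
                 extra = list(variants = variants))
  invisible(list(sweeps = sweeps, tuning = tuning))
}

# Reference values for the reproduction run: the study's reported summary
# statistics that the model recomputes from the synthetic configuration.
reproduction_references <- function() {
  list(
    apical_gain_db = list(expected = 41.1, cmp = "eq", tol = 0.2),
    rf_q10_ratio_40_75 = list(expected = 2, cmp = "eq", tol = 0.2),
    rf_q10_deficit_vs_bm_pct = list(expected = 15, cmp = "eq", tol = 0.2),
    fast_wave_q10_deficit_pct = list(expected = 45, cmp = "eq", tol = 0.2),
    optimal_ratio_min = list(expected = 1.17, cmp = "eq", tol = 0.2),
    optimal_ratio_max = list(expected = 1.22, cmp = "eq", tol = 0.2),
    phase_spread_past_optimum = list(expected = 0.5, cmp = "ge"),
    middle_turn_optimal_ratio = list(expected = 1.14, cmp = "eq", tol = 0.2),
    middle_vs_apical_q10_min = list(expected = 1.5, cmp = "ge")
  )
}

#' Recompute the model's headline quantities from the default configuration
#'
#' Runs the full pipeline on the synthetic stand-in data and recomputes, from
#' scratch: the apical nonlinear gain; the level dependence of the modeled
#' ratio-function Q10dB (40 vs 75 dB SPL); the mean Q10dB deficit of the
#' slow-wave model relative to the input BM tuning over 40-70 dB SPL, and the
#' same for direct (fast-wave) summation; the range of the modeled optimal
#' f2/f1 ratio; the generation-region phase spread just below the optimal
#' ratio at 50 dB SPL; the middle-turn (f2 = 20 kHz) optimal ratio with the
#' 0.32 mm apical generation limit; and the minimum middle-turn/apical
#' vibratory Q10dB ratio. Each entry records the computed value, the
#' reference value it is compared against, and a pass flag.
#'
#' @param config A [run_config()] (or overrides).
#' @param out Optional path for a JSON report.
#' @return A list with `entries` (named list of id/computed/expected/pass),
#'   `details` (the underlying sweeps and tuning objects) and `all_pass`.
#' @export
pipeline_reproduce <- function(config = list(), out = NULL) {
  config <- run_config(config)
  set.seed(config$seed)

  # --- synthetic inputs ------------------------------------------------------
  lev_gen <- config$simulation$levels_generated
  fr_api <- generate_frequency_response(config_profile(config$apical),
                                        levels = lev_gen)
  fr_mid <- generate_frequency_response(config_profile(config$middle_turn),
                                        levels = lev_gen)
  fr_api_free <- remove_middle_ear_delay(fr_api)
  fr_mid_free <- remove_middle_ear_delay(fr_mid)

  levels_main <- config$stimulus$levels          # 40-70 dB SPL
  bm_q10 <- vapply(levels_main, function(l) {
    q10(fr_api$freqs, fr_api$magnitude[level_index(fr_api, l), ])$q10
  }, numeric(1))
  names(bm_q10) <- levels_main

  # --- apical model sweeps ---------------------------------------------------
  sweeps <- run_model_sweeps(fr_api_free, config, config$stimulus$f2,
                             c("slow_wave", "fast_wave", "zero_phase"),
                             levels_main)
  slow75 <- run_model_sweeps(fr_api_free, config, config$stimulus$f2,
                             "slow_wave", 75)$slow_wave[["75"]]

  slow_tuning <- lapply(sweeps$slow_wave, ratio_function_tuning)
  fast_tuning <- lapply(sweeps$fast_wave, ratio_function_tuning)
  t75 <- ratio_function_tuning(slow75)

  slow_q10 <- vapply(slow_tuning, function(t) t$q10, numeric(1))
  fast_q10 <- vapply(fast_tuning, function(t) t$q10, numeric(1))
  opt_ratio <- vapply(slow_tuning, function(t) t$optimal_ratio, numeric(1))

  # --- phase spread just below the 50 dB SPL optimum -------------------------
  rf50 <- sweeps$slow_wave[["50"]]
  i_opt <- which.max(Mod(rf50$dpoae))
  spread_below <- if (i_opt > 1) rf50$spread_cycles[i_opt - 1] else NA_real_

  # --- middle-turn model -----------------------------------------------------
  mid_levels <- c(50, 60, 70)
  mid_sweeps <- run_model_sweeps(fr_mid_free, config,
                                 f2 = config$middle_turn$cf_ref,
                                 "slow_wave", mid_levels,
                                 apical_limit_mm = 0.32)
  mid_opt <- vapply(mid_sweeps$slow_wave,
                    function(rf) ratio_function_tuning(rf)$optimal_ratio,
                    numeric(1))

  mid_q10 <- vapply(levels_main, function(l) {
    q10(fr_mid$freqs, fr_mid$magnitude[level_index(fr_mid, l), ])$q10
  }, numeric(1))

  computed <- list(
    apical_gain_db = nonlinear_gain(fr_api),
    rf_q10_ratio_40_75 = slow_q10[["40"]] / t75$q10,
    rf_q10_deficit_vs_bm_pct = mean(100 * (1 - slow_q10 / bm_q10)),
    fast_wave_q10_deficit_pct = mean(100 * (1 - fast_q10 / bm_q10)),
    optimal_ratio_min = min(opt_ratio),
    optimal_ratio_max = max(opt_ratio),
    phase_spread_past_optimum = spread_below,
    middle_turn_optimal_ratio = mean(mid_opt),
    middle_vs_apical_q10_min = min(mid_q10 / bm_q10)
  )

  refs <- reproduction_references()
  entries <- lapply(names(refs), function(id) {
    ref <- refs[[id]]
    val <- computed[[id]]
    pass <- if (ref$cmp == "ge") {
      is.finite(val) && val >= ref$expected
    } else {
      is.finite(val) && abs(val - ref$expected) <= ref$tol * abs(ref$expected)
    }
    list(id = id, computed = val, expected = ref$expected, cmp = ref$cmp,
         pass = pass)
  })
  names(entries) <- names(refs)

  result <- list(
    entries = entries,
    all_pass = all(vapply(entries, `[[`, logical(1), "pass")),
    details = list(
      fr_api = fr_api, fr_mid = fr_mid,
      bm_q10 = bm_q10, mid_q10 = mid_q10,
      sweeps = sweeps, slow75 = slow75,
      slow_tuning = slow_tuning, fast_tuning = fast_tuning,
      tuning75 = t75, mid_sweeps = mid_sweeps, mid_opt = mid_opt
    )
  )
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(entries, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  result
}
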