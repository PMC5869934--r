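# File formats and the study-level driver.
#
# Conventions: time series as CSV (degrees on disk, radians internally in
# the simulator), fit results as JSON, configuration as YAML. Time columns
# start at 0.0 s.

#' Write a perturbation/sway trial to CSV
#'
#' @param trial A `stance_trial` (or any data frame with `time_s`,
#'   `ss_deg`, `bs_deg`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(all(c("time_s", "ss_deg", "bs_deg") %in% names(trial)))
  utils::write.csv(trial[, c("time_s", "ss_deg", "bs_deg")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a perturbation/sway trial from CSV
#'
#' Expects columns `time_s`, `ss_deg`, `bs_deg` with a uniformly sampled
#' time column starting at any offset; the sample rate is inferred from the
#' time column. Rows with missing values or timing jitter above 1e-6 s are
#' rejected with the offending row number.
#'
#' @param path CSV file path.
#' @param period Perturbation period, s, attached to the returned trial for
#'   downstream analysis.
#' @return A `stance_trial` tibble with attributes `fs` and `period`.
#' @export
read_trial <- function(path, period = 20) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ss_deg", "bs_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(is.finite(as.matrix(df[need])), 1, all))
  if (length(bad))
    stop(sprintf("non-finite value at row %d of %s", bad[1], path))
  t <- df$time_s
  if (length(t) < 2) stop("trial must contain at least 2 samples")
  dt <- (t[length(t)] - t[1]) / (length(t) - 1)
  if (dt <= 0) stop("time column must be strictly increasing")
  jit <- abs(diff(t) - dt)
  if (any(jit > 1e-6))
    stop(sprintf("non-uniform sampling at row %d: time step deviates by %.3g s",
                 which.max(jit) + 1, max(jit)))
  fs <- 1 / dt
  out <- tibble::as_tibble(df[need])
  structure(out, class = c("stance_trial", class(out)),
            fs = fs, period = period,
            n_periods = floor(nrow(out) / (period * fs)))
}

#' Write a perturbation waveform to CSV
#'
#' Two columns: `time_s` and the platform rotation `ss_deg`.
#'
#' @param sig A `prts_signal` from [prts_rotation()].
#' @param path Output file path.
#' @param n_periods Number of tiled periods to write.
#' @return `path`, invisibly.
#' @export
write_perturbation <- function(sig, path, n_periods = 1) {
  stopifnot(inherits(sig, "prts_signal"))
  fs <- attr(sig, "fs")
  pos <- rep(sig$position_deg, n_periods)
  utils::write.csv(
    data.frame(time_s = (seq_along(pos) - 1) / fs, ss_deg = pos),
    path, row.names = FALSE)
  invisible(path)
}

#' Write an identified spectral estimate to CSV
#'
#' @param frf An `frf_estimate` from [estimate_frf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frf <- function(frf, path) {
  stopifnot(inherits(frf, "frf_estimate"))
  utils::write.csv(
    data.frame(freq_hz = frf$freq_hz, re_H = Re(frf$response),
               im_H = Im(frf$response), magnitude = frf$gain,
               phase_deg = frf$phase_deg, coherence = frf$coherence),
    path, row.names = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' Bundles everything needed for a deterministic four-condition study run:
#' anthropometry (explicit, or total mass/height for the Winter
#' derivation), per-condition model parameters, perturbation settings,
#' noise settings, the analysis band and the global seed.
#'
#' @param total_mass,total_height Body size for [winter_anthropometry()];
#'   ignored when `anthro` is given.
#' @param anthro Optional explicit [anthropometry()].
#' @param params Named list of four [ic_parameters()] with `condition`
#'   attributes; default [study_parameters()] on the configured body.
#' @param noise_amplitude Pink-noise RMS torque, N m (shared across
#'   conditions).
#' @param seed Global integer seed.
#' @param fs Sample rate, Hz.
#' @param n_periods Analysed periods per trial.
#' @param f_min,f_max Analysis band, Hz.
#' @return A `study_config` list.
#' @export
study_config <- function(total_mass = 77.7, total_height = 1.79,
                         anthro = NULL, params = NULL,
                         noise_amplitude = 0.6, seed = 1L,
                         fs = 1000, n_periods = 6,
                         f_min = 0.05, f_max = 2.05) {
  if (is.null(anthro)) anthro <- winter_anthropometry(total_mass, total_height)
  if (is.null(params)) params <- study_parameters(anthro)
  if (f_max < f_min) stop("`f_max` must be at least `f_min`")
  structure(list(anthro = anthro, params = params,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed),
                 fs = fs, n_periods = n_periods,
                 f_min = f_min, f_max = f_max),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' The configuration is stored flat: anthropometry fields, one mapping per
#' condition with the flat parameter fields of [ic_parameters_flatten()],
#' and the run settings.
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `path` invisibly ([write_study_config()]); a `study_config`
#'   ([read_study_config()]).
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  a <- config$anthro
  lst <- list(
    anthropometry = list(mass = a$mass, com_height = a$com_height,
                         inertia = a$inertia, g = a$g),
    conditions = purrr::map(config$params, function(p) {
      cond <- attr(p, "condition")
      c(list(amplitude_deg = cond$amplitude_deg, eyes = cond$eyes),
        ic_parameters_flatten(p)[c(FREE_PARAM_NAMES, "W_vis", "W_ves")])
    }),
    noise_amplitude = config$noise_amplitude, seed = config$seed,
    fs = config$fs, n_periods = config$n_periods,
    f_min = config$f_min, f_max = config$f_max)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  a <- lst$anthropometry
  anthro <- anthropometry(a$mass, a$com_height, a$inertia,
                          if (is.null(a$g)) 9.81 else a$g)
  params <- purrr::map(lst$conditions, function(cp) {
    p <- ic_parameters(anthro, W_p = cp$W_p, K_P = cp$K_P, K_D = cp$K_D,
                       tau_D = cp$tau_D, tau_F = cp$tau_F, K_F = cp$K_F,
                       W_vis = cp$W_vis, W_ves = cp$W_ves)
    attr(p, "condition") <- condition(cp$amplitude_deg, cp$eyes)
    p
  })
  study_config(anthro = anthro, params = params,
               noise_amplitude = lst$noise_amplitude, seed = lst$seed,
               fs = lst$fs, n_periods = lst$n_periods,
               f_min = lst$f_min, f_max = lst$f_max)
}

#' Run the full simulate-identify-fit study
#'
#' Executes the whole analysis chain per condition: simulate a noisy trial
#' with the configured ground-truth parameters, identify the frequency
#' response and coherence, fit the model, and score the recovery
#' (variance-accounted-for of the refit against the trial, and mean
#' relative parameter difference against the ground truth). Deterministic
#' given the global seed.
#'
#' @param config A [study_config()].
#' @return A `study_report`: list with `summary` (one tibble row per
#'   condition), `fits`, `trials`, `frfs` and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  trials <- generate_study_dataset(
    config$params,
    noise = noise_config(amplitude = config$noise_amplitude,
                         seed = config$seed),
    fs = config$fs, n_periods = config$n_periods)
  out <- purrr::imap(trials, function(trial, nm) {
    cond <- attr(trial, "condition")
    frf <- tryCatch(
      estimate_frf(trial, f_max = config$f_max),
      error = function(e) stop(sprintf("identification failed for condition %s: %s",
                                       nm, conditionMessage(e))))
    fit <- tryCatch(
      fit_ic_model(frf, config$anthro, cond, trial = trial),
      error = function(e) stop(sprintf("fit failed for condition %s: %s",
                                       nm, conditionMessage(e))))
    truth <- config$params[[nm]]
    tibble::tibble(
      condition = nm,
      amplitude_deg = cond$amplitude_deg,
      eyes = cond$eyes,
      w_p_true = truth$W_p,
      w_p_hat = fit$params$W_p,
      vaf_pct = fit$vaf_pct,
      rel_mean_diff_pct = compare_parameters(fit$params, truth),
      even_fraction_pct = attr(frf, "even_fraction_pct"),
      max_coherence = max(frf$coherence),
      cost = fit$cost,
      converged = fit$converged) -> row
    list(row = row, fit = fit, frf = frf, trial = trial)
  })
  structure(list(
    summary = dplyr::bind_rows(purrr::map(out, "row")),
    fits = purrr::map(out, "fit"),
    frfs = purrr::map(out, "frf"),
    trials = trials,
    config = config
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write a study report to disk
#'
#' Per condition: the trial CSV, the spectral-estimate CSV, and a JSON file
#' with estimated parameters, standard errors, cost, VAF and comparison
#' metrics. A `summary.json` collects the per-condition summary table. The
#' writer only formats numbers produced by the analysis chain.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$fits)) {
    write_trial(report$trials[[nm]], file.path(dir, paste0("trial_", nm, ".csv")))
    write_frf(report$frfs[[nm]], file.path(dir, paste0("frf_", nm, ".csv")))
    fit <- report$fits[[nm]]
    jsonlite::write_json(
      list(condition = format(fit$condition),
           estimates = fit$estimates,
           weights = as.list(fit$weights),
           cost = fit$cost, vaf_pct = fit$vaf_pct,
           converged = fit$converged),
      file.path(dir, paste0("fit_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
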