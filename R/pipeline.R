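# Per-session orchestration and condition comparison.

#' Analyze one recording session
#'
#' Runs the full pipeline on a session: velocity + run/rest segmentation
#' restricted to the analysis window; per-state z-scoring; multitaper
#' peak power for theta, low-gamma and high-gamma in each state;
#' theta-phase / low-gamma-amplitude coupling during running;
#' hippocampal-prefrontal band coherence and phase lag (when a
#' prefrontal channel is present); and rest-state ripple detection.
#' Metrics whose behavioral state is absent are flagged missing rather
#' than reported as zero; sessions without a prefrontal channel simply
#' lack the synchrony fields.
#'
#' @param hpc Hippocampal [as_lfp()] trace (pyramidal-layer channel).
#' @param position Position tibble (`time_s`, `x_cm`, `y_cm`).
#' @param pfc Optional prefrontal [as_lfp()] trace.
#' @param config Optional session metadata (list or `session_config`):
#'   `session_id`, `genotype`, `treatment`, `dose_mg_per_kg`,
#'   `analysis_window` in seconds (defaults to the full recording).
#' @param seed Seed for the coupling surrogate test.
#' @param mi_surrogates Number of MI surrogates (0 skips the surrogate
#'   floor).
#' @param window_s,n_tapers Spectral estimation settings.
#' @return An object of class `session_result`; see [glance()] /
#'   [tidy()] methods.
#' @export
analyze_session <- function(hpc, position, pfc = NULL, config = list(),
                            seed = 1, mi_surrogates = 0,
                            window_s = 2, n_tapers = 5) {
  rate <- lfp_rate(hpc)
  window <- config$analysis_window %||% c(min(hpc$time_s), max(hpc$time_s) + 1 / rate)
  missing_flags <- character(0)

  log_stage("segment", "computing velocity and run/rest segments")
  vel <- compute_velocity(position)
  seg_all <- segment_states(vel)
  seg <- restrict_to_window(seg_all, window)
  loco <- locomotion_summary(vel, seg, window)

  states_present <- intersect(c("run", "rest"), unique(seg$state))
  if (length(states_present) == 0) {
    stop("no run or rest segments inside the analysis window", call. = FALSE)
  }
  has_run <- "run" %in% states_present
  has_rest <- "rest" %in% states_present
  if (!has_run) missing_flags <- c(missing_flags, "run_state")
  if (!has_rest) missing_flags <- c(missing_flags, "rest_state")

  log_stage("zscore", "z-scoring per behavioral state")
  z_hpc <- zscore_by_state(hpc, seg[seg$state %in% states_present, ])

  log_stage("spectra", "multitaper spectra and peak band powers")
  power <- purrr::map_dfr(states_present, function(st) {
    psd <- tryCatch(
      smooth_spectrum(multitaper_psd(z_hpc, state = st, n_tapers = n_tapers,
                                     window_s = window_s)),
      error = function(e) NULL)
    if (is.null(psd)) return(tibble::tibble())
    purrr::map_dfr(c("theta", "lowgamma", "highgamma"), function(bn) {
      dplyr::mutate(peak_band_power(psd, bn), state = st,
                    band_power = band_power(psd, bn), .before = 1)
    })
  })

  cfc <- NULL
  if (has_run) {
    log_stage("cfc", "theta-gamma phase-amplitude coupling (run state)")
    bouts <- state_bouts(z_hpc, "run")
    ph <- numeric(0); env <- numeric(0)
    for (b in bouts) {
      if (length(b) < rate) next
      th <- analytic_signal(bandpass_zero_phase(b, "theta", rate = rate), rate)
      lg <- analytic_signal(bandpass_zero_phase(b, "cfc_lowgamma", rate = rate), rate)
      ok <- th$edge_valid & lg$edge_valid
      ph <- c(ph, th$phase[ok])
      env <- c(env, lg$envelope[ok])
    }
    if (length(ph) >= 18 * 10) {
      mr <- modulation_index(ph, env)
      thr <- if (mi_surrogates > 0) {
        mi_surrogate_threshold(ph, env, n_surrogates = mi_surrogates,
                               seed = seed, rate = rate)
      } else NA_real_
      cfc <- list(mi = mr$mi, preferred_phase_rad = mr$preferred_phase_rad,
                  surrogate_threshold = as.numeric(thr),
                  n_samples = mr$n_samples, result = mr)
    } else {
      missing_flags <- c(missing_flags, "cfc_insufficient_run_data")
    }
  }

  synchrony <- NULL
  if (!is.null(pfc) && has_run) {
    log_stage("synchrony", "hpc-pfc coherence and phase lag (run state)")
    z_pfc <- zscore_by_state(pfc, seg[seg$state %in% states_present, ])
    xb <- state_bouts(z_hpc, "run")
    yb <- state_bouts(z_pfc, "run")
    synchrony <- tryCatch({
      coh <- coherence_spectrum(xb, yb, rate = rate, n_tapers = n_tapers,
                                window_s = window_s)
      pl <- phase_lag(xb, yb, band = "lowgamma", rate = rate)
      list(band_coherence = band_coherence(coh, "lowgamma"),
           n_windows = attr(coh, "n_windows"),
           phase_lag = pl)
    }, error = function(e) {
      missing_flags <<- c(missing_flags, paste0("synchrony: ", conditionMessage(e)))
      NULL
    })
  }

  ripples <- NULL
  if (has_rest) {
    log_stage("ripples", "rest-state ripple detection")
    ripples <- tryCatch({
      ev <- detect_ripples(z_hpc)
      list(stats = ripple_stats(ev), events = ev)
    }, error = function(e) {
      missing_flags <<- c(missing_flags, paste0("ripples: ", conditionMessage(e)))
      NULL
    })
  }

  structure(list(
    session_id = config$session_id %||% NA_character_,
    genotype = config$genotype %||% NA_character_,
    treatment = config$treatment %||% NA_character_,
    dose_mg_per_kg = config$dose_mg_per_kg %||% NA_real_,
    window = window,
    locomotion = loco,
    segments = seg,
    power = power,
    cfc = cfc,
    synchrony = synchrony,
    ripples = ripples,
    missing = missing_flags,
    provenance = list(package_version = as.character(utils::packageVersion("lfpkit")),
                      seed = seed,
                      config_hash = rlang::hash(config))
  ), class = "session_result")
}

#' Analyze a synthetic session object
#'
#' Convenience wrapper running [analyze_session()] on the output of
#' [simulate_session()].
#'
#' @param session An `lfp_session` from [simulate_session()].
#' @param ... Passed to [analyze_session()].
#' @export
analyze_simulated <- function(session, ...) {
  stopifnot(inherits(session, "lfp_session"))
  analyze_session(session$hpc, session$position, pfc = session$pfc, ...)
}

#' Write and read a session result as JSON
#'
#' Serialization is deterministic: re-running an identical analysis and
#' writing it again produces a byte-identical file.
#'
#' @param result A `session_result`.
#' @param path Output JSON path.
#' @export
write_session_result <- function(result, path) {
  out <- list(
    schema = "lfpkit/session_result/1",
    session_id = result$session_id,
    genotype = result$genotype,
    treatment = result$treatment,
    dose_mg_per_kg = result$dose_mg_per_kg,
    window = result$window,
    locomotion = as.data.frame(result$locomotion),
    power = as.data.frame(result$power),
    cfc = result$cfc[c("mi", "preferred_phase_rad", "surrogate_threshold",
                       "n_samples")],
    coherence = if (!is.null(result$synchrony)) list(
      band_coherence = result$synchrony$band_coherence,
      n_windows = result$synchrony$n_windows,
      mean_phase_diff_rad = result$synchrony$phase_lag$mean_phase_diff_rad,
      resultant_length = result$synchrony$phase_lag$resultant_length,
      p_vs_zero = result$synchrony$phase_lag$v_zero$p,
      p_vs_2pi = result$synchrony$phase_lag$v_2pi$p),
    ripples = if (!is.null(result$ripples)) as.data.frame(result$ripples$stats),
    missing = result$missing,
    provenance = result$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session_result
#' @export
read_session_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Compare paired vehicle/treatment sessions
#'
#' For each subject's (vehicle, treated) session pair, computes the
#' per-metric ratio (treated / vehicle; positive metrics only) and
#' signed difference. No hypothesis tests are performed -- the output is
#' effect sizes, one row per subject and metric, with group means as the
#' `"group_means"` attribute.
#'
#' @param pairs A list of pairs; each pair is a list with elements
#'   `vehicle` and `cno` (both `session_result`) and optionally
#'   `subject`.
#' @return A tibble of class `condition_comparison`: `subject`, `metric`,
#'   `vehicle`, `cno`, `ratio`, `difference`, `direction`.
#' @export
compare_conditions <- function(pairs) {
  if (length(pairs) < 1) stop("need at least one session pair", call. = FALSE)
  rows <- purrr::imap_dfr(pairs, function(pr, i) {
    if (is.null(pr$vehicle) || is.null(pr$cno)) {
      stop(sprintf("pair %s is missing a vehicle or cno session", i),
           call. = FALSE)
    }
    gv <- glance(pr$vehicle)
    gc <- glance(pr$cno)
    metrics <- names(gv)[vapply(gv, is.numeric, logical(1))]
    purrr::map_dfr(metrics, function(m) {
      a <- gv[[m]]; b <- gc[[m]]
      tibble::tibble(
        subject = as.character(pr$subject %||% i),
        metric = m,
        vehicle = a,
        cno = b,
        ratio = if (isTRUE(a > 0) && isTRUE(b >= 0)) b / a else NA_real_,
        difference = b - a,
        direction = sign(b - a))
    })
  })
  gm <- dplyr::summarise(
    dplyr::group_by(rows, .data$metric),
    mean_ratio = mean(.data$ratio, na.rm = TRUE),
    mean_difference = mean(.data$difference, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
  structure(rows, class = c("condition_comparison", class(rows)),
            group_means = gm)
}
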