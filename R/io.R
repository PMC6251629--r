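# Readers and writers for the package's native formats.
#
# Signals: either CSV (columns t, v; small fixtures) or raw little-endian
# float32 with a JSON sidecar (<path>.json) holding rate, role, units and
# start time -- hours of 1 kHz LFP make CSV impractical. Positions and
# ripple events are CSV; session results are JSON. All times are seconds
# from session start, double precision.

#' Read an LFP signal file
#'
#' Reads either a two-column CSV (`t`, `v`) or a raw little-endian float32
#' file accompanied by a `<path>.json` sidecar declaring `rate_hz`,
#' `n_samples`, `duration_s`, `t0_s`, `units` and optionally `role`.
#'
#' @param path Path to a `.csv` or `.bin` signal file.
#' @param channel Optional channel role override (`"hpc"` or `"pfc"`).
#' @return An [as_lfp()] tibble.
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, channel = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!all(c("t", "v") %in% names(df))) {
      stop("signal CSV must have columns 't' and 'v'", call. = FALSE)
    }
    if (anyNA(df$v)) {
      stop(sprintf("signal contains NA/NaN samples at indices: %s",
                   paste(utils::head(which(is.na(df$v)), 10), collapse = ", ")),
           call. = FALSE)
    }
    lfp <- as_lfp(data.frame(time_s = df$t, voltage = df$v), role = channel)
    return(lfp)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing JSON sidecar for binary signal: %s", sidecar),
         call. = FALSE)
  }
  hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("rate_hz", "n_samples", "duration_s")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) {
    stop(sprintf("signal header missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (abs(hdr$n_samples - hdr$duration_s * hdr$rate_hz) > 1) {
    stop(sprintf(
      "header inconsistency: %d samples but duration %g s at %g Hz implies %g",
      hdr$n_samples, hdr$duration_s, hdr$rate_hz, hdr$duration_s * hdr$rate_hz),
      call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = hdr$n_samples, size = 4, endian = "little")
  if (length(x) != hdr$n_samples) {
    stop(sprintf("expected %d samples, file holds %d", hdr$n_samples, length(x)),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("signal contains NA/NaN samples at indices: %s",
                 paste(utils::head(which(is.na(x)), 10), collapse = ", ")),
         call. = FALSE)
  }
  role <- channel %||% hdr$role
  as_lfp(x, rate = hdr$rate_hz, role = role,
         t0 = hdr$t0_s %||% 0, zscored = isTRUE(hdr$zscored))
}

#' Write an LFP signal file
#'
#' @param lfp An [as_lfp()] tibble.
#' @param path Output path; `.csv` writes text, anything else writes raw
#'   float32 plus a `<path>.json` sidecar.
#' @param units Unit string stored in the header.
#' @return `path`, invisibly.
#' @export
write_signal <- function(lfp, path, units = "uV") {
  rate <- lfp_rate(lfp)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("t,v", con)
    writeLines(sprintf("%.17g,%.17g", lfp$time_s, lfp$voltage), con)
    return(invisible(path))
  }
  hdr <- list(rate_hz = rate, n_samples = nrow(lfp),
              duration_s = nrow(lfp) / rate, t0_s = lfp$time_s[1],
              units = units, role = lfp_role(lfp),
              zscored = isTRUE(attr(lfp, "lfp_zscored")))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp$voltage), con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write position traces
#'
#' Position CSVs have columns `time_s`, `x_cm`, `y_cm`; timestamps must be
#' strictly increasing.
#'
#' @param path CSV path.
#' @return `read_position()`: a tibble with columns `time_s`, `x_cm`,
#'   `y_cm`.
#' @export
read_position <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    stop("position CSV must have columns time_s, x_cm, y_cm", call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("position timestamps must be strictly increasing", call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_position
#' @param pos Position tibble (`time_s`, `x_cm`, `y_cm`).
#' @export
write_position <- function(pos, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("time_s,x_cm,y_cm", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", pos$time_s, pos$x_cm, pos$y_cm), con)
  invisible(path)
}

#' Read and write ripple-event tables
#'
#' Event CSVs have columns `onset_s`, `offset_s`, `peak_s`,
#' `amplitude_sd`, `duration_ms`, one time-sorted row per event.
#'
#' @param events Event tibble, time-sorted by onset.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  cols <- c("onset_s", "offset_s", "peak_s", "amplitude_sd", "duration_ms")
  if (!all(cols %in% names(events))) {
    stop(sprintf("events must have columns: %s", paste(cols, collapse = ", ")),
         call. = FALSE)
  }
  if (is.unsorted(events$onset_s, strictly = FALSE)) {
    stop("events must be sorted by onset_s", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(events) > 0) {
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g",
                       events$onset_s, events$offset_s, events$peak_s,
                       events$amplitude_sd, events$duration_ms), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- c("onset_s", "offset_s", "peak_s", "amplitude_sd", "duration_ms")
  if (!all(cols %in% names(df))) {
    stop("malformed event CSV", call. = FALSE)
  }
  tibble::as_tibble(df[cols])
}

#' Load a session configuration
#'
#' Session configs are YAML or JSON mirroring the fields of a recording
#' session: `session_id`, `genotype` (`cre_pos`/`cre_neg`), `treatment`
#' (`vehicle`/`cno`), `dose_mg_per_kg`, `analysis_window` (seconds post
#' treatment, `[start, end)`), `channel_roles`, `sampling_rate_lfp`,
#' `sampling_rate_pos`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config.
#' @return A validated list of class `session_config`.
#' @export
read_session_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_session_config(cfg)
}

#' @rdname read_session_config
#' @param cfg A config list.
#' @export
validate_session_config <- function(cfg) {
  defaults <- list(genotype = "cre_pos", treatment = "vehicle",
                   dose_mg_per_kg = 0, sampling_rate_lfp = 1000,
                   sampling_rate_pos = 30)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  cfg$genotype <- match.arg(cfg$genotype, c("cre_pos", "cre_neg"))
  cfg$treatment <- match.arg(cfg$treatment, c("vehicle", "cno"))
  if (cfg$dose_mg_per_kg < 0) stop("dose_mg_per_kg must be >= 0", call. = FALSE)
  if (!is.null(cfg$analysis_window)) {
    w <- as.numeric(unlist(cfg$analysis_window))
    if (length(w) != 2 || w[1] >= w[2]) {
      stop("analysis_window must be c(start, end) with start < end", call. = FALSE)
    }
    cfg$analysis_window <- w
  }
  if (cfg$sampling_rate_lfp < 600) {
    stop("sampling_rate_lfp must be at least 600 Hz to resolve the ripple band",
         call. = FALSE)
  }
  structure(cfg, class = "session_config")
}
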