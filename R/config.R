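# Pipeline configuration: defaults, YAML/JSON loading, schema validation.

#' Default pipeline configuration
#'
#' @return Named list with the resolved defaults: sampling rate (500 Hz),
#'   optional target rate for downsampling, the 11-value ensemble-size grid,
#'   reference channel, recording duration, heart-vector wave parameters,
#'   beat schedule, per-channel gains, and the filter bank (0.5-30 Hz order-3
#'   Butterworth for head/ear channels; 0.5-95 Hz plus a 50 Hz / 5 Hz-wide
#'   notch for the reference).
#' @export
default_config <- function() {
  wp <- default_wave_params()
  list(
    fs = 500,
    fs_target = NULL,
    reference = "wrist",
    duration = 600,
    n_grid = default_n_grid(),
    heart_vector = list(
      centres = as.list(wp$centres),
      widths = as.list(wp$widths),
      amplitudes = list(x = as.list(wp$amplitudes["x", ]),
                        y = as.list(wp$amplitudes["y", ]),
                        z = as.list(wp$amplitudes["z", ]))
    ),
    schedule = list(rr_mean = 0.85, rr_sd = 0.05, seed = 1L),
    channels = list(wrist = 1.0, neck = 0.2, ear = 0.1, scalp = 0.05),
    noise = NULL,
    filters = list(
      ecg = list(f_lo = 0.5, f_hi = 30, order = 3),
      reference = list(f_lo = 0.5, f_hi = 95, order = 3),
      notch = list(f_c = 50, w = 5)
    )
  )
}

# Recursive merge of user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("config error at '", path, "': expected a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  # free-form sections: channel gains and noise entries
  free <- path %in% c("channels", "noise")
  if (!free && length(unknown) > 0) {
    stop("config error: unknown key '",
         paste0(if (nzchar(path)) paste0(path, "$") else "", unknown[1], "'"),
         call. = FALSE)
  }
  out <- defaults
  for (k in names(user)) {
    sub <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!free && is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      out[[k]] <- merge_config(defaults[[k]], user[[k]], sub)
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$fs) || cfg$fs <= 0) {
    stop("config error: 'fs' must be a positive number", call. = FALSE)
  }
  if (!is.null(cfg$fs_target)) {
    if (!is.numeric(cfg$fs_target) || cfg$fs_target <= 0 ||
        cfg$fs_target > cfg$fs) {
      stop("config error: 'fs_target' must be positive and <= fs", call. = FALSE)
    }
  }
  ng <- cfg$n_grid
  if (!is.numeric(ng) || length(ng) < 1 || any(ng != round(ng)) || any(ng < 2)) {
    stop("config error: 'n_grid' must contain integers >= 2", call. = FALSE)
  }
  cfg$n_grid <- as.integer(ng)
  if (!is.character(cfg$reference) || length(cfg$reference) != 1L) {
    stop("config error: 'reference' must be a channel name", call. = FALSE)
  }
  if (!is.numeric(cfg$duration) || cfg$duration <= 0) {
    stop("config error: 'duration' must be positive", call. = FALSE)
  }
  sch <- cfg$schedule
  if (!is.numeric(sch$rr_mean) || sch$rr_mean <= 0.4) {
    stop("config error: 'schedule$rr_mean' must exceed 0.4 s", call. = FALSE)
  }
  if (!is.numeric(sch$rr_sd) || sch$rr_sd < 0) {
    stop("config error: 'schedule$rr_sd' must be non-negative", call. = FALSE)
  }
  gains <- unlist(cfg$channels)
  if (!is.numeric(gains) || is.null(names(gains))) {
    stop("config error: 'channels' must map channel names to gains", call. = FALSE)
  }
  if (!cfg$reference %in% names(gains)) {
    stop("config error: reference channel '", cfg$reference,
         "' not in 'channels'", call. = FALSE)
  }
  fl <- cfg$filters
  for (band in c("ecg", "reference")) {
    b <- fl[[band]]
    if (!(b$f_lo > 0 && b$f_lo < b$f_hi)) {
      stop("config error: 'filters$", band, "' band edges invalid", call. = FALSE)
    }
  }
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration, fills defaults (including the
#' ensemble grid N = 2, 8, 16, 32, 64, 120, 180, 240, 300, 420, 540), and
#' rejects unknown keys with the offending key path. An empty file yields the
#' full default set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A validated configuration list of class `earbeat_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      stop("unsupported config format: .", ext, call. = FALSE)
    )
  }
  cfg <- merge_config(default_config(), user)
  cfg <- validate_config(cfg)
  structure(cfg, class = c("earbeat_config", "list"))
}

# Build package objects from a validated config.
config_wave_params <- function(cfg) {
  hv <- cfg$heart_vector
  amp <- rbind(x = unlist(hv$amplitudes$x), y = unlist(hv$amplitudes$y),
               z = unlist(hv$amplitudes$z))
  wave_params(amp, unlist(hv$centres), unlist(hv$widths))
}
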