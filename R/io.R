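# column-synonym map for tracker-export CSV dialects
.track_synonyms <- list(
  track_id = c("TRACK_ID", "track_id", "track", "Track"),
  frame = c("FRAME", "frame", "Frame"),
  time_s = c("POSITION_T", "time_s", "t", "time", "T"),
  x = c("POSITION_X", "x", "X"),
  y = c("POSITION_Y", "y", "Y"))

match_column <- function(nms, candidates, required = TRUE, what = "") {
  hit <- candidates[candidates %in% nms]
  if (length(hit) == 0L) {
    if (required)
      stop_invalid("missing column ", what, "; accepted names: ",
                   paste(candidates, collapse = ", "))
    return(NA_character_)
  }
  hit[1]
}

#' Read bead tracks from a tracker-export CSV
#'
#' Reads a particle-tracker export (one row per detection) into
#' [bead_track()] objects, accepting the common column-name dialects
#' (`TRACK_ID`/`track_id`, `POSITION_T`/`time_s`, `POSITION_X`/`x`, ...).
#' Times come from the time column when present, else from
#' `frame * frame_interval`; positions are scaled by `pixel_size`. The
#' distance to the magnet tip is computed when a tip position is given.
#'
#' @param path CSV file path.
#' @param frame_interval seconds per frame (used when no time column).
#' @param pixel_size um per pixel applied to the positions.
#' @param tip optional c(x, y) tip position in the scaled coordinates (um).
#' @param embryo_id,phase,condition metadata applied to all tracks.
#' @return list of [bead_track()] objects, one per track id.
#' @export
read_tracks <- function(path, frame_interval = 1, pixel_size = 1,
                        tip = NULL, embryo_id = "unknown",
                        phase = "interphase", condition = "control") {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  nms <- names(df)
  c_id <- match_column(nms, .track_synonyms$track_id, what = "track id")
  c_t <- match_column(nms, .track_synonyms$time_s, required = FALSE)
  c_fr <- match_column(nms, .track_synonyms$frame, required = is.na(c_t),
                       what = "frame/time")
  c_x <- match_column(nms, .track_synonyms$x, what = "x position")
  c_y <- match_column(nms, .track_synonyms$y, what = "y position")
  times_all <- if (!is.na(c_t)) as.numeric(df[[c_t]])
               else as.numeric(df[[c_fr]]) * frame_interval
  lapply(split(seq_len(nrow(df)), df[[c_id]]), function(idx) {
    o <- idx[order(times_all[idx])]
    t <- times_all[o]
    if (any(diff(t) <= 0))
      stop_invalid("non-monotone time within track ", df[[c_id]][o[1]])
    pos <- cbind(as.numeric(df[[c_x]][o]), as.numeric(df[[c_y]][o])) * pixel_size
    bead_track(as.character(df[[c_id]][o[1]]), embryo_id, t, pos,
               distance_to_tip = if (is.null(tip)) rep(1, length(t)) else NULL,
               phase = phase, condition = condition, tip = tip)
  })
}

#' Write bead tracks to a tracker-style CSV
#'
#' Inverse of [read_tracks()] (canonical column names, full float
#' precision; the round trip is lossless).
#'
#' @param tracks list of [bead_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, time_s = tr$times,
               x = tr$positions[, 1], y = tr$positions[, 2]))
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write complex-modulus spectra CSV
#'
#' Spectra travel as CSV with columns `frequency_hz`, `g_prime_pa`,
#' `g_double_prime_pa`, `label`; one file may hold several labelled
#' spectra. Values are written at full float precision so the round trip
#' is lossless.
#'
#' @param path CSV path.
#' @return `read_spectra`: named list of [modulus_spectrum()] (one per
#'   label).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path)
  need <- c("frequency_hz", "g_prime_pa", "g_double_prime_pa", "label")
  if (!all(need %in% names(df)))
    stop_invalid("spectra CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$label), function(g) {
    o <- order(g$frequency_hz)
    modulus_spectrum(g$frequency_hz[o], g$g_prime_pa[o],
                     g$g_double_prime_pa[o], label = g$label[1])
  })
}

#' @rdname read_spectra
#' @param spectra a [modulus_spectrum()] or list of them.
#' @return `write_spectra`: `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "modulus_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(s)
    data.frame(frequency_hz = s$frequency_hz, g_prime_pa = s$g_prime,
               g_double_prime_pa = s$g_double_prime, label = s$label)))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment manifest CSV
#'
#' The manifest lists one row per track file with the experiment
#' parameters: embryo id, condition, pulse schedule and calibration id,
#' mirroring the lab bookkeeping table. Referenced track files are checked
#' to exist (relative to the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced track files exist.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path)
  need <- c("track_file", "embryo_id", "condition", "pulse_start_s",
            "pulse_on_s", "pulse_off_s", "calibration_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$track_file))
    stop_invalid("duplicate track_file entries in manifest")
  if (check_files) {
    paths <- file.path(dirname(path), df$track_file)
    bad <- !file.exists(paths)
    if (any(bad))
      stop_invalid("manifest references missing files: ",
                   paste(df$track_file[bad], collapse = ", "))
  }
  df
}

#' Read a simulation configuration file
#'
#' Flat key--value YAML (or JSON, which YAML parses) overriding the
#' defaults of [sim_config()]; every omitted key keeps its default, which
#' is the study configuration. Jeffreys parameters are given as
#' `interphase_k`, `interphase_gamma1`, ... keys.
#'
#' @param path YAML/JSON config path.
#' @param strict error on unknown keys (default); else warn.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  scalar_keys <- c("R", "target_edge_length", "dt", "interphase_duration",
                   "mphase_duration", "g", "Lambda", "tol", "max_iter",
                   "step_cap_frac", "record_every", "seed")
  phase_keys <- c(outer(c("interphase", "mphase"),
                        c("k", "gamma1", "gamma2"), paste, sep = "_"))
  unknown <- setdiff(names(raw), c(scalar_keys, phase_keys))
  if (length(unknown)) {
    msg <- paste("unknown config keys:", paste(unknown, collapse = ", "))
    if (strict) stop_invalid(msg) else warning(msg)
  }
  args <- raw[intersect(names(raw), scalar_keys)]
  for (ph in c("interphase", "mphase")) {
    base <- if (ph == "interphase") interphase_params() else mphase_params()
    for (fld in c("k", "gamma1", "gamma2")) {
      key <- paste(ph, fld, sep = "_")
      if (!is.null(raw[[key]])) base[[fld]] <- raw[[key]]
    }
    args[[ph]] <- jeffreys_params(base$k, base$gamma1, base$gamma2)
  }
  do.call(sim_config, args)
}

#' Write a simulation result CSV
#'
#' Per-step CSV with columns `time_min`, `phase`, `ingression_um`,
#' `band_length_um`, prefixed by comment lines recording the configuration
#' (provenance header).
#'
#' @param result a [run_cycle()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(result, path) {
  cfg <- attr(result, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    hdr <- sprintf(
      "# bandratchet sim: R=%g dt=%g g=%g Lambda=%g tol=%g seed=%s",
      cfg$R, cfg$dt, cfg$g, cfg$Lambda, cfg$tol, as.character(cfg$seed))
    writeLines(hdr, con)
  }
  write.csv(as.data.frame(result), con, row.names = FALSE)
  invisible(path)
}

#' Read a simulation result CSV written by [write_sim_result()]
#'
#' @param path CSV path.
#' @return data.frame with the per-step columns.
#' @export
read_sim_result <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  read.csv(path, comment.char = "#")
}
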