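# Fixed-schema CSV/JSON readers and writers. Every file carries a header
# comment block recording the schema version, the seed and the parameters
# needed to regenerate it.

write_header <- function(con, kind, params) {
  writeLines(sprintf("# smkin %s v1", kind), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm, paste(format(params[[nm]]), collapse = ",")),
               con)
  }
}

read_header <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr)) return(list(kind = NA_character_, params = list()))
  kind <- sub("^# smkin (\\S+) v1$", "\\1", hdr[1L])
  kv <- hdr[-1L]
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  params <- list()
  for (line in kv) {
    s <- sub("^#\\s*", "", line)
    eq <- regexpr("=", s, fixed = TRUE)
    params[[substr(s, 1L, eq - 1L)]] <- substr(s, eq + 1L, nchar(s))
  }
  list(kind = kind, params = params)
}

check_schema <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_smkin(sprintf("%s: missing columns %s", what,
                       paste(miss, collapse = ", ")), "smkin_schema")
  }
}

meta_params <- function(meta) {
  list(frame_interval = meta$frame_interval,
       exposure_time = meta$exposure_time,
       pixel_size = meta$pixel_size,
       field_size = paste(meta$field_size, collapse = "x"),
       n_frames = meta$n_frames)
}

meta_from_params <- function(p) {
  fs <- as.integer(strsplit(p$field_size, "x")[[1L]])
  acquisition_meta(frame_interval = as.numeric(p$frame_interval),
                   exposure_time = as.numeric(p$exposure_time),
                   pixel_size = as.numeric(p$pixel_size),
                   field_size = fs,
                   n_frames = as.integer(p$n_frames))
}

#' Write and read track CSVs
#'
#' Columns: `track_id`, `frame`, `t_s`, `x_um`, `y_um` and optional
#' `state`/`mobility`. Acquisition metadata and any extra parameters are
#' embedded as `# key=value` header comments, so reading needs no side
#' channel.
#'
#' @param tracks A [track_set()].
#' @param path File path.
#' @param params Extra provenance entries (e.g. `seed`).
#' @return `path` (write) or a [track_set()] (read), invisibly for write.
#' @export
write_tracks_csv <- function(tracks, path, params = list()) {
  stopifnot(inherits(tracks, "track_set"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "track_set", c(meta_params(track_meta(tracks)), params))
  utils::write.csv(as.data.frame(tracks), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  hdr <- read_header(path)
  if (!identical(hdr$kind, "track_set")) {
    stop_smkin("not a smkin track_set CSV", "smkin_schema")
  }
  df <- utils::read.csv(path, comment.char = "#")
  check_schema(df, c("track_id", "frame", "t_s", "x_um", "y_um"), "track CSV")
  track_set(df, meta_from_params(hdr$params))
}

#' Write and read dwell-time CSVs
#'
#' Columns: `duration_s`, `censored`, `source`.
#'
#' @param dwells A [dwell_sample()].
#' @param path File path.
#' @param params Extra provenance entries.
#' @return `path` or a [dwell_sample()].
#' @export
write_dwells_csv <- function(dwells, path, params = list()) {
  stopifnot(inherits(dwells, "dwell_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "dwell_sample", params)
  utils::write.csv(as.data.frame(dwells), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwells_csv
#' @export
read_dwells_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_schema(df, c("duration_s", "censored"), "dwell CSV")
  if (is.null(df$source)) df$source <- "unknown"
  dwell_sample(df$duration_s, df$censored, df$source)
}

#' Write and read intensity-trace CSVs
#'
#' Columns: `t_s`, `counts`.
#'
#' @param trace An [intensity_trace()].
#' @param path File path.
#' @param params Extra provenance entries.
#' @return `path` or an [intensity_trace()].
#' @export
write_trace_csv <- function(trace, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "intensity_trace", params)
  utils::write.csv(data.frame(t_s = trace$t_s, counts = trace$counts),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_schema(df, c("t_s", "counts"), "trace CSV")
  intensity_trace(df$t_s, df$counts)
}

#' Append detected change points to a CSV
#'
#' Columns: `index` (0-based first frame of the new segment), `t_s`,
#' `level_before`, `level_after`, `log_odds`.
#'
#' @param cps A [change_point_set()].
#' @param trace The trace the change points belong to (for times).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_change_points_csv <- function(cps, trace, path) {
  stopifnot(inherits(cps, "change_point_set"))
  k <- cps$change_frames
  df <- data.frame(index = k,
                   t_s = trace$t_s[k + 1L],
                   level_before = cps$levels[seq_along(k)],
                   level_after = cps$levels[seq_along(k) + 1L],
                   log_odds = cps$log_odds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read channel-map JSON
#'
#' @param map A `channel_map`.
#' @param path File path.
#' @return `path` or a `channel_map`.
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "channel_map"))
  jsonlite::write_json(
    list(kind = "smkin_channel_map", version = 1L, order = map$order,
         coef_x = as.list(map$coef_x), coef_y = as.list(map$coef_y),
         residual_rms_um = map$residual_rms_um,
         n_fiducials = map$n_fiducials),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_json
#' @export
read_map_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "smkin_channel_map")) {
    stop_smkin("not a smkin channel map JSON", "smkin_schema")
  }
  structure(list(order = as.integer(j$order),
                 coef_x = unlist(j$coef_x), coef_y = unlist(j$coef_y),
                 residual_rms_um = j$residual_rms_um,
                 n_fiducials = as.integer(j$n_fiducials)),
            class = "channel_map")
}

#' Write a kinetic estimate as JSON
#'
#' @param est A `kinetic_estimate`.
#' @param path File path.
#' @param params Extra provenance entries.
#' @return `path`, invisibly.
#' @export
write_kinetics_json <- function(est, path, params = list()) {
  stopifnot(inherits(est, "kinetic_estimate"))
  jsonlite::write_json(c(unclass(est), params), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read escape-scan CSVs
#'
#' Long format: `tau_off`, `cluster_n`, `k_on`, `tau_esc_mean`, `ratio`,
#' `n_rebinds_mean`, `tau_exit_mean`.
#'
#' @param scan Output of [scan_parameter_grid()].
#' @param path File path.
#' @param params Extra provenance entries.
#' @return `path` or the scan data frame.
#' @export
write_escape_csv <- function(scan, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "escape_scan", params)
  utils::write.csv(scan, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_escape_csv
#' @export
read_escape_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_schema(df, c("tau_off", "cluster_n", "k_on", "tau_esc_mean",
                     "ratio"), "escape CSV")
  df
}
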