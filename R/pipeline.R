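# End-to-end pipeline driver: simulate -> (render -> track ->) kinetics,
# stoichiometry, escape scan; each stage writes its artifacts and a shared
# run log.

default_pipeline_config <- function() {
  list(
    stages = c("simulate", "kinetics", "stoich"),
    seed = 1L,
    out_dir = ".",
    sim = list(d_free = 0.44, d_bound = 0.005, v_radial = 0.05,
               k_bind = 0.1, k_off = 1 / 5.2, k_bl = 1 / 30,
               frame_interval = 0.5, exposure_time = 0.45,
               pixel_size = 0.105, field_size = 48L, n_frames = 240L,
               n_tracks = 12L),
    render = list(psf_sigma = 0.125, photons_per_frame = 400,
                  substeps = 25L, offset = 100, read_sd = 2),
    track = list(max_disp = 0.5, max_gap = 0L, intensity_min = 50,
                 window = 3L),
    kin = list(tau_bl = 30, tau_bl_sem = 0, censor_policy = "exclude",
               dwells_csv = NULL),
    stoich = list(unit_photons = 47, n_calib = 6L, m_feature = 3L,
                  labeled_fraction = 0.5, window_um = 0.315),
    escape = list(tau_off = 5.2, cluster = c(1, 100), k_on = 0.17,
                  n_iter = 200L))
}

merge_config <- function(user, defaults, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop_smkin(sprintf("unknown configuration key: %s", full),
                 "smkin_unknown_key")
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Run the synthetic single-molecule pipeline
#'
#' Executes the selected stages in order and writes their artifacts to
#' `out_dir`:
#' \describe{
#'   \item{simulate}{two-state trajectories with ground truth ->
#'     `tracks.csv`, `dwells.csv`}
#'   \item{render}{camera movie of the simulated tracks -> `stack.tif`}
#'   \item{track}{detect + link + mobility-classify the rendered movie ->
#'     `tracked.csv`, `dwells_classified.csv`}
#'   \item{kinetics}{photobleach-corrected off time from the best available
#'     dwell sample (an explicit CSV, the classified dwells, or the
#'     simulated ones) -> `kinetics.json`}
#'   \item{stoich}{miniature two-channel recruitment experiment: renders a
#'     stack holding one multi-molecule feature plus single-molecule
#'     calibration emitters, integrates, calibrates and counts ->
#'     `stoich.json`}
#'   \item{escape}{cluster-escape parameter scan -> `escape.csv`}
#' }
#' A `run_log.txt` records the package version, seed, stages and the full
#' parameter echo. Unknown configuration keys raise an error naming the
#' key; a stage whose upstream artifact is absent raises a dependency
#' error.
#'
#' @param config Nested list overriding the defaults (see
#'   `smkin:::default_pipeline_config()`); top-level keys `stages`,
#'   `seed`, `out_dir` and sections `sim`, `render`, `track`, `kin`,
#'   `stoich`, `escape`.
#' @return Invisibly, a list with the written file paths and the stage
#'   summaries.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config, default_pipeline_config())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       sprintf(...)), log_con)
  }
  logmsg("smkin %s pipeline start; seed = %d; stages = %s",
         as.character(utils::packageVersion("smkin")), cfg$seed,
         paste(cfg$stages, collapse = ", "))
  logmsg("config: %s", jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 8))

  files <- list(); out <- list()
  prov <- list(seed = cfg$seed)
  sim <- NULL; stack <- NULL; classified <- NULL

  meta <- acquisition_meta(frame_interval = cfg$sim$frame_interval,
                           exposure_time = cfg$sim$exposure_time,
                           pixel_size = cfg$sim$pixel_size,
                           field_size = cfg$sim$field_size,
                           n_frames = cfg$sim$n_frames)

  if ("simulate" %in% cfg$stages) {
    logmsg("stage simulate: %d tracks, %d frames", cfg$sim$n_tracks,
           meta$n_frames)
    params <- sim_kinetic_params(d_free = cfg$sim$d_free,
                                 d_bound = cfg$sim$d_bound,
                                 v_radial = cfg$sim$v_radial,
                                 k_bind = cfg$sim$k_bind,
                                 k_off = cfg$sim$k_off,
                                 k_bl = cfg$sim$k_bl)
    sim <- simulate_two_state_tracks(params, meta, cfg$sim$n_tracks,
                                     boundary = "reflect", seed = cfg$seed)
    files$tracks <- file.path(cfg$out_dir, "tracks.csv")
    write_tracks_csv(sim$tracks, files$tracks, prov)
    files$dwells <- file.path(cfg$out_dir, "dwells.csv")
    write_dwells_csv(dwells_from_truth(sim$truth), files$dwells, prov)
    out$n_dwells <- nrow(read_dwells_csv(files$dwells))
  }

  if ("render" %in% cfg$stages) {
    if (is.null(sim)) {
      stop_smkin("render stage requires the simulate stage",
                 "smkin_missing_dependency")
    }
    logmsg("stage render: psf %.3g um, %g photons/frame",
           cfg$render$psf_sigma, cfg$render$photons_per_frame)
    stack <- render_frames(sim$tracks, psf_sigma = cfg$render$psf_sigma,
                           photons_per_frame = cfg$render$photons_per_frame,
                           substeps = cfg$render$substeps,
                           noise = camera_noise(cfg$render$offset,
                                                cfg$render$read_sd),
                           bridge_d = c(FREE = cfg$sim$d_free,
                                        BOUND = cfg$sim$d_bound),
                           seed = cfg$seed + 1L)
    files$stack <- file.path(cfg$out_dir, "stack.tif")
    write_frame_stack(stack, files$stack)
  }

  if ("track" %in% cfg$stages) {
    if (is.null(stack)) {
      stop_smkin("track stage requires the render stage",
                 "smkin_missing_dependency")
    }
    logmsg("stage track: max_disp %.3g um", cfg$track$max_disp)
    locs <- detect_spots_stack(stack, intensity_min = cfg$track$intensity_min,
                               pixel_size = meta$pixel_size)
    tracked <- link_tracks(locs, meta, max_disp = cfg$track$max_disp,
                           max_gap = cfg$track$max_gap)
    steps <- step_size_distribution(tracked)
    fit <- fit_mobility_mixture(steps)
    classified <- classify_bound_segments(tracked, fit,
                                          window = cfg$track$window)
    files$tracked <- file.path(cfg$out_dir, "tracked.csv")
    write_tracks_csv(classified$tracks, files$tracked, prov)
    files$dwells_classified <- file.path(cfg$out_dir, "dwells_classified.csv")
    write_dwells_csv(classified$dwells, files$dwells_classified, prov)
    out$mobility_fit <- fit
  }

  if ("kinetics" %in% cfg$stages) {
    dwells <- if (!is.null(cfg$kin$dwells_csv)) {
      if (!file.exists(cfg$kin$dwells_csv)) {
        stop_smkin(sprintf("dwell CSV not found: %s", cfg$kin$dwells_csv),
                   "smkin_missing_dependency")
      }
      read_dwells_csv(cfg$kin$dwells_csv)
    } else if (!is.null(classified)) {
      classified$dwells
    } else if (!is.null(sim)) {
      dwells_from_truth(sim$truth)
    } else {
      stop_smkin(
        "kinetics stage needs kin.dwells_csv or an upstream dwell sample",
        "smkin_missing_dependency")
    }
    logmsg("stage kinetics: %d events, tau_bl = %.4g s", nrow(dwells),
           cfg$kin$tau_bl)
    est <- estimate_kinetics(dwells, tau_bl = cfg$kin$tau_bl,
                             tau_bl_sem = cfg$kin$tau_bl_sem,
                             censor_policy = cfg$kin$censor_policy)
    files$kinetics <- file.path(cfg$out_dir, "kinetics.json")
    write_kinetics_json(est, files$kinetics, prov)
    out$kinetics <- est
  }

  if ("stoich" %in% cfg$stages) {
    logmsg("stage stoich: %d-molecule feature, %d calibration traces",
           cfg$stoich$m_feature, cfg$stoich$n_calib)
    st <- stoich_mini_experiment(cfg, meta)
    files$stoich <- file.path(cfg$out_dir, "stoich.json")
    jsonlite::write_json(c(unclass(st$result), prov), files$stoich,
                         auto_unbox = TRUE, digits = NA)
    out$stoich <- st$result
  }

  if ("escape" %in% cfg$stages) {
    logmsg("stage escape: tau_off %s, clusters %s, k_on %s",
           paste(cfg$escape$tau_off, collapse = ","),
           paste(cfg$escape$cluster, collapse = ","),
           paste(cfg$escape$k_on, collapse = ","))
    scan <- scan_parameter_grid(cfg$escape$tau_off, cfg$escape$cluster,
                                cfg$escape$k_on,
                                base = escape_config(n_iter = cfg$escape$n_iter),
                                base_seed = cfg$seed)
    files$escape <- file.path(cfg$out_dir, "escape.csv")
    write_escape_csv(scan, files$escape, prov)
    out$escape <- scan
  }

  logmsg("pipeline done: %s", paste(unlist(files), collapse = ", "))
  invisible(list(files = files, results = out, config = cfg))
}

# Miniature rendered two-channel stoichiometry experiment: one feature of
# m unit-brightness emitters plus n_calib isolated single emitters that
# photobleach in one step; integration + calibration recover m.
stoich_mini_experiment <- function(cfg, meta) {
  s <- cfg$stoich
  nf <- min(meta$n_frames, 60L)
  m2 <- acquisition_meta(frame_interval = meta$frame_interval,
                         exposure_time = meta$exposure_time,
                         pixel_size = meta$pixel_size,
                         field_size = meta$field_size,
                         n_frames = nf)
  ext <- field_extent_um(m2)
  # Feature: m coincident emitters at the field center, never bleaching.
  anchor_xy <- ext / 2
  rows <- list()
  for (j in seq_len(s$m_feature)) {
    rows[[j]] <- data.frame(track_id = j, frame = 0:(nf - 1L),
                            t_s = (0:(nf - 1L)) * m2$frame_interval,
                            x_um = anchor_xy[1], y_um = anchor_xy[2],
                            state = "BOUND")
  }
  # Calibration emitters on a ring, each bleaching in one step mid-movie.
  bleach_frame <- round(nf * seq(0.5, 0.85, length.out = s$n_calib))
  r_ring <- 0.35 * min(ext)
  for (k in seq_len(s$n_calib)) {
    ang <- 2 * pi * k / s$n_calib
    x <- anchor_xy[1] + r_ring * cos(ang)
    y <- anchor_xy[2] + r_ring * sin(ang)
    rows[[s$m_feature + k]] <- data.frame(
      track_id = s$m_feature + k, frame = 0:(bleach_frame[k] - 1L),
      t_s = (0:(bleach_frame[k] - 1L)) * m2$frame_interval,
      x_um = x, y_um = y, state = "BOUND")
  }
  tr <- track_set(do.call(rbind, rows), m2)
  stack <- render_frames(tr, psf_sigma = cfg$render$psf_sigma,
                         photons_per_frame = s$unit_photons,
                         substeps = 1L,
                         noise = camera_noise(cfg$render$offset,
                                              cfg$render$read_sd),
                         seed = cfg$seed + 2L)
  # Anchor track for the feature and for each calibration emitter, spanning
  # the full movie so the bleach step is visible in the integrated trace.
  full <- function(id, x, y) data.frame(
    track_id = id, frame = 0:(nf - 1L),
    t_s = (0:(nf - 1L)) * m2$frame_interval, x_um = x, y_um = y)
  anchors <- rbind(
    full(1L, anchor_xy[1], anchor_xy[2]),
    do.call(rbind, lapply(seq_len(s$n_calib), function(k) {
      ang <- 2 * pi * k / s$n_calib
      full(1L + k, anchor_xy[1] + r_ring * cos(ang),
           anchor_xy[2] + r_ring * sin(ang))
    })))
  traces <- integrate_local_intensity(stack, track_set(anchors, m2),
                                      window_um = s$window_um)
  calib <- calibrate_single_molecule_intensity(traces[-1L])
  feature_mean <- mean(traces[[1L]]$counts, na.rm = TRUE)
  feature_sem <- stats::sd(traces[[1L]]$counts, na.rm = TRUE) /
    sqrt(sum(is.finite(traces[[1L]]$counts)))
  res <- estimate_stoichiometry(feature_mean, calib$unit,
                                labeled_fraction = s$labeled_fraction,
                                feature_sem = feature_sem,
                                unit_sem = ifelse(is.na(calib$sem), 0,
                                                  calib$sem))
  list(result = res, calib = calib, traces = traces)
}
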