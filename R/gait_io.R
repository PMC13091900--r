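#' Motion and force data I/O, and the synthetic gait generator
#'
#' TRC (text motion-capture) and plain CSV readers/writers for marker,
#' ground-reaction-force and muscle-force time series, YAML configuration
#' round-tripping, and a seeded generator that produces a synthetic
#' stance-phase record (markers + GRF + muscle samples) emulating the
#' canonical waveform shapes: double-peaked vertical GRF,
#' braking-then-propulsive anteroposterior GRF, small mediolateral
#' component, and an advancing, tilting tibia.
#'
#' @name gait_io
NULL

#' Read / write TRC marker files
#'
#' Minimal TRC dialect: the standard 5-line header (file type, field
#' names, values, marker names, coordinate labels) followed by
#' frame/time/XYZ columns. Units are normalized to mm on read.
#'
#' @param path file path
#' @return `read_trc`: list with `rate` (Hz), `markers` (character),
#'   `time` (ms), and `data` (frames x markers x 3 array, mm)
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1])) {
    stop("read_trc: malformed TRC header (line 1)")
  }
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- hdr[["Units"]]
  scale <- switch(units, mm = 1, m = 1000, cm = 10,
                  stop("read_trc: unknown units ", units))
  marker_line <- strsplit(lines[4], "\t")[[1]]
  markers <- marker_line[-(1:2)]
  markers <- markers[markers != ""]
  if (length(markers) != n_markers) {
    stop("read_trc: marker count mismatch (line 4)")
  }
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_frames) {
    stop(sprintf("read_trc: expected %d frames, found %d (truncated file?)",
                 n_frames, length(body)))
  }
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t")[[1]]))
    if (length(v) != 2 + 3 * n_markers || any(is.na(v))) {
      stop("read_trc: bad data row at line ", i + 5)
    }
    v
  })
  M <- do.call(rbind, rows)
  data <- array(NA_real_, c(n_frames, n_markers, 3),
                dimnames = list(NULL, markers, c("x", "y", "z")))
  for (k in seq_len(n_markers)) {
    data[, k, ] <- M[, 2 + (3 * (k - 1) + 1):(3 * k)] * scale
  }
  list(rate = rate, markers = markers, time = M[, 2] * 1000, data = data)
}

#' @rdname read_trc
#' @param trajectories frames x markers x 3 array, mm (dimnames give the
#'   marker names)
#' @param rate sampling rate, Hz
#' @return `write_trc`: the path, invisibly
#' @export
write_trc <- function(trajectories, rate, path) {
  dm <- dim(trajectories)
  n_frames <- dm[1]; n_markers <- dm[2]
  markers <- dimnames(trajectories)[[2]]
  if (is.null(markers)) markers <- paste0("M", seq_len(n_markers))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
          collapse = "\t"),
    paste(c(rate, rate, n_frames, n_markers, "mm", rate, 1, n_frames),
          collapse = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(markers, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), n_markers),
                           rep(seq_len(n_markers), each = 3))),
          collapse = "\t")), con)
  tt <- (seq_len(n_frames) - 1) / rate
  for (i in seq_len(n_frames)) {
    row <- c(i, sprintf("%.6f", tt[i]),
             sprintf("%.6f", as.vector(t(trajectories[i, , ]))))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

.read_timeseries_csv <- function(path, required) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  t <- df[[required[1]]]
  if (anyNA(t)) stop("non-numeric time column")
  if (any(duplicated(t))) stop("duplicate timestamps")
  if (any(diff(t) <= 0)) stop("non-monotone time column")
  df
}

#' Read a ground-reaction-force CSV
#'
#' Columns `t` (ms), `Fx`, `Fy`, `Fz` (N). Time must be strictly
#' increasing without duplicates.
#'
#' @param path file path
#' @return data frame with the validated series
#' @export
read_grf_csv <- function(path) {
  .read_timeseries_csv(path, c("t", "Fx", "Fy", "Fz"))
}

#' Read a muscle-force CSV
#'
#' Columns `pct` (stance percentage, strictly increasing) and one column
#' per muscle (TS, TA, EDL, EHL), forces in N.
#'
#' @param path file path
#' @return data frame with the validated profiles
#' @export
read_muscle_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("pct", "TS", "TA", "EDL", "EHL")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_muscle_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(diff(df$pct) <= 0)) {
    stop("read_muscle_csv: 'pct' must be strictly increasing")
  }
  if (any(as.matrix(df[need[-1]]) < 0)) {
    stop("read_muscle_csv: negative forces")
  }
  df
}

#' Resample a time series to a new grid by linear interpolation
#' @param t,x original grid and values (x may be a matrix, rows = t)
#' @param t_out target grid
#' @return values on `t_out`
#' @export
resample_series <- function(t, x, t_out) {
  if (is.matrix(x)) {
    apply(x, 2, function(col) interp_clamped(t_out, t, col))
  } else {
    interp_clamped(t_out, t, x)
  }
}

#' Synthetic gait parameters
#'
#' @param body_mass kg
#' @param stance_duration ms
#' @param foot_length mm (matches the model build scale)
#' @param sampling_rate Hz (>= 100)
#' @param seed integer seed
#' @param marker_noise mm (sd of added marker noise)
#' @param grf_noise N (sd of added GRF noise)
#' @return a `synthetic_gait_params` list
#' @export
synthetic_gait_params <- function(body_mass = 72, stance_duration = 700,
                                  foot_length = 255, sampling_rate = 200,
                                  seed = 0L, marker_noise = 0,
                                  grf_noise = 0) {
  if (sampling_rate < 100) {
    stop("synthetic_gait_params: sampling_rate must be >= 100 Hz")
  }
  vals <- c(body_mass, stance_duration, foot_length, sampling_rate)
  if (any(vals <= 0)) stop("synthetic_gait_params: all values must be > 0")
  list(body_mass = body_mass, stance_duration = stance_duration,
       foot_length = foot_length, sampling_rate = sampling_rate,
       seed = as.integer(seed), marker_noise = marker_noise,
       grf_noise = grf_noise)
}

#' Generate a synthetic stance-phase gait record
#'
#' Deterministic per seed. The vertical GRF is a double-peaked waveform
#' (peaks about 1.1 BW near 25 % and 75 % stance, valley about 0.75 BW);
#' the anteroposterior GRF is a braking-then-propulsion wave with zero
#' crossing near mid-stance and near-zero net impulse; the mediolateral
#' component is small. The three tibial markers (medial malleolus,
#' lateral malleolus, tibial tuberosity) follow an advancing shank that
#' tilts from a posterior lean at heel contact through vertical near 20 %
#' stance to an anterior lean at toe-off, with heel rise in late stance.
#'
#' @param params a [synthetic_gait_params()] list
#' @param model optional `foot_model` whose build landmarks define the
#'   marker offsets (default: a fresh default build)
#' @return a `gait_record`: `time` (ms), `pct`, `markers`
#'   (frames x 3 markers x 3, mm), `grf` (frames x 3: Fx anterior, Fy
#'   medial, Fz vertical, N), `muscles` (profile data frame),
#'   `body_weight` (N), `stance_window` (ms), `params`
#' @export
synthesize_gait <- function(params = synthetic_gait_params(),
                            model = NULL) {
  if (is.null(model)) {
    model <- build_foot(foot_build_params(scale = params$foot_length))
  }
  bw <- params$body_mass * GRAVITY_MS2 # N
  dur <- params$stance_duration
  dt <- 1000 / params$sampling_rate
  time <- seq(0, dur, by = dt)
  s <- time / dur # normalized stance time [0, 1]

  # vertical: two Gaussian bumps (peaks ~1.1 BW at 25/75 % stance) over a
  # plateau giving a ~0.75 BW mid-stance valley, windowed at the ends
  env <- (1 - exp(-(s / 0.06)^2)) * (1 - exp(-((1 - s) / 0.06)^2))
  fz <- bw * (0.368 * exp(-((s - 0.25) / 0.13)^2) +
              0.368 * exp(-((s - 0.75) / 0.13)^2) + 0.732) * env
  # anteroposterior (x anterior positive): braking < 0 then propulsion > 0,
  # odd about mid-stance so the net impulse vanishes
  fx <- -bw * 0.17 * sin(2 * pi * s) * sin(pi * s)^0.25
  # mediolateral: small medial bump
  fy <- bw * 0.05 * sin(pi * s)^2

  grf <- cbind(Fx = fx, Fy = fy, Fz = fz)

  # shank kinematics: ankle center advances, sits high at heel strike,
  # dips with load (pad compression) and rises as the heel lifts
  ankle0 <- landmark_position(model, "ankle_center")
  # the ankle advances about half a foot length relative to the planted
  # foot: from just behind its neutral position at heel strike to above
  # the metatarsal heads at toe-off
  adv <- params$foot_length * 0.5
  xs <- ankle0[1] + adv * (s - 0.2) * (0.55 + 0.45 * s)
  # pad-compression dip: deep enough that the heel pad bottoms out and
  # the foot rolls flat, sharing load with the forefoot by mid-stance
  drop_v <- 10 * (fz / bw)
  strike_lift <- 6 * exp(-(s / 0.06)^2)
  # heel rise paced gently enough that the foot keeps rolling over the
  # loaded forefoot pads instead of lifting off wholesale
  heel_rise <- 50 * pmax(0, (s - 0.55) / 0.45)^1.8
  zs <- ankle0[3] - drop_v + strike_lift + heel_rise
  ys <- ankle0[2] + 2 * sin(pi * s)
  # shank pitch about y: -18 deg (posterior lean) through near-vertical at
  # 20 % stance to ~+27 deg anterior lean at toe-off
  pitch <- (-18 + 40 * (0.12 + 0.88 * s^0.85) *
              (1 + 0.3 * pmax(0, s - 0.6))) * pi / 180
  pitch <- pmin(pitch, 28 * pi / 180)

  tibia0 <- model$bones$tibia$centroid
  lm <- list(
    medial_malleolus = landmark_position(model, "medial_malleolus"),
    lateral_malleolus = landmark_position(model, "lateral_malleolus"),
    tibial_tuberosity = landmark_position(model, "tibial_tuberosity"))
  offs <- lapply(lm, function(p) p - ankle0)

  nfr <- length(time)
  markers <- array(NA_real_, c(nfr, 3, 3),
                   dimnames = list(NULL, names(lm), c("x", "y", "z")))
  for (i in seq_len(nfr)) {
    R <- rot_y(pitch[i])
    ank <- c(xs[i], ys[i], zs[i])
    for (k in seq_along(offs)) {
      markers[i, k, ] <- ank + as.numeric(R %*% offs[[k]])
    }
  }

  if (params$marker_noise > 0 || params$grf_noise > 0) {
    set.seed(params$seed)
    if (params$marker_noise > 0) {
      markers <- markers + stats::rnorm(length(markers),
                                        sd = params$marker_noise)
    }
    if (params$grf_noise > 0) {
      grf <- grf + stats::rnorm(length(grf), sd = params$grf_noise)
    }
  }

  structure(list(time = time, pct = 100 * s, markers = markers, grf = grf,
                 muscles = default_muscle_profiles(), body_weight = bw,
                 stance_window = c(0, dur), params = params),
            class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat("<gait_record>\n")
  cat(sprintf("  %d frames over %g ms (%g Hz), body weight %.1f N\n",
              length(x$time), diff(range(x$time)),
              x$params$sampling_rate, x$body_weight))
  cat(sprintf("  peak vertical GRF %.2f BW, AP range [%.2f, %.2f] BW\n",
              max(x$grf[, "Fz"]) / x$body_weight,
              min(x$grf[, "Fx"]) / x$body_weight,
              max(x$grf[, "Fx"]) / x$body_weight))
  invisible(x)
}

#' Write / read a gait record's GRF as CSV
#' @param record a `gait_record`
#' @param path file path
#' @return the path (write) or a data frame (read), invisibly
#' @export
write_grf_csv <- function(record, path) {
  df <- data.frame(t = record$time, Fx = record$grf[, "Fx"],
                   Fy = record$grf[, "Fy"], Fz = record$grf[, "Fz"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Round-trip a configuration list through YAML
#' @param config a plain named list (numbers, strings, nested lists)
#' @param path file path; `NULL` returns the YAML text
#' @return `write_config`: path or text; `read_config`: the list
#' @export
write_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(config, precision = 17)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_config
#' @param text YAML text (alternative to `path`)
#' @export
read_config <- function(path = NULL, text = NULL) {
  if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
}

#' Write a run manifest next to an output file
#'
#' Records the configuration, seed, package version and timestamp beside
#' a run output so results remain traceable.
#'
#' @param out_path the output the manifest describes
#' @param config configuration list
#' @param seed integer seed used
#' @return the manifest path, invisibly
#' @export
write_run_manifest <- function(out_path, config, seed = NA_integer_) {
  manifest <- list(
    output = basename(out_path),
    seed = seed,
    package_version = as.character(utils::packageVersion("pedsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  path <- paste0(out_path, ".manifest.yaml")
  write_config(manifest, path)
  invisible(path)
}
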