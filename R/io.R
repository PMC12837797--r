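#' Write / read a voluntary-contraction trial as delimited text
#'
#' CSV layout: `time_s`, `lever_angle_deg`, `torque_nm`, then the six
#' envelope columns named by channel. UTF-8, '.' decimal. Speed and
#' lever-arm length travel in a `# key: value` comment header.
#'
#' @param trial A [vct_trial()].
#' @param path Output path.
#' @return `path` invisibly; `read_vct_csv()` returns a [vct_trial()].
#' @export
write_vct_csv <- function(trial, path) {
  stopifnot(inherits(trial, "vct_trial"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# speed_deg_s: %.10g", trial$speed),
               sprintf("# lever_arm_length_m: %.10g",
                       trial$lever_arm_length)), con)
  df <- data.frame(time_s = trial$time, lever_angle_deg = trial$lever_angle,
                   torque_nm = trial$torque)
  df <- cbind(df, as.data.frame(trial$envelopes))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_header_value <- function(lines, key) {
  ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
  if (length(ln) != 1) stop("missing header line '# ", key, ":' in file")
  as.numeric(sub(paste0("^# ", key, ": *"), "", ln))
}

#' @rdname write_vct_csv
#' @export
read_vct_csv <- function(path) {
  lines <- readLines(path, n = 10)
  speed <- read_header_value(lines, "speed_deg_s")
  d_l <- read_header_value(lines, "lever_arm_length_m")
  df <- utils::read.csv(path, comment.char = "#")
  vct_trial(df$time_s, df$lever_angle_deg, df$torque_nm,
            as.matrix(df[, EMG_CHANNELS]), speed, d_l)
}

#' Write / read a lifting-task trial as delimited text
#'
#' CSV layout: `time_s`, six envelope columns, `torso_angle_deg`,
#' `ball_height_m`. The subject record is supplied separately on read.
#'
#' @param trial A [task_trial()].
#' @param path Output path.
#' @param subject Subject record to attach on read.
#' @return `path` invisibly; `read_task_csv()` returns a [task_trial()].
#' @export
write_task_csv <- function(trial, path) {
  stopifnot(inherits(trial, "task_trial"))
  df <- data.frame(time_s = trial$time)
  df <- cbind(df, as.data.frame(trial$envelopes))
  df$torso_angle_deg <- trial$torso_angle
  df$ball_height_m <- trial$ball_height
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_task_csv
#' @export
read_task_csv <- function(path, subject) {
  df <- utils::read.csv(path)
  task_trial(df$time_s, as.matrix(df[, EMG_CHANNELS]),
             df$torso_angle_deg, df$ball_height_m, subject)
}

#' Write / read rest-trial raw traces as delimited text
#'
#' CSV layout: `time_s` plus one raw-signal column per channel.
#'
#' @param traces Named list of [emg_trace()] objects.
#' @param path Output path.
#' @return `path` invisibly; the reader returns the named trace list.
#' @export
write_rest_csv <- function(traces, path) {
  rate <- traces[[1]]$sampling_rate
  df <- data.frame(time_s = (seq_along(traces[[1]]$samples) - 1) / rate)
  for (ch in EMG_CHANNELS) df[[ch]] <- traces[[ch]]$samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rest_csv
#' @export
read_rest_csv <- function(path) {
  df <- utils::read.csv(path)
  rate <- 1 / mean(diff(df$time_s))
  out <- lapply(EMG_CHANNELS, function(ch)
    emg_trace(df[[ch]], rate, ch, "rest"))
  stats::setNames(out, EMG_CHANNELS)
}

#' Write / read a subject record as key-value text
#'
#' @param subject A [subject_record()].
#' @param path File path.
#' @return `path` invisibly; the reader returns a [subject_record()].
#' @export
write_subject_file <- function(subject, path) {
  stopifnot(inherits(subject, "emg_subject"))
  keys <- c("mass", "height", "torso_depth", "torso_width", "leg_length",
            "lever_arm_length")
  writeLines(c(sprintf("id = %s", subject$id),
               sprintf("%s = %.10g", keys,
                       vapply(keys, function(k) subject[[k]], numeric(1)))),
             path)
  invisible(path)
}

#' @rdname write_subject_file
#' @export
read_subject_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, " *= *")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  subject_record(mass = as.numeric(vals[["mass"]]),
                 height = as.numeric(vals[["height"]]),
                 torso_depth = as.numeric(vals[["torso_depth"]]),
                 torso_width = as.numeric(vals[["torso_width"]]),
                 leg_length = as.numeric(vals[["leg_length"]]),
                 lever_arm_length = as.numeric(vals[["lever_arm_length"]]),
                 id = vals[["id"]])
}

#' Write / read a fitted relationship as structured text (JSON)
#'
#' Stores form, specificity, coefficients, speed, muscle, sample count and
#' residual diagnostics, so calibrations can be applied to later task
#' sessions without refitting.
#'
#' @param fit A [force_emg] object.
#' @param path File path.
#' @return `path` invisibly; the reader returns a [force_emg] object
#'   (without the original sample data).
#' @export
write_relationship_json <- function(fit, path) {
  stopifnot(inherits(fit, "force_emg"))
  obj <- list(muscle = fit$muscle, form = fit$form,
              specificity = fit$specificity, speed = fit$speed,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se), rss = fit$rss, n = fit$n,
              sigma = fit$sigma)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_relationship_json
#' @export
read_relationship_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 form = obj$form, specificity = obj$specificity,
                 muscle = obj$muscle, speed = obj$speed,
                 rss = obj$rss, n = obj$n, sigma = obj$sigma,
                 se = unlist(obj$se), fitted = NULL, normalization = NULL,
                 data = NULL),
            class = "force_emg")
}

#' Simulate a full study to disk
#'
#' Generates the whole synthetic cohort and writes, per subject, the
#' delimited-text files the pipeline reads: subject record, raw rest trial,
#' the VCT set (each with its rest-sweep calibration file), and one
#' stoop-to-stand task trial. Ground truth goes to a JSON sidecar the
#' pipeline never reads.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of per-subject directories written.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    synth <- generate_subject(config, i)
    sd <- file.path(out_dir, synth$subject$id)
    dir.create(sd, showWarnings = FALSE)
    write_subject_file(synth$subject, file.path(sd, "subject.txt"))
    write_rest_csv(generate_rest_trial(synth, config),
                   file.path(sd, "rest.csv"))
    for (sp in config$vct_speeds) {
      for (k in seq_along(config$effort_levels)) {
        vct <- generate_vct(synth, config, sp, config$effort_levels[k],
                            trial_id = k)
        write_vct_csv(vct, file.path(sd, sprintf("vct_%g_%d.csv", sp, k)))
        if (k == 1L) {
          utils::write.csv(
            data.frame(angle_deg = vct$rest_sweep$angle,
                       torque_nm = vct$rest_sweep$torque),
            file.path(sd, sprintf("rest_sweep_%g.csv", sp)),
            row.names = FALSE)
        }
      }
    }
    slss <- generate_slss_trial(synth, config)
    write_task_csv(slss, file.path(sd, "slss.csv"))
    truth <- synth$truth
    jsonlite::write_json(
      list(relationships = truth$relationships,
           csa_ratio = truth$csa_ratio, gravity = truth$gravity,
           geometry = as.data.frame(truth$geometry)),
      file.path(sd, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    dirs[i] <- sd
  }
  invisible(dirs)
}
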