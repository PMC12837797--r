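GRAVITY <- 9.81  # m/s^2

#' Construct a subject record
#'
#' Anthropometry used to scale muscle geometry and the upper-body weight
#' term of the load model. Body weight is `mass * 9.81` N.
#'
#' @param mass Body mass, kg.
#' @param height Stature, m.
#' @param torso_depth Sacrum-to-sternum sagittal distance, m.
#' @param torso_width Distance between iliac-crest markers, m.
#' @param leg_length Vertical iliac crest to calcaneus distance, m.
#' @param lever_arm_length Distance from the L4/L5 joint to the dynamometer
#'   lever-arm pad, m. Defaults to 0.30 * height when not measured.
#' @param id Optional subject identifier.
#' @return An object of class `emg_subject`.
#' @export
subject_record <- function(mass, height, torso_depth, torso_width,
                           leg_length, lever_arm_length = 0.30 * height,
                           id = NA_character_) {
  vals <- c(mass = mass, height = height, torso_depth = torso_depth,
            torso_width = torso_width, leg_length = leg_length,
            lever_arm_length = lever_arm_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all subject dimensions must be positive and finite")
  structure(list(id = id, mass = mass, height = height,
                 body_weight = mass * GRAVITY,
                 torso_depth = torso_depth, torso_width = torso_width,
                 leg_length = leg_length,
                 lever_arm_length = lever_arm_length),
            class = "emg_subject")
}

#' @export
print.emg_subject <- function(x, ...) {
  cat(sprintf(paste0("<subject %s> mass %.1f kg (BW %.0f N), height %.2f m, ",
                     "torso %.3f x %.3f m, leg %.2f m\n"),
              format(x$id), x$mass, x$body_weight, x$height,
              x$torso_depth, x$torso_width, x$leg_length))
  invisible(x)
}

#' Torso dimensions from marker positions
#'
#' Computes torso depth (sagittal-axis component of the sacrum-to-sternum
#' vector), torso width (Euclidean distance between the iliac-crest markers)
#' and leg length (vertical distance from iliac crest to calcaneus) from a
#' standing-trial marker frame. Coordinates use a right-handed lab frame with
#' x sagittal (forward) and z vertical (up).
#'
#' @param markers A data.frame with columns `marker`, `x`, `y`, `z` (one row
#'   per marker) containing at least `sacrum`, `sternum`, `l_iliac`,
#'   `r_iliac`, `calcaneus`.
#' @return Named list with `torso_depth`, `torso_width`, `leg_length` (m).
#' @export
measure_torso <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "x", "y", "z") %in% names(markers)))
  need <- c("sacrum", "sternum", "l_iliac", "r_iliac", "calcaneus")
  missing <- setdiff(need, markers$marker)
  if (length(missing) > 0)
    stop("missing marker(s): ", paste(missing, collapse = ", "))
  pos <- function(name) {
    r <- markers[match(name, markers$marker), ]
    c(r$x, r$y, r$z)
  }
  depth <- abs(pos("sternum")[1] - pos("sacrum")[1])
  width <- sqrt(sum((pos("l_iliac") - pos("r_iliac"))^2))
  leg <- abs(pos("l_iliac")[3] - pos("calcaneus")[3])
  list(torso_depth = depth, torso_width = width, leg_length = leg)
}

#' Default anthropometric coefficient table
#'
#' Linear coefficients mapping torso depth and width (m) to muscle
#' cross-sectional area (cm^2) and moment arm (m) for the three sagittal
#' trunk muscle groups. The literature regression values are not reproduced
#' here; these defaults land in physiological ranges at typical torso
#' dimensions (depth ~0.20 m, width ~0.30 m: ES CSA ~20 cm^2, arm ~5.4 cm;
#' RA arm ~9 cm) and are meant to be replaced with study-specific values via
#' [read_coefficient_table()]. All round-trip validation in this package is
#' relative to whichever table is in use.
#'
#' @return A data.frame with one row per muscle group (`ES`, `RA`, `EO`) and
#'   columns `csa_intercept`, `csa_depth`, `csa_width` (cm^2 per m) and
#'   `arm_intercept`, `arm_depth`, `arm_width` (m per m).
#' @export
default_coefficient_table <- function() {
  data.frame(
    muscle = c("ES", "RA", "EO"),
    csa_intercept = c(0, 0, 0),
    csa_depth = c(70, 25, 35),
    csa_width = c(20, 10, 15),
    arm_intercept = c(0, 0, 0),
    arm_depth = c(0.27, 0.45, 0.40),
    arm_width = c(0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Read / write an anthropometric coefficient table
#'
#' The table is stored as plain `key = value` text, one line per
#' muscle-coefficient pair (e.g. `ES.csa_depth = 70`), so it can be edited
#' by hand and kept under version control.
#'
#' @param path File path.
#' @return `read_coefficient_table()` returns the table data.frame;
#'   `write_coefficient_table()` returns `path` invisibly.
#' @export
read_coefficient_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tab <- default_coefficient_table()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed line in coefficient table: ", ln)
    key <- strsplit(trimws(kv[1]), ".", fixed = TRUE)[[1]]
    if (length(key) != 2) stop("malformed key in coefficient table: ", kv[1])
    row <- match(key[1], tab$muscle)
    if (is.na(row)) stop("unknown muscle in coefficient table: ", key[1])
    if (!key[2] %in% names(tab)[-1])
      stop("unknown coefficient in table: ", key[2])
    tab[row, key[2]] <- as.numeric(kv[2])
  }
  tab
}

#' @rdname read_coefficient_table
#' @param table A coefficient table data.frame.
#' @export
write_coefficient_table <- function(table, path) {
  lines <- character(0)
  for (i in seq_len(nrow(table))) {
    for (col in names(table)[-1]) {
      lines <- c(lines, sprintf("%s.%s = %.10g", table$muscle[i], col,
                                table[i, col]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Estimate muscle geometry from subject dimensions
#'
#' Applies the linear anthropometric coefficient table to the subject's
#' torso depth and width, producing one cross-sectional area and one moment
#' arm per muscle group. The two sides of each bilateral pair share this
#' geometry (bilateral forces are treated as equal in the sagittal plane).
#'
#' @param subject An [subject_record()].
#' @param table Coefficient table; defaults to [default_coefficient_table()].
#' @return A data.frame of class `muscle_geometry` with one row per group
#'   (`ES`, `RA`, `EO`) and columns `csa` (cm^2) and `moment_arm` (m).
#' @export
estimate_muscle_geometry <- function(subject,
                                     table = default_coefficient_table()) {
  stopifnot(inherits(subject, "emg_subject"))
  need <- c("ES", "RA", "EO")
  if (!all(need %in% table$muscle))
    stop("coefficient table missing muscle(s): ",
         paste(setdiff(need, table$muscle), collapse = ", "))
  tab <- table[match(need, table$muscle), ]
  geom <- data.frame(
    muscle = need,
    csa = tab$csa_intercept + tab$csa_depth * subject$torso_depth +
      tab$csa_width * subject$torso_width,
    moment_arm = tab$arm_intercept + tab$arm_depth * subject$torso_depth +
      tab$arm_width * subject$torso_width,
    stringsAsFactors = FALSE
  )
  if (any(geom$csa <= 0) || any(geom$moment_arm <= 0))
    stop("coefficient table produced non-positive geometry")
  class(geom) <- c("muscle_geometry", "data.frame")
  geom
}

#' Muscle line-of-action inclinations
#'
#' Assigns each muscle group a single inclination angle used both in the
#' moment balances (through its cosine) and in the vertical force balance
#' (through its sine). ES and RA angles are estimated from the moment arm
#' and the dynamometer lever-arm length as `asin(d_M / d_L)`; the external
#' oblique crossing angle is fixed at 45 degrees. The RA angle can
#' optionally be fixed at 45 degrees as well (`ra_angle_fixed_45`), matching
#' the alternative reading of the abdominal crossing-angle assumption.
#'
#' @param geometry A [estimate_muscle_geometry()] result.
#' @param lever_arm_length Lever-arm length d_L, m (> every moment arm).
#' @param ra_angle_fixed_45 If `TRUE`, set the RA angle to 45 degrees
#'   instead of estimating it from geometry.
#' @return The geometry data.frame with an added `inclination` column
#'   (degrees).
#' @export
muscle_angles <- function(geometry, lever_arm_length,
                          ra_angle_fixed_45 = FALSE) {
  stopifnot(inherits(geometry, "muscle_geometry"))
  if (lever_arm_length <= 0) stop("lever_arm_length must be > 0")
  est <- geometry$muscle %in% c("ES", "RA")
  if (any(geometry$moment_arm[est] >= lever_arm_length))
    stop("moment arm >= lever arm length: inclination undefined")
  inc <- numeric(nrow(geometry))
  inc[est] <- asin(geometry$moment_arm[est] / lever_arm_length) * 180 / pi
  inc[geometry$muscle == "EO"] <- 45
  if (ra_angle_fixed_45) inc[geometry$muscle == "RA"] <- 45
  geometry$inclination <- inc
  geometry
}
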