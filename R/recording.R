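#' Canonical 15-joint skeleton order
#'
#' The joint order used throughout the package: the standard 15-node skeleton
#' exposed by first-generation depth-camera middleware. The order is a
#' package convention (configurable wherever joint names are accepted) since
#' no universal standard exists.
#'
#' @return character vector of 15 joint identifiers.
#' @export
jnp_joints <- function() {
  c("head", "neck", "torso",
    "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_hand", "r_hand",
    "l_hip", "r_hip", "l_knee", "r_knee", "l_foot", "r_foot")
}

#' Construct and validate a skeleton recording
#'
#' One subject-session of quiet stance: 2-D trajectories (x = mediolateral,
#' y = vertical, metres) of 15 body joints sampled at `sample_rate` Hz for
#' `duration` seconds. At the defaults (30 Hz, 40 s) a recording holds
#' exactly 1200 samples per joint.
#'
#' @param samples numeric array `T x 15 x 2` of coordinates in metres.
#' @param subject_id character scalar.
#' @param group `"control"` (young) or `"experimental"` (elderly, the target
#'   class).
#' @param session integer 1..6.
#' @param sample_rate sampling frequency in Hz (default 30).
#' @param duration recording length in seconds (default 40).
#' @param joint_names ordered joint identifiers; default [jnp_joints()].
#' @return an object of class `skeleton_recording`.
#' @export
skeleton_recording <- function(samples, subject_id, group, session,
                               sample_rate = 30, duration = 40,
                               joint_names = jnp_joints()) {
  if (!is.array(samples) || length(dim(samples)) != 3)
    stop("samples must be a T x n_joints x 2 array")
  n_t <- dim(samples)[1]
  if (n_t < 1) stop("recording must contain at least one sample (T >= 1)")
  if (dim(samples)[2] != length(joint_names))
    stop("samples have ", dim(samples)[2], " joints but ",
         length(joint_names), " joint names were given")
  if (length(joint_names) != 15)
    stop("exactly 15 joints are required, got ", length(joint_names))
  if (dim(samples)[3] != 2)
    stop("samples must carry exactly the (x, y) coordinate pair")
  expected_t <- round(sample_rate * duration)
  if (n_t != expected_t)
    stop("T = ", n_t, " does not equal round(sample_rate * duration) = ",
         expected_t)
  if (anyNA(samples) || !all(is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1, ]
    stop("non-finite coordinate at sample ", bad[1], ", joint '",
         joint_names[bad[2]], "', axis ", c("x", "y")[bad[3]])
  }
  group <- match.arg(group, c("control", "experimental"))
  session <- as.integer(session)
  if (is.na(session) || session < 1 || session > 6)
    stop("session must be an integer in 1..6, got ", session)
  dimnames(samples) <- list(NULL, joint_names, c("x", "y"))
  structure(
    list(subject_id = as.character(subject_id), group = group,
         session = session, sample_rate = sample_rate, duration = duration,
         joint_names = joint_names, samples = samples),
    class = "skeleton_recording"
  )
}

#' @export
print.skeleton_recording <- function(x, ...) {
  cat(sprintf(
    "<skeleton_recording> %s session %d (%s)\n  %d samples x %d joints @ %g Hz, %g s\n",
    x$subject_id, x$session, x$group, dim(x$samples)[1],
    length(x$joint_names), x$sample_rate, x$duration))
  invisible(x)
}

#' Write a skeleton recording to CSV
#'
#' Columns: `time_s`, then `<joint>_x`, `<joint>_y` for each joint in
#' canonical order. Time is printed with 6 decimals and coordinates with 9,
#' so a write/read round trip reproduces the samples to 1e-9 m.
#'
#' @param rec a `skeleton_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "skeleton_recording"))
  n_t <- dim(rec$samples)[1]
  tvec <- (seq_len(n_t) - 1) / rec$sample_rate
  coord_names <- as.vector(t(outer(rec$joint_names, c("x", "y"), paste,
                                   sep = "_")))
  flat <- matrix(aperm(rec$samples, c(3, 2, 1)), nrow = n_t, byrow = TRUE)
  lines <- c(
    paste(c("time_s", coord_names), collapse = ","),
    paste(sprintf("%.6f", tvec),
          apply(flat, 1, function(r) paste(sprintf("%.9f", r), collapse = ",")),
          sep = ",")
  )
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a skeleton recording from CSV
#'
#' Inverse of [write_recording()]. The file must carry a `time_s` column
#' followed by 30 coordinate columns named `<joint>_x`, `<joint>_y` in the
#' expected joint order; time must increase monotonically and all values be
#' finite. Validation errors name the offending column or row.
#'
#' @param path CSV file path.
#' @param subject_id,group,session recording metadata (e.g. from a manifest
#'   row).
#' @param sample_rate,duration expected sampling design; defaults inferred
#'   from the time column when `NULL`.
#' @param joint_names expected joint order; default [jnp_joints()].
#' @return a validated `skeleton_recording`.
#' @export
read_recording <- function(path, subject_id, group, session,
                           sample_rate = NULL, duration = NULL,
                           joint_names = jnp_joints()) {
  df <- read.csv(path, check.names = FALSE)
  expected <- c("time_s", as.vector(t(outer(joint_names, c("x", "y"),
                                            paste, sep = "_"))))
  if (!identical(names(df), expected)) {
    missing_cols <- setdiff(expected, names(df))
    extra <- setdiff(names(df), expected)
    stop("recording '", path, "' has wrong columns",
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  n_t <- nrow(df)
  if (n_t < 1) stop("recording '", path, "' is empty")
  tvec <- df$time_s
  if (anyNA(tvec) || any(diff(tvec) <= 0)) {
    row <- which(is.na(tvec) | c(FALSE, diff(tvec) <= 0))[1]
    stop("non-monotone or missing time at row ", row, " of '", path, "'")
  }
  mat <- as.matrix(df[, -1])
  if (anyNA(mat) || !all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], ", column '",
         colnames(mat)[bad[2]], "' of '", path, "'")
  }
  if (is.null(sample_rate))
    sample_rate <- round(1 / stats::median(diff(tvec)))
  if (is.null(duration)) duration <- n_t / sample_rate
  samples <- aperm(array(t(mat), dim = c(2, length(joint_names), n_t)),
                   c(3, 2, 1))
  skeleton_recording(samples, subject_id, group, session,
                     sample_rate = sample_rate, duration = duration,
                     joint_names = joint_names)
}

#' Construct a dataset manifest
#'
#' One row per recording: its path (or id), subject, group and session.
#'
#' @param path character vector of recording paths or ids.
#' @param subject_id,group,session parallel metadata vectors.
#' @return a data frame of class `jnp_manifest`.
#' @export
jnp_manifest <- function(path, subject_id, group, session) {
  df <- data.frame(path = as.character(path),
                   subject_id = as.character(subject_id),
                   group = as.character(group),
                   session = as.integer(session),
                   stringsAsFactors = FALSE)
  class(df) <- c("jnp_manifest", "data.frame")
  df
}

#' Validate a dataset manifest
#'
#' Checks the manifest invariants: unique (subject, session) pairs and
#' group labels restricted to `control` / `experimental`.
#'
#' @param m a manifest data frame (columns `path`, `subject_id`, `group`,
#'   `session`).
#' @return character vector of findings, each naming the offending rows;
#'   empty iff the manifest is valid.
#' @export
validate_manifest <- function(m) {
  findings <- character()
  need <- c("path", "subject_id", "group", "session")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    return(paste0("manifest lacks column(s): ",
                  paste(missing_cols, collapse = ", ")))
  key <- paste(m$subject_id, m$session, sep = "#")
  dup <- which(duplicated(key))
  if (length(dup))
    findings <- c(findings, paste0(
      "duplicated (subject_id, session) pair '", m$subject_id[dup],
      "', session ", m$session[dup], " at row ", dup))
  bad_group <- which(!m$group %in% c("control", "experimental"))
  if (length(bad_group))
    findings <- c(findings, paste0(
      "invalid group label '", m$group[bad_group], "' at row ", bad_group))
  bad_sess <- which(is.na(m$session) | m$session < 1)
  if (length(bad_sess))
    findings <- c(findings, paste0("invalid session at row ", bad_sess))
  findings
}

#' Read / write a manifest CSV
#'
#' @param path CSV path with columns `path, subject_id, group, session`.
#' @return [read_manifest()]: a validated `jnp_manifest`;
#'   [write_manifest()]: `path` invisibly.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- jnp_manifest(df$path, df$subject_id, df$group, df$session)
  fx <- validate_manifest(m)
  if (length(fx)) stop("invalid manifest '", path, "':\n  ",
                       paste(fx, collapse = "\n  "))
  m
}

#' @rdname read_manifest
#' @param m a `jnp_manifest`.
#' @export
write_manifest <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("path,subject_id,group,session",
               paste(m$path, m$subject_id, m$group, m$session, sep = ",")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
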