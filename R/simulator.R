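#' Default upright static pose
#'
#' Joint coordinates (metres) of a relaxed double-leg stance, arms at the
#' sides: x is mediolateral (+ = subject's left in the image), y vertical
#' (+ = up, 0 at the floor).
#'
#' @return 15 x 2 matrix, rows named by [jnp_joints()].
#' @export
default_pose <- function() {
  p <- rbind(
    head       = c( 0.00, 1.70),
    neck       = c( 0.00, 1.55),
    torso      = c( 0.00, 1.15),
    l_shoulder = c( 0.20, 1.45),
    r_shoulder = c(-0.20, 1.45),
    l_elbow    = c( 0.25, 1.15),
    r_elbow    = c(-0.25, 1.15),
    l_hand     = c( 0.28, 0.85),
    r_hand     = c(-0.28, 0.85),
    l_hip      = c( 0.12, 0.95),
    r_hip      = c(-0.12, 0.95),
    l_knee     = c( 0.12, 0.50),
    r_knee     = c(-0.12, 0.50),
    l_foot     = c( 0.14, 0.05),
    r_foot     = c(-0.14, 0.05)
  )
  colnames(p) <- c("x", "y")
  p
}

# Inverted-pendulum gains: sway displacement scales with joint height above
# the ankles, normalized so the pelvis (hip height) has gain 1. Feet are
# anchored (gain 0) unless a phenotype frees them.
pendulum_gains <- function(pose = default_pose(), feet_gain = 0) {
  ankle <- 0.05
  pelvis <- 0.95
  g <- pmax((pose[, "y"] - ankle) / (pelvis - ankle), 0)
  names(g) <- rownames(pose)
  g[c("l_foot", "r_foot")] <- feet_gain
  g
}

#' Define a tremor component
#'
#' A sinusoidal oscillation applied to a subset of joints. Frequencies must
#' sit below the 15 Hz Nyquist limit of the 30 Hz sampling design.
#'
#' @param joints character vector, subset of [jnp_joints()].
#' @param frequency oscillation frequency in Hz, `0 < frequency < 15`.
#' @param amplitude peak displacement in metres, `>= 0`.
#' @param axis `"x"`, `"y"` or `"both"`.
#' @param phase_mode `"symmetric"` (left/right in phase), `"antisymmetric"`
#'   (left/right in counter-phase) or `"independent"` (random phase per
#'   joint).
#' @return an object of class `tremor_component`.
#' @export
tremor_component <- function(joints, frequency, amplitude, axis = "x",
                             phase_mode = "independent") {
  bad <- setdiff(joints, jnp_joints())
  if (length(bad)) stop("unknown joint(s): ", paste(bad, collapse = ", "))
  if (!is.finite(frequency) || frequency <= 0 || frequency >= 15)
    stop("tremor frequency must lie in (0, 15) Hz (Nyquist at 30 Hz ",
         "sampling), got ", frequency)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("tremor amplitude must be >= 0")
  axis <- match.arg(axis, c("x", "y", "both"))
  phase_mode <- match.arg(phase_mode,
                          c("symmetric", "antisymmetric", "independent"))
  structure(list(joints = joints, frequency = frequency,
                 amplitude = amplitude, axis = axis,
                 phase_mode = phase_mode),
            class = "tremor_component")
}

# Phenotype presets. Magnitudes are synthetic calibration values, not
# empirical claims: sway RMS 3 mm (young) / 8 mm (elderly); physiologic
# tremor 8-12 Hz at ~1 mm; essential/parkinsonian-like presets 4-6 Hz at
# 3-8 mm on distal joints; whole-body horizontal shake for the postural
# phenotypes. Each letter mirrors one observed abnormal pattern:
#   A forearm + knee slight tremor          B forearm + hand obvious tremor
#   C whole-body horizontal, left arm more  D whole-body horizontal
#   E symmetric wrists + lower limbs        F intense asymmetric, feet free
phenotype_presets <- function() {
  forearms <- c("l_elbow", "r_elbow", "l_hand", "r_hand")
  body <- setdiff(jnp_joints(), c("l_foot", "r_foot"))
  list(
    stable_young = list(group = "control", sway_rms = 0.003, feet_gain = 0,
                        tremors = list()),
    generic_elderly = list(group = "experimental", sway_rms = 0.008,
                           feet_gain = 0,
                           tremors = list(
                             tremor_component(forearms, 10, 0.001, "x",
                                              "independent"))),
    A = list(group = "experimental", sway_rms = 0.008, feet_gain = 0,
             tremors = list(
               tremor_component(c("l_elbow", "r_elbow", "l_knee", "r_knee"),
                                10, 0.001, "x", "independent"))),
    B = list(group = "experimental", sway_rms = 0.008, feet_gain = 0,
             tremors = list(
               tremor_component(forearms, 9, 0.003, "x", "independent"))),
    C = list(group = "experimental", sway_rms = 0.010, feet_gain = 0,
             tremors = list(
               tremor_component(body, 4.5, 0.004, "x", "symmetric"),
               tremor_component(c("l_elbow", "l_hand"), 5, 0.004, "x",
                                "independent"))),
    D = list(group = "experimental", sway_rms = 0.010, feet_gain = 0,
             tremors = list(
               tremor_component(body, 4.5, 0.004, "x", "symmetric"))),
    E = list(group = "experimental", sway_rms = 0.008, feet_gain = 0,
             tremors = list(
               tremor_component(c("l_hand", "r_hand", "l_knee", "r_knee",
                                  "l_foot", "r_foot"),
                                5, 0.005, "x", "symmetric"))),
    F = list(group = "experimental", sway_rms = 0.012, feet_gain = 0.3,
             tremors = list(
               tremor_component(jnp_joints(), 5, 0.008, "x",
                                "antisymmetric")))
  )
}

#' Generative parameters for one subject
#'
#' Builds a subject profile for a phenotype, with per-subject parameter
#' jitter drawn from the seeded stream so subjects of the same phenotype
#' differ realistically. Deterministic given `(group, phenotype, seed)`.
#'
#' Phenotypes `A`-`F` and `generic_elderly` describe experimental (elderly)
#' subjects; `stable_young` describes control subjects with no tremor.
#'
#' @param group `"control"` or `"experimental"`; must be consistent with the
#'   phenotype.
#' @param phenotype one of `"stable_young"`, `"generic_elderly"`, `"A"`..`"F"`.
#' @param seed integer subject seed.
#' @param jitter logical; `FALSE` freezes every parameter at the preset value
#'   (used by null-control cohorts where all profiles must be identical).
#' @return an object of class `subject_profile`.
#' @export
make_profile <- function(group, phenotype, seed, jitter = TRUE) {
  group <- match.arg(group, c("control", "experimental"))
  presets <- phenotype_presets()
  if (!phenotype %in% names(presets))
    stop("unknown phenotype '", phenotype, "'")
  preset <- presets[[phenotype]]
  if (!identical(preset$group, group))
    stop("phenotype '", phenotype, "' belongs to the ", preset$group,
         " group, not ", group)
  with_seed(derive_seed(seed, 101), {
    jit <- function(x, frac) if (jitter) x * runif(1, 1 - frac, 1 + frac)
      else x
    tremors <- lapply(preset$tremors, function(tc) {
      tremor_component(tc$joints,
                       frequency = min(14.9, jit(tc$frequency, 0.10)),
                       amplitude = jit(tc$amplitude, 0.25),
                       axis = tc$axis, phase_mode = tc$phase_mode)
    })
    structure(
      list(group = group, phenotype = phenotype,
           static_pose = default_pose(),
           sway_rms = jit(preset$sway_rms, 0.20),
           sway_band = c(0.1, 1.0),
           pendulum_gain = pendulum_gains(feet_gain = preset$feet_gain),
           tremors = tremors,
           sensor_noise_sd = 0.0015,
           seed = as.integer(seed)),
      class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s / %s, sway RMS %.1f mm, %d tremor(s), noise %.1f mm\n",
              x$group, x$phenotype, 1000 * x$sway_rms, length(x$tremors),
              1000 * x$sensor_noise_sd))
  invisible(x)
}

# Band-limited sway trace: Ornstein-Uhlenbeck velocity integrated to a
# position series, band-passed (4th order Butterworth, zero phase) to the
# profile's sway band, then normalized to unit RMS. Returns a zero-mean
# series of length n.
sway_trace <- function(n, fs, band) {
  pad <- 4 * fs
  m <- n + 2 * pad
  dt <- 1 / fs
  theta <- 1.0
  v <- filter_ou(rnorm(m), theta, dt)
  p <- cumsum(v) * dt
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, p - mean(p))
  s <- s[(pad + 1):(pad + n)]
  s <- s - mean(s)
  r <- sqrt(mean(s^2))
  if (r > 0) s / r else s
}

# First-order autoregressive smoothing of white noise: the discretized OU
# velocity process.
filter_ou <- function(w, theta, dt) {
  a <- exp(-theta * dt)
  as.numeric(stats::filter(w * sqrt(dt), a, method = "recursive"))
}

#' Simulate one quiet-stance recording
#'
#' The generative model is
#' `static_pose + pendulum_gain[j] * pelvis_sway(t) + tremor sinusoids +
#' i.i.d. Gaussian sensor noise`. Mediolateral (x) sway carries the full
#' profile RMS; a small independent vertical component (25% of the
#' mediolateral RMS) reflects that vertical movement in stance is negligible.
#' Fully reproducible from `(profile, session, seed)`.
#'
#' @param profile a `subject_profile`.
#' @param session integer 1..6.
#' @param seed integer run seed (combined with the profile seed and session
#'   to derive the session substream).
#' @param sample_rate,duration sampling design (defaults 30 Hz, 40 s).
#' @return a `skeleton_recording` with `round(sample_rate * duration)`
#'   samples (1200 at defaults).
#' @export
simulate_recording <- function(profile, session, seed = 0,
                               sample_rate = 30, duration = 40) {
  stopifnot(inherits(profile, "subject_profile"))
  session <- as.integer(session)
  if (is.na(session) || session < 1 || session > 6)
    stop("session must be in 1..6")
  n <- round(sample_rate * duration)
  joints <- jnp_joints()
  with_seed(derive_seed(profile$seed, session, seed), {
    tvec <- (seq_len(n) - 1) / sample_rate
    samples <- array(0, dim = c(n, length(joints), 2),
                     dimnames = list(NULL, joints, c("x", "y")))
    # baseline pose
    for (ax in 1:2)
      samples[, , ax] <- matrix(profile$static_pose[, ax], n,
                                length(joints), byrow = TRUE)
    # pelvis-referenced sway propagated through the pendulum gains
    if (profile$sway_rms > 0) {
      sx <- sway_trace(n, sample_rate, profile$sway_band) * profile$sway_rms
      sy <- sway_trace(n, sample_rate, profile$sway_band) *
        (0.25 * profile$sway_rms)
      g <- profile$pendulum_gain[joints]
      samples[, , 1] <- samples[, , 1] + outer(sx, g)
      samples[, , 2] <- samples[, , 2] + outer(sy, g)
    }
    # segment tremors
    for (tc in profile$tremors) {
      base_phase <- runif(1, 0, 2 * pi)
      for (j in tc$joints) {
        phase <- switch(tc$phase_mode,
          symmetric = base_phase,
          antisymmetric = if (startsWith(j, "r_")) base_phase + pi
                          else base_phase,
          independent = runif(1, 0, 2 * pi))
        wave <- tc$amplitude * sin(2 * pi * tc$frequency * tvec + phase)
        if (tc$axis %in% c("x", "both"))
          samples[, j, 1] <- samples[, j, 1] + wave
        if (tc$axis %in% c("y", "both"))
          samples[, j, 2] <- samples[, j, 2] + wave
      }
    }
    # sensor jitter
    if (profile$sensor_noise_sd > 0)
      samples <- samples + array(rnorm(length(samples), 0,
                                       profile$sensor_noise_sd),
                                 dim = dim(samples))
    skeleton_recording(samples,
                       subject_id = sprintf("s%04d", profile$seed %% 10000L),
                       group = profile$group, session = session,
                       sample_rate = sample_rate, duration = duration)
  })
}

#' Simulate a two-group cohort of recordings
#'
#' Emulates the study design: `n_control` young and `n_experimental` elderly
#' subjects, each recorded for `sessions` standing sessions. Per-subject and
#' per-session seeds are derived from the master seed by integer mixing, so
#' the dataset is reproducible and insertion-order independent. The defaults
#' (20 control, 25 experimental, 6 sessions) reproduce the reference image
#' bookkeeping of 120 control and 150 experimental plots.
#'
#' @param n_control,n_experimental subject counts (>= 1).
#' @param sessions sessions per subject (default 6).
#' @param phenotype_mix named list with elements `control` and
#'   `experimental`, each a named numeric vector of phenotype proportions
#'   summing to 1. Default: all control subjects `stable_young`; experimental
#'   subjects 40% `generic_elderly` and 10% each of phenotypes A-F.
#' @param seed master seed.
#' @return list with elements `manifest` (a `jnp_manifest`; `path` holds the
#'   recording id), `recordings` (named list of `skeleton_recording`) and
#'   `profiles` (named list of `subject_profile`).
#' @export
simulate_dataset <- function(n_control = 20, n_experimental = 25,
                             sessions = 6,
                             phenotype_mix = default_phenotype_mix(),
                             seed = 1) {
  if (n_control < 1 || n_experimental < 1 || sessions < 1)
    stop("subject and session counts must be >= 1")
  for (g in c("control", "experimental")) {
    mix <- phenotype_mix[[g]]
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-8)
      stop("phenotype mix for group '", g, "' must sum to 1")
    presets <- phenotype_presets()
    for (ph in names(mix)) {
      if (!ph %in% names(presets))
        stop("unknown phenotype '", ph, "' in mix")
      if (!identical(presets[[ph]]$group, g))
        stop("phenotype '", ph, "' is not a ", g, "-group phenotype")
    }
  }
  assign_phenotypes <- function(mix, n) {
    counts <- floor(mix * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- mix * n - counts
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    rep(names(mix), times = counts)
  }
  subjects <- data.frame(
    subject_id = c(sprintf("C%03d", seq_len(n_control)),
                   sprintf("E%03d", seq_len(n_experimental))),
    group = rep(c("control", "experimental"),
                c(n_control, n_experimental)),
    phenotype = c(assign_phenotypes(phenotype_mix$control, n_control),
                  assign_phenotypes(phenotype_mix$experimental,
                                    n_experimental)),
    index = c(seq_len(n_control), 1000L + seq_len(n_experimental)),
    stringsAsFactors = FALSE
  )
  profiles <- list()
  recordings <- list()
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    prof <- make_profile(s$group, s$phenotype,
                         seed = derive_seed(seed, s$index))
    profiles[[s$subject_id]] <- prof
    for (ses in seq_len(sessions)) {
      rec <- simulate_recording(prof, session = ((ses - 1) %% 6) + 1,
                                seed = derive_seed(seed, s$index, ses))
      rec$subject_id <- s$subject_id
      id <- sprintf("%s_s%d", s$subject_id, ses)
      recordings[[id]] <- rec
      rows[[length(rows) + 1]] <- data.frame(
        path = id, subject_id = s$subject_id, group = s$group,
        session = ses, stringsAsFactors = FALSE)
    }
  }
  mdf <- do.call(rbind, rows)
  manifest <- jnp_manifest(mdf$path, mdf$subject_id, mdf$group, mdf$session)
  fx <- validate_manifest(manifest)
  if (length(fx)) stop("internal: generated manifest invalid: ", fx[1])
  list(manifest = manifest, recordings = recordings, profiles = profiles)
}

#' @rdname simulate_dataset
#' @export
default_phenotype_mix <- function() {
  list(control = c(stable_young = 1),
       experimental = c(generic_elderly = 0.4, A = 0.1, B = 0.1, C = 0.1,
                        D = 0.1, E = 0.1, F = 0.1))
}

#' Simulate a null-control cohort
#'
#' Leakage control: every subject — whatever its group label — shares one
#' identical profile (the jitter-free `stable_young` parameter set), so the
#' two groups differ in nothing but their labels and noise realizations. Any
#' downstream classification accuracy systematically above chance would
#' indicate information leaking through the pipeline.
#'
#' @inheritParams simulate_dataset
#' @return as [simulate_dataset()].
#' @export
simulate_null_dataset <- function(n_control = 20, n_experimental = 25,
                                  sessions = 6, seed = 1) {
  base <- make_profile("control", "stable_young",
                       seed = derive_seed(seed, 77), jitter = FALSE)
  profiles <- list()
  recordings <- list()
  rows <- list()
  ids <- c(sprintf("C%03d", seq_len(n_control)),
           sprintf("E%03d", seq_len(n_experimental)))
  groups <- rep(c("control", "experimental"), c(n_control, n_experimental))
  for (i in seq_along(ids)) {
    prof <- base
    prof$group <- groups[i]
    profiles[[ids[i]]] <- prof
    for (ses in seq_len(sessions)) {
      rec <- simulate_recording(prof, session = ((ses - 1) %% 6) + 1,
                                seed = derive_seed(seed, i, ses))
      rec$subject_id <- ids[i]
      id <- sprintf("%s_s%d", ids[i], ses)
      recordings[[id]] <- rec
      rows[[length(rows) + 1]] <- data.frame(
        path = id, subject_id = ids[i], group = groups[i], session = ses,
        stringsAsFactors = FALSE)
    }
  }
  mdf <- do.call(rbind, rows)
  list(manifest = jnp_manifest(mdf$path, mdf$subject_id, mdf$group,
                               mdf$session),
       recordings = recordings, profiles = profiles)
}
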