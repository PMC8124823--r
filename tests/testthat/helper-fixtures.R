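# Shared fixtures, built in code at test time.

# A recording with all joints frozen at the static pose (no dynamics).
static_recording <- function(duration = 40, sample_rate = 30,
                             subject = "S1", group = "control",
                             session = 1) {
  n <- round(sample_rate * duration)
  pose <- default_pose()
  samples <- array(0, dim = c(n, 15, 2))
  for (ax in 1:2) samples[, , ax] <- matrix(pose[, ax], n, 15, byrow = TRUE)
  skeleton_recording(samples, subject, group, session,
                     sample_rate = sample_rate, duration = duration)
}

# Profile with every stochastic term switched off.
silent_profile <- function(seed = 1) {
  prof <- make_profile("control", "stable_young", seed = seed)
  prof$sway_rms <- 0
  prof$sensor_noise_sd <- 0
  prof$tremors <- list()
  prof
}

# Small rendered cohort reused by feature/grid tests: n subjects per group,
# few sessions, full-size canvas.
small_cohort <- function(n_per_group = 4, sessions = 2, seed = 11) {
  sim <- simulate_dataset(n_per_group, n_per_group, sessions, seed = seed)
  imgs <- lapply(sim$recordings, render_jnp)
  names(imgs) <- names(sim$recordings)
  list(sim = sim, images = imgs,
       labels = structure(sim$manifest$group, names = sim$manifest$path))
}

# Discrete periodogram: power at the one-sided FFT bins, with bin
# frequencies. Independent oracle for the simulator's spectral content.
periodogram <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2 / n
  k <- seq_len(floor(n / 2))
  list(freq = (k - 1) * fs / n, power = sp[k])
}

# Connected components of a logical mask via flood fill (4-neighbour).
# Independent oracle for disc counting in renderer tests.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1) %% nr + 1
      j <- (p - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(mask)) {
          q <- ii + (jj - 1) * nr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- comp
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  comp
}

# Pixel mask of one palette colour in a rendered image.
colour_mask <- function(img, joint) {
  px <- jnp_pixels(img)
  pal <- img$config$palette[joint, ]
  px[, , 1] == pal[1] & px[, , 2] == pal[2] & px[, , 3] == pal[3]
}
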