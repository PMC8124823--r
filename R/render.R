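#' Default 15-colour joint palette
#'
#' Fifteen saturated, pairwise-distinct RGB colours, one per joint in
#' canonical order, all distinct from the default white background.
#'
#' @return 15 x 3 integer matrix (0-255), rows named by [jnp_joints()].
#' @export
jnp_palette <- function() {
  p <- rbind(
    head       = c(230,  25,  75),
    neck       = c( 60, 180,  75),
    torso      = c(  0, 130, 200),
    l_shoulder = c(245, 130,  48),
    r_shoulder = c(145,  30, 180),
    l_elbow    = c( 70, 240, 240),
    r_elbow    = c(240,  50, 230),
    l_hand     = c(210, 245,  60),
    r_hand     = c(250, 190, 212),
    l_hip      = c(  0, 128, 128),
    r_hip      = c(220, 190, 255),
    l_knee     = c(170, 110,  40),
    r_knee     = c(128,   0,   0),
    l_foot     = c(128, 128,   0),
    r_foot     = c(  0,   0, 128)
  )
  colnames(p) <- c("r", "g", "b")
  storage.mode(p) <- "integer"
  p
}

#' Joint-node plot rendering configuration
#'
#' The raster contract: 875 x 656 pixels, 24-bit RGB, one plotted frame per
#' second over the whole recording (40 markers per joint at the default
#' design). The world window is fixed rather than auto-scaled so that sway
#' magnitude differences between subjects stay visible across images.
#'
#' @param width,height canvas size in pixels (defaults 875 x 656).
#' @param plot_rate plotted frames per second (default 1); must divide the
#'   recording sample rate.
#' @param world_window `c(x_min, x_max, y_min, y_max)` in metres; default
#'   x in \[-1, 1\], y in \[0, 2.2\].
#' @param palette 15 x 3 integer matrix of joint colours.
#' @param marker_radius marker disc radius in pixels (default 2).
#' @param background length-3 RGB background colour (default white).
#' @return an object of class `jnp_config`.
#' @export
jnp_config <- function(width = 875, height = 656, plot_rate = 1,
                       world_window = c(-1, 1, 0, 2.2),
                       palette = jnp_palette(), marker_radius = 2,
                       background = c(255L, 255L, 255L)) {
  if (width < 1 || height < 1) stop("canvas must be at least 1 x 1")
  if (plot_rate <= 0) stop("plot_rate must be positive")
  if (length(world_window) != 4 || world_window[2] <= world_window[1] ||
      world_window[4] <= world_window[3])
    stop("world_window must be c(x_min, x_max, y_min, y_max) with ",
         "x_max > x_min and y_max > y_min")
  if (!is.matrix(palette) || nrow(palette) != 15 || ncol(palette) != 3)
    stop("palette must be a 15 x 3 RGB matrix")
  if (any(palette < 0) || any(palette > 255) ||
      any(background < 0) || any(background > 255))
    stop("colours must lie in 0..255")
  codes <- palette[, 1] * 65536L + palette[, 2] * 256L + palette[, 3]
  bg_code <- background[1] * 65536 + background[2] * 256 + background[3]
  if (anyDuplicated(codes) || any(codes == bg_code))
    stop("palette colours must be pairwise distinct and distinct from the ",
         "background")
  structure(list(width = as.integer(width), height = as.integer(height),
                 bit_depth = 24L, plot_rate = plot_rate,
                 world_window = as.numeric(world_window),
                 palette = palette, marker_radius = as.integer(marker_radius),
                 background = as.integer(background)),
            class = "jnp_config")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map world coordinates to pixel coordinates
#'
#' Linear map of the configured world window onto the canvas, with the y
#' axis inverted so "up" points toward row 0. Rounding is half-away-from-zero
#' (stated explicitly: banker's rounding would diverge across platforms).
#' Out-of-window points are allowed and flagged, not clamped.
#'
#' @param p numeric length-2 `(x, y)` in metres, or an n x 2 matrix.
#' @param cfg a `jnp_config`.
#' @return for a single point, a named vector `c(col, row)` (0-based) with
#'   attribute `inside`; for a matrix, an n x 2 matrix with an `inside`
#'   attribute vector.
#' @export
world_to_pixel <- function(p, cfg) {
  w <- cfg$world_window
  single <- is.null(dim(p))
  if (single) p <- matrix(p, 1, 2)
  col <- round_half_away((p[, 1] - w[1]) / (w[2] - w[1]) * (cfg$width - 1))
  row <- round_half_away((w[4] - p[, 2]) / (w[4] - w[3]) * (cfg$height - 1))
  inside <- col >= 0 & col < cfg$width & row >= 0 & row < cfg$height
  out <- cbind(col = col, row = row)
  if (single) {
    out <- c(col = col[1], row = row[1])
    attr(out, "inside") <- inside[1]
  } else {
    attr(out, "inside") <- inside
  }
  out
}

#' Rasterize a recording into a joint-node plot
#'
#' Frames are decimated to `plot_rate` (every `sample_rate / plot_rate`-th
#' sample starting at the first; the ratio must be an integer — no
#' resampling). For each retained frame, each joint is stamped as a filled
#' disc of `marker_radius` pixels in its palette colour, later joints
#' compositing over earlier ones in canonical order. Discs use an exact
#' centre-distance test with no anti-aliasing, so the output is a pure
#' function of `(recording, config)` and bit-identical across platforms.
#'
#' @param rec a `skeleton_recording`.
#' @param cfg a `jnp_config`.
#' @return an object of class `jnp_image`: list with `pixels` (raw array
#'   `height x width x 3`), `config`, `source_id`, and `report` (frames
#'   plotted, out-of-window point count). A warning is raised when more than
#'   1% of points fall outside the world window.
#' @export
render_jnp <- function(rec, cfg = jnp_config()) {
  stopifnot(inherits(rec, "skeleton_recording"), inherits(cfg, "jnp_config"))
  step <- rec$sample_rate / cfg$plot_rate
  if (abs(step - round(step)) > 1e-9)
    stop("plot_rate ", cfg$plot_rate, " Hz does not divide the sample rate ",
         rec$sample_rate, " Hz; no resampling is performed")
  step <- as.integer(round(step))
  n_t <- dim(rec$samples)[1]
  frames <- seq.int(1L, n_t, by = step)
  # channel planes as integer matrices (height x width)
  planes <- lapply(cfg$background, function(v)
    matrix(as.integer(v), cfg$height, cfg$width))
  r <- cfg$marker_radius
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  n_out <- 0L
  for (f in frames) {
    pts <- world_to_pixel(rec$samples[f, , ], cfg)
    inside <- attr(pts, "inside")
    n_out <- n_out + sum(!inside)
    for (j in seq_len(nrow(pts))) {
      cc <- pts[j, 1] + off$dx
      rr <- pts[j, 2] + off$dy
      keep <- cc >= 0 & cc < cfg$width & rr >= 0 & rr < cfg$height
      if (!any(keep)) next
      idx <- (rr[keep] + 1L) + (cc[keep]) * cfg$height
      for (ch in 1:3) planes[[ch]][idx] <- cfg$palette[j, ch]
    }
  }
  total_pts <- length(frames) * nrow(cfg$palette)
  if (n_out / total_pts > 0.01)
    warning(sprintf("%d of %d plotted points (%.1f%%) fall outside the world window",
                    n_out, total_pts, 100 * n_out / total_pts))
  pixels <- array(as.raw(0), dim = c(cfg$height, cfg$width, 3))
  for (ch in 1:3) pixels[, , ch] <- as.raw(planes[[ch]])
  structure(list(pixels = pixels, config = cfg,
                 source_id = sprintf("%s_s%d", rec$subject_id, rec$session),
                 report = list(frames = length(frames),
                               points_out_of_window = n_out,
                               total_points = total_pts)),
            class = "jnp_image")
}

#' @export
print.jnp_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<jnp_image> %s: %d x %d px, %d-bit RGB (%d frames, %d points out of window)\n",
              x$source_id, d[2], d[1], x$config$bit_depth,
              x$report$frames, x$report$points_out_of_window))
  invisible(x)
}

#' Pixel values of a joint-node plot as integers
#'
#' @param img a `jnp_image`.
#' @return integer array `height x width x 3` with values 0-255.
#' @export
jnp_pixels <- function(img) {
  stopifnot(inherits(img, "jnp_image"))
  array(as.integer(img$pixels), dim = dim(img$pixels))
}

#' Save / load a joint-node plot as PNG
#'
#' Standard 8-bit-per-channel RGB PNG without alpha; `load_png(save_png(x))`
#' is the identity on pixels, and repeated saves of the same image are
#' byte-identical.
#'
#' @param img a `jnp_image`.
#' @param path PNG file path.
#' @return [save_png()]: `path` invisibly; [load_png()]: a `jnp_image`
#'   (with `config` reduced to the canvas geometry for foreign files).
#' @export
save_png <- function(img, path) {
  stopifnot(inherits(img, "jnp_image"))
  png::writePNG(jnp_pixels(img) / 255, target = path)
  invisible(path)
}

#' @rdname save_png
#' @param cfg optional `jnp_config` to attach (canvas size must match).
#' @export
load_png <- function(path, cfg = NULL) {
  px <- png::readPNG(path, info = TRUE)
  info <- attr(px, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 8)
    stop("'", path, "' is a ", info$bit.depth,
         "-bit PNG; only 8-bit-per-channel RGB (24 bpp) is supported")
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("'", path, "' is not a 3-channel RGB PNG (24 bpp required)")
  pix_int <- array(as.integer(round(px * 255)), dim = dim(px))
  if (is.null(cfg)) {
    cfg <- jnp_config(width = dim(px)[2], height = dim(px)[1])
  } else if (cfg$height != dim(px)[1] || cfg$width != dim(px)[2]) {
    stop("PNG size ", dim(px)[2], " x ", dim(px)[1],
         " does not match the config canvas")
  }
  pixels <- array(as.raw(pix_int), dim = dim(px))
  structure(list(pixels = pixels, config = cfg,
                 source_id = tools::file_path_sans_ext(basename(path)),
                 report = list(frames = NA_integer_,
                               points_out_of_window = NA_integer_,
                               total_points = NA_integer_)),
            class = "jnp_image")
}

# Count of pixels that differ from the configured background.
non_background_pixels <- function(img) {
  px <- jnp_pixels(img)
  bg <- img$config$background
  sum(px[, , 1] != bg[1] | px[, , 2] != bg[2] | px[, , 3] != bg[3])
}
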