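#' Canopy image specification
#'
#' Parameters of the synthetic top-down canopy renderer: green leaf ellipses
#' scattered on a soil-coloured background, as seen by a camera mounted
#' above the plants.
#'
#' @param width,height Image size in pixels.
#' @param ground_area Ground area represented by the frame, m^2.
#' @param n_leaves Number of rendered leaf ellipses.
#' @param leaf_radius Mean semi-major axis of a leaf ellipse, px.
#' @param background RGB of the background in \[0, 1\].
#' @param seed Integer seed.
#' @return Object of class `straw_canopy_spec`.
#' @export
canopy_image_spec <- function(width = 320, height = 240, ground_area = 2,
                              n_leaves = 60, leaf_radius = 18,
                              background = c(0.35, 0.25, 0.18),
                              seed = 0) {
  if (width < 1 || height < 1) stop("image must have positive size", call. = FALSE)
  if (n_leaves < 0) stop("n_leaves must be >= 0", call. = FALSE)
  if (leaf_radius <= 0) stop("leaf_radius must be > 0", call. = FALSE)
  if (length(background) != 3L || any(background < 0) || any(background > 1)) {
    stop("background must be an RGB triple in [0, 1]", call. = FALSE)
  }
  structure(list(width = width, height = height, ground_area = ground_area,
                 n_leaves = n_leaves, leaf_radius = leaf_radius,
                 background = background, seed = seed),
            class = "straw_canopy_spec")
}

#' Render a synthetic top-down canopy image
#'
#' Draws randomly placed, rotated green ellipses ("leaves") on the
#' background and reports the exact rendered green-pixel fraction as ground
#' truth for the cover-fraction estimator. Deterministic per seed.
#'
#' @param spec A [canopy_image_spec()].
#' @return List with `image` (array `height x width x 3`, values in
#'   \[0, 1\]) and `cover` (true fraction of pixels painted green).
#' @export
render_canopy_image <- function(spec) {
  stopifnot(inherits(spec, "straw_canopy_spec"))
  w <- spec$width; h <- spec$height
  img <- array(rep(spec$background, each = h * w), dim = c(h, w, 3))
  mask <- matrix(FALSE, h, w)
  if (spec$n_leaves > 0) {
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    leaves <- with_seed(spec$seed + 3L, data.frame(
      cx = stats::runif(spec$n_leaves, 1, w),
      cy = stats::runif(spec$n_leaves, 1, h),
      rx = spec$leaf_radius * stats::runif(spec$n_leaves, 0.6, 1.4),
      ry = spec$leaf_radius * stats::runif(spec$n_leaves, 0.35, 0.8),
      th = stats::runif(spec$n_leaves, 0, pi),
      # green shades; excess-green stays well above any soil background
      r = stats::runif(spec$n_leaves, 0.10, 0.30),
      g = stats::runif(spec$n_leaves, 0.45, 0.80),
      b = stats::runif(spec$n_leaves, 0.05, 0.25)
    ))
    for (i in seq_len(spec$n_leaves)) {
      l <- leaves[i, ]
      dx <- xs - l$cx; dy <- ys - l$cy
      u <- dx * cos(l$th) + dy * sin(l$th)
      v <- -dx * sin(l$th) + dy * cos(l$th)
      inside <- (u / l$rx)^2 + (v / l$ry)^2 <= 1
      if (any(inside)) {
        img[, , 1][inside] <- l$r
        img[, , 2][inside] <- l$g
        img[, , 3][inside] <- l$b
        mask <- mask | inside
      }
    }
  }
  list(image = img, cover = mean(mask))
}

#' Estimate canopy cover (iLAI) from a top-down image
#'
#' Classifies vegetation pixels by excess-green index
#' (`2G - R - B > threshold`) and returns the green-pixel fraction, which is
#' used directly as the intercepted leaf-area index.
#'
#' @param image Array `height x width x 3` with values in \[0, 1\].
#' @param threshold Excess-green classification threshold.
#' @return Cover fraction in \[0, 1\].
#' @export
estimate_ilai_from_image <- function(image, threshold = 0.15) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("image must be an RGB array (height x width x 3)", call. = FALSE)
  }
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  mean(exg > threshold)
}
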