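#' Hough circle transform parameters
#'
#' Mirrors the parameter surface of the classical gradient-method circle
#' transform: `dp` (inverse ratio of accumulator to image resolution),
#' `min_dist` (minimum distance between accepted circle centres), `param1`
#' (edge-strength threshold on the normalized magnitude map, playing the
#' role of the upper Canny threshold), `param2` (centre accumulator vote
#' threshold) and the radius search bounds. `NULL` entries are resolved
#' from the image at detection time: `min_dist = min_dim / 4`,
#' `min_radius = min_dim / 8`, `max_radius = min_dim / 2`.
#'
#' @param dp accumulator downscaling factor, >= 1.
#' @param min_dist minimum inter-centre distance in pixels.
#' @param param1 edge threshold (intensity units on the 0-255 map).
#' @param param2 accumulator vote threshold.
#' @param min_radius,max_radius radius search range in pixels.
#' @return a `hough_params` list.
#' @export
hough_params <- function(dp = 1, min_dist = NULL, param1 = 100,
                         param2 = 50, min_radius = NULL, max_radius = NULL) {
  structure(list(dp = dp, min_dist = min_dist, param1 = param1,
                 param2 = param2, min_radius = min_radius,
                 max_radius = max_radius), class = "hough_params")
}

validate_hough <- function(p) {
  if (p$dp < 1) stop("dp must be >= 1")
  if (p$min_dist <= 0) stop("min_dist must be positive")
  if (p$param1 <= 0 || p$param2 <= 0) stop("param1 and param2 must be positive")
  if (p$min_radius < 0 || p$min_radius > p$max_radius)
    stop("need 0 <= min_radius <= max_radius")
  p
}

resolve_hough <- function(p, dims) {
  m <- min(dims[1:2])
  if (is.null(p$min_dist)) p$min_dist <- m / 4
  if (is.null(p$min_radius)) p$min_radius <- round(m / 8)
  if (is.null(p$max_radius)) p$max_radius <- round(m / 2)
  validate_hough(p)
}

minmax_normalize <- function(x) {
  rng <- range(x)
  # guard against amplifying FFT round-off on (near-)constant images;
  # 1e-6 is negligible on the 0-255 intensity scale
  if (rng[2] - rng[1] < 1e-6) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1]) * 255
}

sobel_pair <- function(m) {
  # returns list(gx, gy) on an (H, W) matrix; x = columns, y = rows
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (cols)
  ky <- t(kx)                                               # d/dy (rows)
  eb <- EBImage::Image(t(m))
  gx <- t(EBImage::imageData(EBImage::filter2(eb, t(kx), boundary = "replicate")))
  gy <- t(EBImage::imageData(EBImage::filter2(eb, t(ky), boundary = "replicate")))
  list(gx = gx, gy = gy)
}

#' Compute a normalized gradient-magnitude edge map
#'
#' Pipeline: Gaussian blur on each RGB channel, 3x3 Sobel first derivatives
#' per channel, root-sum-of-squares combination of the per-channel
#' magnitudes, then min-max normalization to `[0, 255]`. The result
#' emphasises circular plate rims for the Hough stage. The per-pixel
#' gradient direction of the dominant channel is attached as attributes
#' `gx`/`gy` for the detector's gradient voting.
#'
#' @param image an `rgb_image` (H, W, 3).
#' @param blur_kernel odd Gaussian kernel size in pixels.
#' @param blur_sigma Gaussian standard deviation in pixels.
#' @return `(H, W)` matrix of class `edge_map`, values in `[0, 255]`.
#' @export
compute_edge_map <- function(image, blur_kernel = 9L, blur_sigma = 2) {
  if (!is_rgb_image(image)) stop("edge map needs a 3-channel RGB image")
  if (blur_kernel < 1 || blur_kernel %% 2 == 0)
    stop("blur_kernel must be odd and >= 1")
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  brush <- EBImage::makeBrush(blur_kernel, shape = "Gaussian",
                              sigma = blur_sigma)
  mags <- array(0, c(H, W, 3))
  gxs <- array(0, c(H, W, 3)); gys <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    eb <- EBImage::Image(t(img[, , ch]))
    blurred <- t(EBImage::imageData(EBImage::filter2(eb, brush, boundary = "replicate")))
    g <- sobel_pair(blurred)
    gxs[, , ch] <- g$gx; gys[, , ch] <- g$gy
    mags[, , ch] <- sqrt(g$gx^2 + g$gy^2)
  }
  combined <- sqrt(mags[, , 1]^2 + mags[, , 2]^2 + mags[, , 3]^2)
  # direction of the locally strongest channel
  dom <- max.col(matrix(mags, ncol = 3L), ties.method = "first")
  pick <- cbind(seq_len(H * W), dom)
  gx <- matrix(matrix(gxs, ncol = 3L)[pick], H, W)
  gy <- matrix(matrix(gys, ncol = 3L)[pick], H, W)
  structure(minmax_normalize(combined), gx = gx, gy = gy,
            class = "edge_map")
}

#' Detect circular plates on an edge map
#'
#' Gradient-voting Hough circle transform: edge pixels above `param1` vote
#' along their gradient direction (both senses) at every radius in the
#' search range; accumulator local maxima above `param2`, thinned so
#' accepted centres are at least `min_dist` apart, become detections whose
#' radius is the mode of the edge-pixel distance histogram. When the edge
#' map lacks stored gradient directions, directions are estimated by Sobel
#' on the magnitude map itself (radial for an annular ridge).
#'
#' @param edges an [compute_edge_map()] result (or any `(H, W)` matrix of
#'   edge strengths in `[0, 255]`).
#' @param params a [hough_params()]; `NULL` fields resolved from `edges`.
#' @return `data.frame(cx, cy, r, score)` sorted by descending vote score;
#'   zero rows when nothing clears the thresholds.
#' @export
detect_plates <- function(edges, params = hough_params()) {
  mag <- unclass(edges)
  if (!is.matrix(mag)) stop("edges must be a single-channel matrix")
  p <- resolve_hough(params, dim(mag))
  gx <- attr(edges, "gx"); gy <- attr(edges, "gy")
  if (is.null(gx) || is.null(gy)) {
    g <- sobel_pair(mag)
    gx <- g$gx; gy <- g$gy
  }
  res <- cpp_hough_circles(mag, gx, gy, p$dp, p$min_dist, p$param1,
                           p$param2, as.integer(p$min_radius),
                           as.integer(p$max_radius), -1L)
  out <- as.data.frame(res)
  out[order(-out$score), , drop = FALSE]
}

#' Pick the circle that best fits the culture plate
#'
#' Among detections lying fully inside the frame, returns the one with the
#' highest vote score; ties broken by larger radius, then smaller `cy`,
#' then smaller `cx`.
#'
#' @param circles `data.frame(cx, cy, r, score)`.
#' @param image_dims `(H, W)` of the source image.
#' @return one-row `data.frame`, or `NULL` when no circle qualifies.
#' @export
select_best_circle <- function(circles, image_dims) {
  if (is.null(circles) || nrow(circles) == 0) return(NULL)
  H <- image_dims[1]; W <- image_dims[2]
  inside <- circles$cx - circles$r >= 0 & circles$cy - circles$r >= 0 &
    circles$cx + circles$r <= W - 1 & circles$cy + circles$r <= H - 1
  cand <- circles[inside, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  o <- order(-cand$score, -cand$r, cand$cy, cand$cx)
  cand[o[1], , drop = FALSE]
}

#' Crop a detected circle's bounding square and resize
#'
#' Crops the axis-aligned bounding square of the circle (clamped to the
#' image bounds) and resizes it bilinearly to `target`.
#'
#' @param image `rgb_image`.
#' @param circle one-row `data.frame(cx, cy, r)`.
#' @param target output `(h, w)`.
#' @return `rgb_image` of dimension `(target[1], target[2], 3)`.
#' @export
crop_circle <- function(image, circle, target = c(224L, 224L)) {
  stopifnot(target[1] > 0, target[2] > 0)
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- circle$cx[1]; cy <- circle$cy[1]; r <- circle$r[1]
  if (cx + r < 0 || cy + r < 0 || cx - r > W - 1 || cy - r > H - 1)
    stop("circle lies entirely outside the image")
  x0 <- max(0, round(cx - r)); x1 <- min(W - 1, round(cx + r))
  y0 <- max(0, round(cy - r)); y1 <- min(H - 1, round(cy + r))
  sub <- img[(y0:y1) + 1, (x0:x1) + 1, , drop = FALSE]
  resize_rgb(as_rgb_image(sub), h = target[1], w = target[2])
}

#' Annotate detections on a copy of the image
#'
#' Draws each circle's circumference in pure green `(0, 255, 0)` and its
#' centre as a small pure red `(255, 0, 0)` dot; the input is not modified.
#'
#' @param image `rgb_image`.
#' @param circles `data.frame(cx, cy, r)` (possibly empty or `NULL`).
#' @return annotated `rgb_image` copy.
#' @export
annotate_detections <- function(image, circles) {
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (is.null(circles) || nrow(circles) == 0) return(as_rgb_image(img))
  put <- function(yy, xx, col) {
    keep <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
    yy <- yy[keep] + 1; xx <- xx[keep] + 1
    for (ch in 1:3) img[cbind(yy, xx, ch)] <<- col[ch]
  }
  for (i in seq_len(nrow(circles))) {
    cx <- circles$cx[i]; cy <- circles$cy[i]; r <- circles$r[i]
    th <- seq(0, 2 * pi, length.out = max(16, ceiling(4 * pi * r)))
    put(round(cy + r * sin(th)), round(cx + r * cos(th)), c(0, 255, 0))
    dot <- expand.grid(dy = -2:2, dx = -2:2)
    dot <- dot[dot$dy^2 + dot$dx^2 <= 4, ]
    put(round(cy) + dot$dy, round(cx) + dot$dx, c(255, 0, 0))
  }
  as_rgb_image(img)
}
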