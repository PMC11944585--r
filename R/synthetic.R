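#' Species colour profiles for synthetic colonies
#'
#' A `species_profile` captures the chromogenic signature the generator
#' paints: the mean colony colour at the centre, the peripheral (ring)
#' colour it grades into towards the margin, the per-channel standard
#' deviation of the colony's mottled texture, and the spatial correlation
#' length of that mottling. This parameterises the concentric colour zoning
#' typical of *Aspergillus* and *Penicillium* colonies.
#'
#' @param name species label.
#' @param center_rgb,ring_rgb length-3 mean colours, each channel in
#'   `[0, 255]`.
#' @param color_sd per-channel standard deviation of the colony mottling
#'   (intensity units, >= 0).
#' @param texture_scale correlation length of the mottling in pixels
#'   (>= 1; 1 means independent per-pixel texture).
#' @return a `species_profile` list.
#' @export
species_profile <- function(name, center_rgb, ring_rgb, color_sd = 8,
                            texture_scale = 8) {
  stopifnot(length(center_rgb) == 3L, length(ring_rgb) == 3L)
  if (min(center_rgb, ring_rgb) < 0 || max(center_rgb, ring_rgb) > 255)
    stop("profile channel means must lie in [0, 255]")
  if (color_sd < 0) stop("color_sd must be >= 0")
  if (texture_scale < 1) stop("texture_scale must be >= 1")
  structure(list(name = as.character(name),
                 center_rgb = as.numeric(center_rgb),
                 ring_rgb = as.numeric(ring_rgb),
                 color_sd = color_sd, texture_scale = texture_scale),
            class = "species_profile")
}

#' Plate geometry and imaging conditions for one synthetic photograph
#'
#' @param center_xy plate centre `(cx, cy)` in 0-based pixel coordinates.
#' @param radius plate radius in pixels (> 0).
#' @param background `"light"` or `"dark"` backdrop, mirroring the two
#'   imaging set-ups plates are photographed on.
#' @param noise_sd additive Gaussian sensor noise, intensity units.
#' @return a `plate_spec` list.
#' @export
plate_spec <- function(center_xy, radius, background = c("light", "dark"),
                       noise_sd = 5) {
  background <- match.arg(background)
  stopifnot(length(center_xy) == 2L)
  if (radius <= 0) stop("plate radius must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(center_xy = as.numeric(center_xy), radius = radius,
                 background = background, noise_sd = noise_sd),
            class = "plate_spec")
}

# fixed scene tones (8-bit): backdrop greys, agar (Sabouraud-like cream),
# plate rim highlight
.bg_tone <- c(light = 190, dark = 30)
.agar_rgb <- c(205, 193, 156)
.rim_value <- 250
.rim_width <- 3

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a set of chromatically separated species profiles
#'
#' Draws `n_species` colour profiles whose centre colours are pairwise at
#' least `min_distance` apart in RGB Euclidean distance (rejection
#' sampling), so nearest-centroid assignment on mean colony colour is
#' well-posed. Deterministic under `seed`.
#'
#' @param n_species number of species, between 2 and 26.
#' @param seed integer RNG seed.
#' @param min_distance pairwise RGB distance floor between centre colours.
#' @return list of [species_profile()]s named `species_A`, `species_B`, ...
#' @export
make_profile_set <- function(n_species, seed = 1L, min_distance = 60) {
  if (n_species < 2 || n_species > 26)
    stop("n_species must be between 2 and 26")
  run_with_seed(seed, {
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(centers) < n_species) {
      cand <- runif(3, 30, 225)
      ok <- nrow(centers) == 0 ||
        all(sqrt(colSums((t(centers) - cand)^2)) >= min_distance)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 50000L)
        stop("could not place ", n_species, " colours at distance ",
             min_distance, "; lower min_distance")
    }
    lapply(seq_len(n_species), function(i) {
      ring <- pmin(255, pmax(0, centers[i, ] + runif(3, -70, 70)))
      species_profile(paste0("species_", LETTERS[i]),
                      center_rgb = centers[i, ], ring_rgb = ring)
    })
  })
}

# zero-mean mottling field with correlation length `scale`, sd `sd`, one
# channel; built at low resolution and bilinearly upsampled
mottle_field <- function(h, w, scale, sd) {
  if (sd == 0) return(matrix(0, h, w))
  if (scale <= 1) return(matrix(rnorm(h * w, 0, sd), h, w))
  lh <- max(2L, ceiling(h / scale)); lw <- max(2L, ceiling(w / scale))
  low <- matrix(rnorm(lh * lw, 0, sd), lh, lw)
  up <- EBImage::resize(EBImage::Image(t(low)), w = w, h = h)
  t(EBImage::imageData(up))
}

#' Render one synthetic plate photograph
#'
#' Paints, onto a light or dark backdrop: a thin bright rim annulus at the
#' plate radius (the circular edge a Hough detector keys on), a cream agar
#' disc, and a colony disc whose colour grades radially from the profile's
#' centre colour to its ring colour, softened at the margin, with seeded
#' zero-mean mottling. Independent per-pixel Gaussian sensor noise (clipped
#' to `[0, 255]`) is added everywhere.
#'
#' @param profile a [species_profile()].
#' @param spec a [plate_spec()]; its circle must fit inside the canvas.
#' @param canvas `(H, W)` canvas size in pixels.
#' @param seed integer RNG seed.
#' @param colony_frac colony radius as a fraction of the plate radius
#'   (proxy for developmental stage).
#' @param texture logical; paint the mottled texture? (`FALSE` gives the
#'   pure radial gradient.)
#' @return list with `image` (an `rgb_image`) and `circle` (the ground
#'   truth `data.frame(cx, cy, r)` equal to `spec`).
#' @export
render_plate <- function(profile, spec, canvas = c(512L, 512L), seed = 1L,
                         colony_frac = 0.7, texture = TRUE) {
  stopifnot(inherits(profile, "species_profile"), inherits(spec, "plate_spec"))
  H <- canvas[1]; W <- canvas[2]
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]; r <- spec$radius
  if (cx - r < 0 || cy - r < 0 || cx + r > W - 1 || cy + r > H - 1)
    stop("plate circle does not fit inside the canvas")

  run_with_seed(seed, {
    xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
    ys <- matrix(0:(H - 1), H, W)
    dist <- sqrt((xs - cx)^2 + (ys - cy)^2)

    r_col <- colony_frac * r
    inside <- dist <= r                      # plate membership (inclusive)
    rim <- inside & dist >= r - .rim_width
    # soft colony margin: fully colony to 0.85 r_col, fades out by r_col
    alpha <- pmin(1, pmax(0, (r_col - dist) / (0.15 * r_col)))
    w_ring <- pmin(1, dist / r_col)          # centre->ring blend weight

    img <- array(0, c(H, W, 3))
    mot <- if (texture && profile$color_sd > 0) {
      lapply(1:3, function(ch)
        mottle_field(H, W, profile$texture_scale, profile$color_sd))
    } else NULL
    for (ch in 1:3) {
      base <- matrix(.bg_tone[[spec$background]], H, W)
      base[inside] <- .agar_rgb[ch]
      colony <- (1 - w_ring) * profile$center_rgb[ch] +
        w_ring * profile$ring_rgb[ch]
      if (!is.null(mot)) colony <- colony + mot[[ch]]
      base <- (1 - alpha) * base + alpha * colony
      base[rim] <- .rim_value
      if (spec$noise_sd > 0)
        base <- base + rnorm(H * W, 0, spec$noise_sd)
      img[, , ch] <- pmin(255, pmax(0, base))
    }
    list(image = as_rgb_image(img),
         circle = data.frame(cx = cx, cy = cy, r = r))
  })
}

#' Generate a species-labelled synthetic plate dataset on disk
#'
#' Writes `n_per_species` images per profile into one subdirectory per
#' species (the training layout the classifier expects), randomising plate
#' position, radius, colony developmental stage and backdrop per image.
#' Fully reproducible under `seed`.
#'
#' @param profiles list of [species_profile()]s.
#' @param n_per_species images per species.
#' @param out_dir output directory (created if missing).
#' @param seed integer RNG seed.
#' @param canvas `(H, W)` canvas size.
#' @param radius_range plate radius range in pixels; default scales with
#'   the canvas (16-33% of its shorter side).
#' @param noise_sd sensor noise level.
#' @param format `"png"` (lossless) or `"jpeg"`.
#' @return the manifest `data.frame` (`path,label,cx,cy,r,seed`), invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(profiles, n_per_species, out_dir, seed = 1L,
                             canvas = c(512L, 512L),
                             radius_range = NULL, noise_sd = 5,
                             format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (is.null(radius_range))
    radius_range <- round(min(canvas) * c(0.16, 0.33))
  stopifnot(length(profiles) >= 1, n_per_species >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  H <- canvas[1]; W <- canvas[2]
  margin <- 10

  draws <- run_with_seed(seed, {
    n_tot <- length(profiles) * n_per_species
    data.frame(
      r = round(runif(n_tot, radius_range[1], radius_range[2])),
      u_cx = runif(n_tot), u_cy = runif(n_tot),
      frac = runif(n_tot, 0.5, 0.85),
      dark = runif(n_tot) < 0.5,
      img_seed = sample.int(.Machine$integer.max - 1L, n_tot)
    )
  })

  rows <- vector("list", nrow(draws))
  i <- 0L
  for (p in profiles) {
    sub <- file.path(out_dir, p$name)
    dir.create(sub, showWarnings = FALSE)
    for (j in seq_len(n_per_species)) {
      i <- i + 1L
      d <- draws[i, ]
      cx <- round(d$r + margin + d$u_cx * (W - 1 - 2 * (d$r + margin)))
      cy <- round(d$r + margin + d$u_cy * (H - 1 - 2 * (d$r + margin)))
      sp <- plate_spec(c(cx, cy), d$r,
                       background = if (d$dark) "dark" else "light",
                       noise_sd = noise_sd)
      ren <- render_plate(p, sp, canvas = canvas, seed = d$img_seed,
                          colony_frac = d$frac)
      fn <- file.path(p$name, sprintf("%s_%03d.%s", p$name, j,
                                      if (format == "png") "png" else "jpg"))
      write_rgb(ren$image, file.path(out_dir, fn))
      rows[[i]] <- data.frame(path = fn, label = p$name, cx = cx, cy = cy,
                              r = d$r, seed = d$img_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
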