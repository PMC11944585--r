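test_that("edge map rejects bad inputs and nulls out constant images", {
  expect_error(compute_edge_map(matrix(0, 10, 10)), "3-channel")
  img <- as_rgb_image(array(128, c(64, 64, 3)))
  expect_error(compute_edge_map(img, blur_kernel = 4), "odd")
  em <- compute_edge_map(img)
  expect_true(all(em == 0))
})

test_that("edge map localises step edges, including single-channel ones", {
  # vertical step edge at column 32 in all channels
  img <- array(50, c(64, 64, 3))
  img[, 33:64, ] <- 200
  em <- compute_edge_map(as_rgb_image(img), blur_kernel = 5, blur_sigma = 1)
  peak_cols <- apply(unclass(em)[16:48, ], 1, which.max)
  expect_true(all(abs(peak_cols - 32.5) <= 1.5))
  expect_true(all(unclass(em)[, c(1:20, 45:64)] < 10))
  expect_true(min(em) >= 0 && max(em) <= 255)

  # edge present only in the red channel
  img2 <- array(100, c(64, 64, 3))
  img2[, 33:64, 1] <- 220
  em2 <- compute_edge_map(as_rgb_image(img2), blur_kernel = 5,
                          blur_sigma = 1)
  expect_gt(max(unclass(em2)[, 30:35]), 200)
  expect_true(all(unclass(em2)[, c(1:20, 45:64)] < 10))
})

test_that("min-max normalization to [0,255] is idempotent", {
  em <- compute_edge_map(demo_plate()$image)
  once <- colonyid:::minmax_normalize(unclass(em))
  expect_equal(colonyid:::minmax_normalize(once), once)
  expect_equal(unclass(em), once)  # compute_edge_map output already normalized
})

test_that("hough parameters are validated", {
  em <- matrix(0, 64, 64)
  expect_error(detect_plates(em, hough_params(dp = 0.5)), "dp")
  expect_error(detect_plates(em, hough_params(min_dist = -1)), "min_dist")
  expect_error(detect_plates(em, hough_params(param2 = 0)), "param")
  expect_error(detect_plates(em, hough_params(min_radius = 50,
                                              max_radius = 10)),
               "min_radius")
})

test_that("blank edge maps yield no detections", {
  out <- detect_plates(matrix(0, 256, 256))
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0)
})

test_that("a rendered plate is recovered within 5 px on either background", {
  for (bg in c("dark", "light")) {
    prof <- make_profile_set(4, seed = 7)[[2]]
    ren <- render_plate(prof, plate_spec(c(150, 160), 80, bg, noise_sd = 5),
                        canvas = c(400L, 400L), seed = 3)
    det <- detect_plates(compute_edge_map(ren$image))
    expect_gt(nrow(det), 0)
    top <- det[1, ]
    expect_lte(abs(top$cx - 150), 5)
    expect_lte(abs(top$cy - 160), 5)
    expect_lte(abs(top$r - 80), 5)
    # all detections respect the radius search bounds
    expect_true(all(det$r >= round(400 / 8) & det$r <= round(400 / 2)))
  }
})

test_that("two plates 300 px apart give exactly two detections at minDist 200", {
  prof <- make_profile_set(4, seed = 7)
  r1 <- render_plate(prof[[1]], plate_spec(c(106, 256), 70, "dark",
                                           noise_sd = 0),
                     canvas = c(512L, 512L), seed = 1, texture = FALSE)
  r2 <- render_plate(prof[[2]], plate_spec(c(406, 256), 70, "dark",
                                           noise_sd = 0),
                     canvas = c(512L, 512L), seed = 2, texture = FALSE)
  img <- unclass(r1$image)
  xs <- matrix(0:511, 512, 512, byrow = TRUE)
  ys <- matrix(0:511, 512, 512)
  mask <- sqrt((xs - 406)^2 + (ys - 256)^2) <= 70
  for (ch in 1:3) {
    a <- img[, , ch]; b <- unclass(r2$image)[, , ch]
    a[mask] <- b[mask]; img[, , ch] <- a
  }
  det <- detect_plates(compute_edge_map(as_rgb_image(img)),
                       hough_params(min_dist = 200, min_radius = 40,
                                    max_radius = 100))
  expect_equal(nrow(det), 2)
  expect_setequal(round(det$cx / 100), c(1, 4))
  # pairwise centre distance respects minDist
  expect_gte(sqrt(diff(det$cx)^2 + diff(det$cy)^2), 200)
})

test_that("detection is translation-equivariant within 2 px", {
  prof <- make_profile_set(4, seed = 7)[[3]]
  base <- c(200, 210)
  ren0 <- render_plate(prof, plate_spec(base, 100, "dark", noise_sd = 3),
                       canvas = c(512L, 512L), seed = 5)
  top0 <- detect_plates(compute_edge_map(ren0$image))[1, ]
  for (shift in list(c(30, 15), c(-40, 25))) {
    ren <- render_plate(prof, plate_spec(base + shift, 100, "dark",
                                         noise_sd = 3),
                        canvas = c(512L, 512L), seed = 5)
    top <- detect_plates(compute_edge_map(ren$image))[1, ]
    expect_lte(abs((top$cx - top0$cx) - shift[1]), 2)
    expect_lte(abs((top$cy - top0$cy) - shift[2]), 2)
  }
})

test_that("best-circle selection follows the score/radius/position rule", {
  expect_null(select_best_circle(NULL, c(100, 100)))
  expect_null(select_best_circle(data.frame(cx = numeric(0), cy = numeric(0),
                                            r = numeric(0),
                                            score = numeric(0)),
                                 c(100, 100)))
  one <- data.frame(cx = 50, cy = 50, r = 20, score = 10)
  expect_equal(select_best_circle(one, c(100, 100)), one)

  # highest score wins even against a larger circle
  two <- data.frame(cx = c(300, 300), cy = c(300, 310), r = c(80, 200),
                    score = c(120, 90))
  expect_equal(select_best_circle(two, c(600, 600))$score, 120)

  # ties: larger radius first, then smaller (cy, cx)
  ties <- data.frame(cx = c(200, 210, 220), cy = c(200, 210, 190),
                     r = c(50, 80, 80), score = c(70, 70, 70))
  best <- select_best_circle(ties, c(600, 600))
  expect_equal(best$r, 80)
  expect_equal(best$cy, 190)

  # circles poking outside the frame are excluded
  edgecase <- data.frame(cx = c(10, 200), cy = c(10, 200), r = c(50, 40),
                         score = c(999, 5))
  expect_equal(select_best_circle(edgecase, c(400, 400))$score, 5)
})

test_that("crop_circle honours target dims, colour and bounds", {
  img <- array(0, c(200, 200, 3))
  img[, , 1] <- 255  # uniform red
  crop <- crop_circle(as_rgb_image(img),
                      data.frame(cx = 100, cy = 100, r = 40),
                      target = c(64L, 64L))
  expect_equal(dim(unclass(crop)), c(64L, 64L, 3L))
  expect_true(all(unclass(crop)[, , 1] == 255))
  expect_true(all(unclass(crop)[, , 2:3] == 0))

  expect_error(crop_circle(as_rgb_image(img),
                           data.frame(cx = 500, cy = 500, r = 40)),
               "outside")

  # crop of a rendered plate reproduces the noise-free colony colours
  prof <- species_profile("t", c(150, 60, 30), c(60, 140, 90), color_sd = 6)
  spn <- plate_spec(c(128, 128), 100, "light", noise_sd = 5)
  noisy <- render_plate(prof, spn, canvas = c(256L, 256L), seed = 4,
                        colony_frac = 0.8)
  clean <- render_plate(prof, plate_spec(c(128, 128), 100, "light",
                                         noise_sd = 0),
                        canvas = c(256L, 256L), seed = 4, colony_frac = 0.8,
                        texture = FALSE)
  circ <- data.frame(cx = 128, cy = 128, r = 40)  # interior of the colony
  m_noisy <- apply(unclass(crop_circle(noisy$image, circ, c(64L, 64L))), 3,
                   mean)
  m_clean <- apply(unclass(crop_circle(clean$image, circ, c(64L, 64L))), 3,
                   mean)
  expect_true(all(abs(m_noisy - m_clean) < 10))
})

test_that("annotation paints green circumference and red centre on a copy", {
  img <- demo_plate()$image
  same <- annotate_detections(img, NULL)
  expect_equal(unclass(same), unclass(img))

  circ <- data.frame(cx = 250, cy = 260, r = 140)
  ann <- annotate_detections(img, circ)
  # original untouched
  expect_false(identical(unclass(ann), unclass(img)))
  # centre dot is pure red
  expect_equal(as.numeric(unclass(ann)[261, 251, ]), c(255, 0, 0))
  # a point on the circumference is pure green
  expect_equal(as.numeric(unclass(ann)[261, 251 + 140, ]), c(0, 255, 0))
})
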