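test_that("Procrustes alignment recovers known similarity transforms", {
  pts <- cbind(c(0, 3, 3, 0, 5, 5), c(0, 0, 2, 2, 1, 4))

  # identity
  tr <- procrustes_align(pts, pts)
  expect_lt(abs(tr$rotation_deg), 1e-9)
  expect_lt(abs(tr$scale - 1), 1e-9)
  expect_lt(max(abs(tr$translation)), 1e-9)
  expect_lt(tr$residual, 1e-18)

  # rotation by +10 deg about the centroid -> recovered rotation -10 deg
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- colMeans(pts)
  rot <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr, `+`)
  tr2 <- procrustes_align(rot, pts)
  expect_lt(abs(tr2$rotation_deg - (-10)), 1e-6)
  expect_lt(abs(tr2$scale - 1), 1e-6)

  # full similarity recovery: rotate 23 deg, scale 1.4, translate (5, -3)
  th <- 23 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(1.4 * pts %*% t(R), 2, c(5, -3), `+`)
  tr3 <- procrustes_align(pts, moved)
  expect_lt(abs(tr3$rotation_deg - 23), 1e-6)
  expect_lt(abs(tr3$scale - 1.4), 1e-6)
  expect_lt(max(abs(tr3$translation - c(5, -3))), 1e-6)
  expect_lt(max(abs(transform_points(pts, tr3) - moved)), 1e-6)
})

test_that("alignment never exceeds the pre-alignment residual and refuses degenerate input", {
  withr::with_seed(4, {
    for (i in 1:5) {
      a <- matrix(runif(12, 0, 100), 6, 2)
      b <- matrix(runif(12, 0, 100), 6, 2)
      tr <- procrustes_align(a, b)
      pre <- sum((a - b)^2)
      expect_lte(tr$residual, pre + 1e-9)
      # no reflection
      expect_gt(det(tr$rotation), 0)
    }
  })
  expect_error(procrustes_align(cbind(1:6, 2 * (1:6)), cbind(1:6, 1:6 * 3)),
               "degenerate")
  expect_error(procrustes_align(matrix(1, 6, 2), matrix(2, 6, 2)),
               "degenerate")
})

test_that("Procrustes solution agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  withr::with_seed(11, {
    a <- matrix(runif(12, 0, 10), 6, 2)
    th <- 0.4
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    b <- sweep(0.8 * a %*% t(R), 2, c(2, 1), `+`) +
      matrix(rnorm(12, 0, 0.05), 6, 2)
  })
  tr <- procrustes_align(a, b)
  vg <- vegan::procrustes(b, a)  # vegan rotates its 2nd argument onto the 1st
  expect_equal(tr$scale, vg$scale, tolerance = 1e-9)
  # vegan reports the rotated configuration about its own centroid
  fitted_mine <- transform_points(a, tr)
  ctr <- function(m) sweep(m, 2, colMeans(m))
  expect_lt(max(abs(ctr(fitted_mine) - ctr(vg$Yrot))), 1e-6)
})

test_that("elliptical masking sets only outside pixels to background", {
  img <- random_image(64, seed = 2)
  # ellipse spanning the whole image: nothing changes
  m <- apply_elliptical_mask(img, c(31.5, 31.5), c(31.9, 31.9))
  inside <- dfmap:::elliptical_mask_indicator(64, 64, c(31.5, 31.5),
                                              c(31.9, 31.9))
  expect_equal(m[inside], img[inside])
  expect_true(all(m[!inside] == 128))

  # all-grey image is unchanged
  g <- matrix(128, 64, 64)
  expect_equal(apply_elliptical_mask(g, c(32, 32), c(20, 25)), g)

  # ellipse must fit inside the image
  expect_error(apply_elliptical_mask(img, c(32, 32), c(40, 10)), "fit")

  # pixel count inside a centred ellipse approximates pi * a * b
  big <- matrix(0, 256, 256)
  n_in <- sum(dfmap:::elliptical_mask_indicator(256, 256, c(127.5, 127.5),
                                                c(100, 125)))
  expect_lt(abs(n_in - pi * 100 * 125) / (pi * 100 * 125), 0.02)
})

test_that("luminance equalisation matches histograms across the set", {
  withr::with_seed(5, {
    a <- matrix(runif(64^2, 50, 200), 64, 64)
    b <- matrix(rbeta(64^2, 2, 5) * 255, 64, 64)
    c2 <- 0.5 * a + 40  # linear remap of a shares its rank order
  })
  eq <- equalize_luminance(list(a, b, c2))

  # within-mask means agree to < 1 grey level
  means <- vapply(eq, mean, numeric(1))
  expect_lt(max(means) - min(means), 1)

  # rank order preserved within each image
  expect_equal(order(eq[[2]]), order(b))

  # images sharing rank order map to the same histogram (here: same image)
  expect_lt(max(abs(eq[[1]] - eq[[3]])), 1e-9)

  # identical inputs are returned unchanged
  same <- equalize_luminance(list(a, a))
  expect_equal(same[[1]], a)
  expect_equal(same[[2]], a)

  expect_error(equalize_luminance(list(a, matrix(7, 64, 64))), "degenerate")
  expect_error(equalize_luminance(list(a)), "length")
})

test_that("stimulus rendering spans 0-255 exactly and deterministically", {
  cfg <- small_config(n_features = 80)
  fs <- decompose_image(random_image(64, seed = 6), cfg)

  withr::with_seed(1, {
    for (k in c(1, 5, 40, 80)) {
      sel <- sample.int(80, k)
      st <- render_stimulus(fs, sel)
      expect_equal(min(st), 0L)
      expect_equal(max(st), 255L)
      # bit-exact idempotence
      expect_identical(unclass(st)[, ], unclass(render_stimulus(fs, sel))[, ])
    }
  })

  # single phase-0 atom: the pre-image is symmetric under 180-degree
  # rotation about the centre, and the linear rescale preserves that
  cfg1 <- tiny_config(image_size = 33, n_features = 1)
  sfv <- sf_levels(cfg1)[2]
  fs1 <- dfmap:::new_features(tibble::tibble(
    feature = 1L, x = 16L, y = 16L, sf = sfv, orientation = 90,
    envelope_sd = envelope_sd(sfv, cfg1), phase = 0, amplitude = 1,
    fit_score = 1), "atom", cfg1)
  st1 <- render_stimulus(fs1, 1L)
  px <- unclass(st1)
  expect_lte(max(abs(px - px[33:1, 33:1])), 1)

  expect_error(render_stimulus(fs, integer(0)), "at least one")
})

test_that("constant reconstructions are rejected with a clear message", {
  cfg <- tiny_config(image_size = 24, n_features = 2)
  fs <- decompose_image(random_image(24, seed = 8), cfg)
  # two copies of the same atom in antiphase cancel exactly
  fs$x <- c(12L, 12L); fs$y <- c(12L, 12L)
  fs$sf <- rep(fs$sf[1], 2); fs$orientation <- rep(fs$orientation[1], 2)
  fs$envelope_sd <- rep(fs$envelope_sd[1], 2)
  fs$phase <- c(0, pi)
  expect_error(render_stimulus(fs, c(1L, 2L)), "rescale error")
})

test_that("image warping by a similarity transform is invertible on interior content", {
  img <- random_image(64, seed = 12)
  th <- 3 * pi / 180
  tr <- structure(list(
    rotation = matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
    rotation_deg = 3, scale = 1.02, translation = c(1.5, -0.8)),
    class = "dfm_transform")
  w <- warp_image(img, tr)
  inv <- procrustes_align(transform_points(cbind(c(10, 50, 30), c(10, 12, 50)), tr),
                          cbind(c(10, 50, 30), c(10, 12, 50)))
  back <- warp_image(w, inv)
  core <- 20:44
  expect_gt(cor(as.vector(back[core, core]), as.vector(img[core, core])), 0.98)
})
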