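make_fdi <- function(values, images, nf) {
  # values: participants x images x features array
  structure(values, images = images, class = "dfm_fdi")
}

fake_features <- function(xy, n, config) {
  tbl <- tibble::tibble(
    feature = seq_len(nrow(xy)),
    x = as.integer(xy[, 1]), y = as.integer(xy[, 2]),
    sf = rep(sf_levels(config)[1], nrow(xy)),
    orientation = rep(orientation_levels(config)[1], nrow(xy)),
    envelope_sd = envelope_sd(sf_levels(config)[1], config),
    phase = 0, amplitude = 1, fit_score = 1
  )
  dfmap:::new_features(tbl, "img", config)
}

test_that("positional projection deposits, smooths and conserves mass", {
  cfg <- dfm_config(image_size = 64, n_features = 3)
  imgs <- tibble::tibble(image_id = "img", category = "child")
  fs <- list(img = fake_features(cbind(c(30, 31, 50), c(30, 30, 12)), 3, cfg))

  # all-zero FDi -> all-zero map
  fdi0 <- make_fdi(array(0, c(1, 1, 3), dimnames = list("p1", "img", NULL)),
                   imgs, 3)
  m0 <- project_positions(fdi0, fs, smoothing_sd = 3)
  expect_equal(m0[["img"]], matrix(0, 64, 64))

  # single unit deposit -> the unit-sum Gaussian kernel centred there
  fdi1 <- make_fdi(array(c(1, 0, 0), c(1, 1, 3),
                         dimnames = list("p1", "img", NULL)), imgs, 3)
  m1 <- project_positions(fdi1, fs, smoothing_sd = 3)[["img"]]
  expect_lt(abs(sum(m1) - 1), 1e-6)
  expect_equal(which.max(m1), 30L * 64L + 31L)

  # arbitrary deposits (with a collision at (30,30)): total mass equals the
  # sum of deposited FDi for interior features
  fdi2 <- make_fdi(array(c(0.7, -0.2, 1.5), c(1, 1, 3),
                         dimnames = list("p1", "img", NULL)), imgs, 3)
  m2 <- project_positions(fdi2, fs, smoothing_sd = 3)[["img"]]
  expect_lt(abs(sum(m2) - 2.0), 1e-6)

  expect_error(project_positions(fdi2, fs, smoothing_sd = 0), "smoothing_sd")
})

test_that("participant averaging precedes projection", {
  cfg <- dfm_config(image_size = 32, n_features = 1)
  imgs <- tibble::tibble(image_id = "img", category = "child")
  fs <- list(img = fake_features(cbind(16, 16), 1, cfg))
  arr <- array(c(1, 3), c(2, 1, 1), dimnames = list(c("p1", "p2"), "img", NULL))
  m <- project_positions(make_fdi(arr, imgs, 1), fs, smoothing_sd = 2)[["img"]]
  expect_lt(abs(sum(m) - 2), 1e-6)  # mean of 1 and 3
})

test_that("band profiles reproduce a hand-computed correlation", {
  cfg <- desk_dictionary(n_features = 6)
  fs <- decompose_image(random_image(64, seed = 13), cfg, "imgA")
  band_of <- match(fs$sf, sf_levels(cfg))
  sels <- list(1:2, 3L, c(1L, 4L), 5:6, 2L, 1L, c(2L, 3L), 4L, 1:3, 6L)
  correct <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  s <- manual_session(rep("imgA", 10), rep("child", 10), correct, sels,
                      n_features = 6)
  prof <- band_profile(list(s), list(imgA = fs), axis = "sf",
                       predictor = "count")
  for (b in unique(band_of)) {
    counts <- vapply(sels, function(x) sum(band_of[x] == b), numeric(1))
    expected <- if (var(counts) == 0) 0 else cor(counts, as.numeric(correct))
    got <- prof$coefficient[prof$band == b]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # proportion predictor divides by the trial's feature count
  prop <- band_profile(list(s), list(imgA = fs), axis = "sf")
  b1 <- unique(band_of)[1]
  pcounts <- vapply(sels, function(x) sum(band_of[x] == b1), numeric(1)) /
    lengths(sels)
  expect_equal(prop$coefficient[prop$band == b1],
               cor(pcounts, as.numeric(correct)), tolerance = 1e-12)
})

test_that("a band-tuned observer produces its maximum coefficient in that band", {
  cfg <- desk_dictionary(n_features = 200)
  fs <- decompose_image(random_image(64, seed = 14), cfg, "imgA")
  target_band <- 3
  in_band <- which(match(fs$sf, sf_levels(cfg)) == target_band)
  expect_gt(length(in_band), 5)
  withr::with_seed(15, {
    nt <- 4000
    sels <- lapply(seq_len(nt), function(i) sample.int(200, 40))
    k <- vapply(sels, function(x) sum(x %in% in_band), numeric(1))
    correct <- runif(nt) < plogis((k - mean(k)) * 1.5)
  })
  s <- manual_session(rep("imgA", nt), rep("child", nt), correct, sels,
                      n_features = 200)
  prof <- band_profile(list(s), list(imgA = fs), axis = "sf")
  expect_equal(which.max(prof$coefficient), target_band)
})

test_that("null responses give near-zero band coefficients", {
  cfg <- desk_dictionary(n_features = 200)
  fs <- decompose_image(random_image(64, seed = 16), cfg, "imgA")
  withr::with_seed(17, {
    nt <- 20000
    sels <- lapply(seq_len(nt), function(i) sample.int(200, sample(20:60, 1)))
    correct <- runif(nt) > 0.25
  })
  s <- manual_session(rep("imgA", nt), rep("child", nt), correct, sels,
                      n_features = 200)
  prof <- band_profile(list(s), list(imgA = fs), axis = "orientation")
  expect_true(all(abs(prof$coefficient) < 0.05))
})

test_that("the pooled-variance t contrast is exact, antisymmetric and degenerate-safe", {
  # printed 6-vs-6 fixture: means 1.0 and 0.0, both sample sd 0.5
  a <- sqrt(5 / 24)
  g1 <- 1 + c(-a, -a, -a, a, a, a)
  g2 <- 0 + c(-a, -a, -a, a, a, a)
  expect_equal(sd(g1), 0.5, tolerance = 1e-12)
  prof <- tibble::tibble(
    image_id = paste0(rep(c("child_", "adult_"), each = 6), 1:6),
    category = rep(c("child", "adult"), each = 6),
    axis = "sf", band = 1L, level = 2.4,
    coefficient = c(g1, g2)
  )
  class(prof) <- c("dfm_band_profiles", class(prof))
  con <- contrast_bands(prof)
  expect_equal(con$t, 3.464, tolerance = 1e-3 / 3.464)
  expect_equal(attr(con, "df"), 10)
  expect_true(con$significant)

  # independent oracle
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(con$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(con$p, tt$p.value, tolerance = 1e-12)

  # swapping group labels negates t exactly
  prof_sw <- prof
  prof_sw$category <- rep(c("adult", "child"), each = 6)
  expect_equal(contrast_bands(prof_sw)$t, -con$t, tolerance = 1e-15)

  # identical groups -> t = 0, p = 1
  prof0 <- prof
  prof0$coefficient <- rep(g1, 2)
  con0 <- contrast_bands(prof0)
  expect_equal(con0$t, 0)
  expect_equal(con0$p, 1)

  # zero pooled variance -> flagged t = 0, p = 1
  profc <- prof
  profc$coefficient <- rep(c(1, 0), each = 6)
  conc <- contrast_bands(profc)
  expect_equal(conc$t, 0)  # degenerate handled, not Inf
  expect_equal(conc$p, 1)
})

test_that("map contrasts follow the positional sign convention", {
  withr::with_seed(18, {
    imgs <- tibble::tibble(
      image_id = paste0(rep(c("child_", "adult_"), each = 4), 1:4),
      category = rep(c("child", "adult"), each = 4))
    maps <- lapply(seq_len(8), function(i) {
      m <- matrix(rnorm(16 * 16, 0, 0.1), 16, 16)
      if (i > 4) m[5, 5] <- m[5, 5] + 3  # adult evidence at one pixel
      m
    })
  })
  names(maps) <- imgs$image_id
  pm <- structure(maps, images = imgs, smoothing_sd = 1,
                  class = "dfm_position_maps")
  con <- contrast_maps(pm)
  expect_equal(con$positive, "adult")
  expect_gt(con$t[5, 5], 3)
  expect_true(con$significant[5, 5])
  expect_equal(con$significant, con$p < con$alpha, ignore_attr = TRUE)
  # pixelwise agreement with t.test at a random location
  v1 <- vapply(maps[5:8], function(m) m[7, 3], numeric(1))
  v2 <- vapply(maps[1:4], function(m) m[7, 3], numeric(1))
  tt <- t.test(v1, v2, var.equal = TRUE)
  expect_equal(con$t[7, 3], unname(tt$statistic), tolerance = 1e-12)
})
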