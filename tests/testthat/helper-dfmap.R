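# Shared fixtures and independent oracles. Everything is generated in
# code at test time; heavyweight objects are cached per test run.

tiny_config <- function(image_size = 32, n_features = 8) {
  dfm_config(image_size = image_size, n_sf = 2, sf_min = 2, sf_max = 6,
             n_orientations = 2, orientation_step = 90,
             n_features = n_features)
}

small_config <- function(image_size = 64, n_features = 300) {
  dfm_config(image_size = image_size, n_sf = 6, sf_min = 2.4, sf_max = 20,
             n_orientations = 4, orientation_step = 45,
             n_features = n_features)
}

# a seeded non-constant asymmetric test image (no ties under scoring)
random_image <- function(n, seed = 7) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(n * n), n, n)
    # smooth a little so low-SF channels see structure
    k <- outer(dnorm(-2:2), dnorm(-2:2)); k <- k / sum(k)
    p <- stats::nextn(n + 4, c(2L, 3L, 5L))
    mp <- matrix(0, p, p); mp[1:n, 1:n] <- base
    kp <- matrix(0, p, p); idx <- ((-2:2) %% p) + 1; kp[idx, idx] <- k
    sm <- Re(stats::fft(stats::fft(mp) * stats::fft(kp), inverse = TRUE)) / p^2
    sm[1:n, 1:n] * 40 + 128
  })
}

# Brute-force decomposition oracle: scores every candidate atom by direct
# pixel-space least squares (zero-padded image, full-kernel Gram, unit
# kernel energy), then applies the same greedy ranked selection with
# per-channel separation. Independent of the FFT implementation path.
brute_force_scores <- function(image, config) {
  image <- image - mean(image)
  n <- config$image_size
  sfs <- sf_levels(config)
  oris <- orientation_levels(config)
  out <- list()
  ch <- 0L
  for (si in seq_along(sfs)) for (oi in seq_along(oris)) {
    ch <- ch + 1L
    sf <- sfs[si]; ori <- oris[oi]
    sd <- envelope_sd(sf, config)
    r <- as.integer(ceiling(4 * sd))
    s <- seq(-r, r)
    dx <- matrix(s, 2 * r + 1, 2 * r + 1, byrow = TRUE)
    dy <- matrix(s, 2 * r + 1, 2 * r + 1)
    th <- ori * pi / 180
    env <- exp(-(dx^2 + dy^2) / (2 * sd^2))
    u <- 2 * pi * sf / n * (dx * cos(th) + dy * sin(th))
    e <- env * cos(u); o <- env * sin(u)
    gee <- sum(e * e); goo <- sum(o * o); geo <- sum(e * o)
    det <- gee * goo - geo^2
    s2 <- sum(env^2)
    for (y in 0:(n - 1)) for (x in 0:(n - 1)) {
      cols <- max(1L, x + 1L - r):min(n, x + 1L + r)
      rows <- max(1L, y + 1L - r):min(n, y + 1L + r)
      kc <- cols - (x + 1L - r) + 1L
      kr <- rows - (y + 1L - r) + 1L
      patch <- image[rows, cols, drop = FALSE]
      pe <- sum(patch * e[kr, kc]); po <- sum(patch * o[kr, kc])
      ae <- (goo * pe - geo * po) / det
      ao <- (gee * po - geo * pe) / det
      out[[length(out) + 1L]] <- c(channel = ch, x = x, y = y, sf = sf,
                                   orientation = ori,
                                   score = sqrt(max(pe * ae + po * ao, 0) / s2))
    }
  }
  as.data.frame(do.call(rbind, out))
}

brute_force_select <- function(scores, config) {
  n <- config$image_size
  # spec tie-break: channel index, then row-major position
  ord <- order(-scores$score, scores$channel, scores$y * n + scores$x,
               method = "radix")
  sep <- config$min_separation_fraction * n / scores$sf
  acc <- list()
  sel <- integer()
  for (i in ord) {
    k <- scores$channel[i]
    if (sep[i] >= 1) {
      a <- acc[[as.character(k)]]
      if (!is.null(a) &&
          any((a[, 1] - scores$x[i])^2 + (a[, 2] - scores$y[i])^2 < sep[i]^2)) {
        next
      }
      acc[[as.character(k)]] <- rbind(a, c(scores$x[i], scores$y[i]))
    }
    sel <- c(sel, i)
    if (length(sel) == config$n_features) break
  }
  scores[sel, ]
}

# small synthetic face set + feature sets + observer, cached per run
.fixture_cache <- new.env(parent = emptyenv())

# desk-scale analogue of the default study: 64-px images and a 6 x 4
# channel dictionary whose SF range respects the Nyquist limit, with the
# same signal layout (low/high SF horizontal+oblique child signal at
# eyes/jaw, mid-SF vertical adult signal at nose/brows)
desk_dictionary <- function(image_size = 64, n_features = 500) {
  dfm_config(image_size = image_size, n_sf = 6, sf_min = 2.4, sf_max = 20,
             n_orientations = 4, orientation_step = 45,
             n_features = n_features)
}

desk_signal <- function() {
  tibble::tribble(
    ~category, ~fx,  ~fy,   ~sf_level, ~orientation, ~sign,
    "child",   0.50, 0.40,  3L,        90,           1,
    "child",   0.50, 0.80,  3L,        90,           1,
    "child",   0.34, 0.44,  6L,        90,           1,
    "child",   0.66, 0.44,  6L,        90,           1,
    "child",   0.40, 0.76,  3L,        45,           1,
    "adult",   0.50, 0.42,  5L,        180,          -1,
    "adult",   0.50, 0.58,  5L,        180,          -1,
    "adult",   0.34, 0.32,  5L,        180,          -1,
    "adult",   0.66, 0.32,  5L,        180,          -1
  )
}

desk_face_spec <- function(seed = 11) {
  synthetic_face_spec(seed = seed, category_signal = desk_signal())
}

small_face_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- desk_dictionary()
    faces <- generate_faces(desk_face_spec(), cfg)
    fsets <- lapply(seq_len(nrow(faces$images)), function(i) {
      decompose_image(faces$images$pixels[[i]], cfg,
                      faces$images$image_id[i])
    })
    names(fsets) <- faces$images$image_id
    observer <- observer_from_truth(fsets, faces)
    .fixture_cache$small <- list(cfg = cfg, faces = faces, fsets = fsets,
                                 observer = observer)
  }
  .fixture_cache$small
}

# hand-built minimal session for estimator fixtures
manual_session <- function(image_id, category, correct, selections,
                           n_features, participant_id = "p1") {
  n <- length(correct)
  log <- tibble::tibble(
    trial = seq_len(n), image_id = image_id, category = category,
    n_presented = lengths(selections),
    response = ifelse(correct, category, ifelse(category == "child",
                                                "adult", "child")),
    correct = correct,
    quest_recommendation = lengths(selections)
  )
  images <- dplyr::distinct(log, image_id, category)
  structure(list(log = log, selections = selections, quest = NULL,
                 threshold = NULL, participant_id = participant_id,
                 n_features = as.integer(n_features), images = images,
                 seed = NA_integer_),
            class = "dfm_session")
}

# cached miniature pipeline run (desk scale)
desk_run <- function() {
  if (is.null(.fixture_cache$desk_run)) {
    .fixture_cache$desk_run <- run_pipeline(
      dfm_run_config(master_seed = 9, n_participants = 4, n_trials = 600,
                     dictionary = desk_dictionary(),
                     face_spec = desk_face_spec()))
  }
  .fixture_cache$desk_run
}

# cached full study-scale run (paper configuration: 250-px dictionary,
# 16 participants x 2400 trials)
cohort_run <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- run_pipeline(dfm_run_config(master_seed = 1))
  }
  .fixture_cache$cohort
}
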