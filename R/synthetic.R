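#' Specification of a synthetic two-category face set
#'
#' The generator emulates a small aligned, masked, luminance-controlled
#' face-image set for a child-vs-adult categorisation experiment, with the
#' crucial difference that the category-diagnostic information is injected
#' at known positions, SF bands and orientation bands, so estimator
#' recovery can be scored against ground truth.
#'
#' All exemplars share the same base structure (an elliptical face region
#' with eye/eyebrow/nose/mouth blobs); a child image adds the child signal
#' atoms, an adult image adds the adult signal atoms, and each exemplar
#' gets its own seeded luminance jitter (and optional pixel noise, see
#' below). Signal atoms are Gabor
#' wavelets drawn from the analysis dictionary itself (positions given as
#' fractions of the image size, SF as a dictionary level index), so the
#' ground truth maps directly onto the feature space of the analysis.
#'
#' The default design places child evidence at low (~5.1 cpi) and high
#' (~49.4 cpi) SF with horizontal (90 deg) and oblique (60/150 deg)
#' orientations in the eye and jaw region, and adult evidence at mid SF
#' (~23 cpi) with vertical (180 deg) orientation along the nasal bone and
#' eyebrows.
#'
#' Exemplar variability has two sources. Each exemplar gets its own
#' luminance gain and offset (`gain_jitter_sd`, `offset_jitter_sd`) — the
#' classic photographic nuisance that luminance equalisation removes in a
#' real stimulus pipeline. Gain/offset jitter changes the images but not
#' the *ranking* of the decomposition's fit scores, so the diagnostic
#' features of same-category exemplars stay in exact feature-index
#' correspondence — the property that makes cross-image FDi averages
#' meaningful. Additive white pixel noise (`exemplar_noise_sd`) is also
#' available but defaults to 0, because it perturbs fit-score ranks and
#' thereby breaks that correspondence.
#'
#' @param seed Integer seed for the exemplar jitter and noise.
#' @param n_per_category Exemplars per category (default 6, i.e. a
#'   12-image set).
#' @param exemplar_noise_sd Additive white pixel noise sd in grey levels
#'   (default 0; see above).
#' @param gain_jitter_sd Sd of the per-exemplar contrast gain around 1.
#' @param offset_jitter_sd Sd of the per-exemplar luminance offset, grey
#'   levels.
#' @param signal_amplitude Peak amplitude of each injected signal atom, in
#'   grey levels. The default is high enough that the injected atoms
#'   dominate the top fit-score ranks of the decomposition.
#' @param category_signal Optional tibble overriding the default signal
#'   design; columns `category`, `fx`, `fy` (centre as fractions of the
#'   image size), `sf_level` (dictionary SF level index), `orientation`
#'   (degrees, must be a dictionary level), `sign` (+1 child, -1 adult).
#' @return A `dfm_face_spec` list.
#' @export
synthetic_face_spec <- function(seed = 1L, n_per_category = 6L,
                                exemplar_noise_sd = 0,
                                gain_jitter_sd = 0.06,
                                offset_jitter_sd = 3,
                                signal_amplitude = 60,
                                category_signal = NULL) {
  if (is.null(category_signal)) category_signal <- default_category_signal()
  stopifnot(all(category_signal$sign %in% c(-1, 1)),
            n_per_category >= 1, exemplar_noise_sd >= 0,
            gain_jitter_sd >= 0, gain_jitter_sd < 0.5, offset_jitter_sd >= 0)
  structure(list(seed = as.integer(seed),
                 n_per_category = as.integer(n_per_category),
                 exemplar_noise_sd = exemplar_noise_sd,
                 gain_jitter_sd = gain_jitter_sd,
                 offset_jitter_sd = offset_jitter_sd,
                 signal_amplitude = signal_amplitude,
                 category_signal = category_signal),
            class = "dfm_face_spec")
}

default_category_signal <- function() {
  tibble::tribble(
    ~category, ~fx,   ~fy,   ~sf_level, ~orientation, ~sign,
    "child",   0.50,  0.40,  5L,        90,           1,   # eye band, low SF
    "child",   0.34,  0.416, 17L,       90,           1,   # left eye, high SF
    "child",   0.66,  0.416, 17L,       90,           1,   # right eye, high SF
    "child",   0.42,  0.74,  17L,       90,           1,   # mouth corner, high SF
    "child",   0.58,  0.74,  17L,       90,           1,   # mouth corner, high SF
    "child",   0.36,  0.77,  5L,        60,           1,   # jaw oblique
    "child",   0.64,  0.77,  5L,        150,          1,   # jaw oblique
    "adult",   0.50,  0.33,  13L,       180,          -1,  # glabella, mid SF
    "adult",   0.50,  0.45,  13L,       180,          -1,  # nasal bone, mid SF
    "adult",   0.50,  0.57,  13L,       180,          -1,
    "adult",   0.34,  0.32,  13L,       180,          -1,  # left eyebrow
    "adult",   0.66,  0.32,  13L,       180,          -1   # right eyebrow
  )
}

# shared base face: soft-edged ellipse + feature blobs + a fixed texture
# field, parameterised by image size. The smooth rim avoids concentrating
# dictionary energy on a single artificial boundary; the texture (part of
# the shared base structure, identical in every exemplar) plays the role
# of skin texture and shading in photographs — it populates every
# SF/orientation channel with genuine structure, so the 2200 selected
# features have a balanced band composition instead of being dominated by
# the periodic side-responses of the few injected signal atoms.
base_face <- function(n) {
  xs <- seq_len(n) - 1
  gx <- matrix(xs, n, n, byrow = TRUE)
  gy <- matrix(xs, n, n)
  rho <- sqrt(((gx - 0.5 * n) / (0.36 * n))^2 +
                ((gy - 0.53 * n) / (0.45 * n))^2)
  img <- 128 + 35 * stats::plogis((1 - rho) / 0.05)
  withr::with_seed(874511, {
    img <- img + matrix(stats::rnorm(n * n, 0, 6), n, n)
  })
  blob <- function(img, fx, fy, sx, sy, amp) {
    xs <- seq_len(n) - 1
    gx <- matrix(xs - fx * n, n, n, byrow = TRUE)
    gy <- matrix(xs - fy * n, n, n)
    img + amp * exp(-(gx^2 / (2 * (sx * n)^2) + gy^2 / (2 * (sy * n)^2)))
  }
  img <- blob(img, 0.34, 0.40, 0.032, 0.032, -55)  # eyes
  img <- blob(img, 0.66, 0.40, 0.032, 0.032, -55)
  img <- blob(img, 0.34, 0.32, 0.050, 0.016, -35)  # eyebrows
  img <- blob(img, 0.66, 0.32, 0.050, 0.016, -35)
  img <- blob(img, 0.50, 0.54, 0.020, 0.060, -25)  # nose
  img <- blob(img, 0.50, 0.72, 0.072, 0.024, -40)  # mouth
  img
}

base_landmarks <- function(n) {
  pt <- function(group, fx, fy) {
    tibble::tibble(group = group, x = fx * n, y = fy * n)
  }
  dplyr::bind_rows(
    pt("left_eye", c(0.30, 0.34, 0.38, 0.34), c(0.40, 0.375, 0.40, 0.425)),
    pt("right_eye", c(0.62, 0.66, 0.70, 0.66), c(0.40, 0.375, 0.40, 0.425)),
    pt("left_eyebrow", c(0.29, 0.34, 0.39), c(0.325, 0.305, 0.325)),
    pt("right_eyebrow", c(0.61, 0.66, 0.71), c(0.325, 0.305, 0.325)),
    pt("nose", c(0.46, 0.50, 0.54), c(0.565, 0.53, 0.565)),
    pt("mouth", c(0.428, 0.50, 0.572), c(0.72, 0.735, 0.72))
  ) |>
    dplyr::mutate(point = dplyr::row_number(), .before = 1)
}

#' Generate a synthetic face set with known diagnostic structure
#'
#' @param spec A [synthetic_face_spec()].
#' @param config The [dfm_config()] the set is generated for; signal atoms
#'   are resolved against its SF and orientation levels.
#' @return A `dfm_face_set` list with elements
#'   \describe{
#'     \item{images}{tibble with columns `image_id`, `category`, `pixels`
#'       (list-column of matrices).}
#'     \item{landmarks}{tibble of 20 points per image (`image_id`, `point`,
#'       `group`, `x`, `y`).}
#'     \item{truth}{tibble of resolved signal atoms: `category`, `x`, `y`,
#'       `sf_level`, `sf`, `orientation`, `envelope_sd`, `sign`,
#'       `amplitude`.}
#'     \item{spec, config}{the inputs.}
#'   }
#' @export
generate_faces <- function(spec, config = dfm_config()) {
  n <- config$image_size
  sfs <- sf_levels(config)
  oris <- orientation_levels(config)
  cs <- spec$category_signal
  if (any(cs$sf_level < 1 | cs$sf_level > config$n_sf)) {
    stop("invalid spec: signal atom SF level outside the dictionary",
         call. = FALSE)
  }
  if (!all(cs$orientation %in% oris)) {
    stop("invalid spec: signal atom orientation is not a dictionary level",
         call. = FALSE)
  }
  truth <- cs |>
    dplyr::mutate(
      x = as.integer(round(.data$fx * n)),
      y = as.integer(round(.data$fy * n)),
      sf = sfs[.data$sf_level],
      envelope_sd = envelope_sd(.data$sf, config),
      amplitude = spec$signal_amplitude
    ) |>
    dplyr::select("category", "x", "y", "sf_level", "sf", "orientation",
                  "envelope_sd", "sign", "amplitude")
  inside <- elliptical_mask_indicator(n, n, c(0.5 * n, 0.53 * n),
                                      c(0.36 * n, 0.45 * n))
  if (!all(inside[cbind(truth$y + 1L, truth$x + 1L)])) {
    stop("invalid spec: signal atom centre outside the face region",
         call. = FALSE)
  }

  base <- base_face(n)
  signal_img <- function(cat) {
    tr <- dplyr::filter(truth, .data$category == cat)
    img <- matrix(0, n, n)
    for (i in seq_len(nrow(tr))) {
      img <- img + render_gabor(tr$x[i], tr$y[i], tr$sf[i], tr$orientation[i],
                                tr$envelope_sd[i], phase = 0,
                                amplitude = tr$amplitude[i], image_size = n)
    }
    img
  }
  sig <- list(child = signal_img("child"), adult = signal_img("adult"))

  withr::local_seed(spec$seed)
  rows <- list()
  lms <- list()
  lm0 <- base_landmarks(n)
  for (cat in c("child", "adult")) {
    for (k in seq_len(spec$n_per_category)) {
      id <- paste0(cat, "_", k)
      gain <- stats::rnorm(1, 1, spec$gain_jitter_sd)
      offset <- stats::rnorm(1, 0, spec$offset_jitter_sd)
      noise <- if (spec$exemplar_noise_sd > 0) {
        matrix(stats::rnorm(n * n, 0, spec$exemplar_noise_sd), n, n)
      } else 0
      px <- 128 + gain * (base + sig[[cat]] - 128) + offset + noise
      px <- pmin(pmax(px, 0), 255)
      rows[[id]] <- tibble::tibble(image_id = id, category = cat,
                                   pixels = list(px))
      lms[[id]] <- dplyr::mutate(lm0, image_id = id, .before = 1)
    }
  }
  structure(list(images = dplyr::bind_rows(rows),
                 landmarks = dplyr::bind_rows(lms),
                 truth = truth, spec = spec, config = config),
            class = "dfm_face_set")
}

#' @export
print.dfm_face_set <- function(x, ...) {
  cat("<dfm_face_set> ", nrow(x$images), " images (",
      x$spec$n_per_category, " per category), ",
      x$config$image_size, " px, ", nrow(x$truth),
      " ground-truth signal atoms\n", sep = "")
  invisible(x)
}

#' Match ground-truth signal atoms to decomposed features
#'
#' For each injected signal atom of the image's category, finds the nearest
#' decomposed feature in the same SF/orientation channel within half the
#' channel's minimum selection separation (at least 2 px) — inside the
#' atom's envelope, and unambiguous because selected same-channel atoms
#' are at least the full separation apart. Features matched to at least
#' one signal atom are that image's diagnostic features.
#'
#' @param features A `dfm_features` decomposition of one synthetic image.
#' @param truth The `truth` tibble of the face set.
#' @param category Category of the image (`"child"` or `"adult"`).
#' @return Sorted integer vector of diagnostic feature indices. Attribute
#'   `matched` maps each signal atom to its feature (NA if unmatched).
#' @export
diagnostic_indicator <- function(features, truth, category) {
  tr <- dplyr::filter(truth, .data$category == !!category)
  n <- attr(features, "config")$image_size
  matched <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    cfgm <- attr(features, "config")
    radius <- max(2, 0.5 * cfgm$min_separation_fraction * n / tr$sf[i])
    cand <- which(features$sf == tr$sf[i] &
                    features$orientation == tr$orientation[i])
    if (!length(cand)) { matched[i] <- NA_integer_; next }
    d2 <- (features$x[cand] - tr$x[i])^2 + (features$y[cand] - tr$y[i])^2
    j <- which.min(d2)
    matched[i] <- if (d2[j] <= radius^2) cand[j] else NA_integer_
  }
  structure(sort(unique(matched[!is.na(matched)])), matched = matched)
}
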