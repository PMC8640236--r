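#' Landmark group means
#'
#' Reduces a 20-point landmark set to the six mean coordinates used for
#' alignment (left eye, right eye, left eyebrow, right eyebrow, nose,
#' mouth). Landmarks are a tibble with columns `point`, `x`, `y`, `group`;
#' the generator's grouping is 4 points per eye and 3 each for the
#' eyebrows, nose and mouth.
#'
#' @param landmarks Tibble with columns `x`, `y`, `group`.
#' @return Tibble with columns `group`, `x`, `y` (one row per group, in a
#'   fixed group order).
#' @export
landmark_means <- function(landmarks) {
  groups <- c("left_eye", "right_eye", "left_eyebrow", "right_eyebrow",
              "nose", "mouth")
  out <- landmarks |>
    dplyr::mutate(group = factor(.data$group, levels = groups)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$group)
  out
}

#' Similarity Procrustes alignment of landmark means
#'
#' Finds the similarity transform (rotation, scale, translation; no
#' reflection) minimizing the sum of squared distances from the transformed
#' source points to the reference points. Both landmark sets are reduced to
#' their six group means before fitting.
#'
#' @param source,reference Landmark tibbles (columns `x`, `y`, `group`) or
#'   k x 2 coordinate matrices already reduced to means.
#' @return A `dfm_transform` list: `rotation` (2 x 2 matrix),
#'   `rotation_deg`, `scale`, `translation` (length 2), `residual`
#'   (post-alignment sum of squares).
#' @examples
#' pts <- cbind(c(0, 1, 1, 0, 2, 2), c(0, 0, 1, 1, 0, 2))
#' tr <- procrustes_align(pts, pts)
#' tr$scale  # 1
#' @export
procrustes_align <- function(source, reference) {
  X <- as_coord_matrix(source)
  Y <- as_coord_matrix(reference)
  stopifnot(nrow(X) == nrow(Y))
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] < 1e-10) {
    stop("alignment error: degenerate (collinear or coincident) landmark means",
         call. = FALSE)
  }
  # rotation only: flip the smallest singular direction if a reflection
  # would otherwise be optimal
  d <- c(1, sign(det(sv$u %*% t(sv$v))))
  R <- sv$v %*% diag(d) %*% t(sv$u)
  s <- sum(sv$d * d) / sum(Xc^2)
  tr <- cy - s * as.vector(R %*% cx)
  fitted <- sweep(s * X %*% t(R), 2, tr, `+`)
  structure(list(
    rotation = R,
    rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
    scale = s,
    translation = tr,
    residual = sum((fitted - Y)^2)
  ), class = "dfm_transform")
}

as_coord_matrix <- function(p) {
  if (is.matrix(p)) return(p)
  m <- landmark_means(p)
  cbind(m$x, m$y)
}

#' Apply a similarity transform to points
#'
#' @param points n x 2 matrix (x, y).
#' @param transform A `dfm_transform` from [procrustes_align()].
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  sweep(transform$scale * points %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' Warp an image by a similarity transform
#'
#' Inverse-maps each output pixel through the transform and samples the
#' source bilinearly; pixels mapping outside the source get the background
#' grey value.
#'
#' @param image Numeric matrix.
#' @param transform A `dfm_transform`; the output is the image as seen
#'   after moving source content by `transform`.
#' @param background Fill value for out-of-bounds samples (mid-grey 128).
#' @return Numeric matrix, same size as `image`.
#' @export
warp_image <- function(image, transform, background = 128) {
  n <- nrow(image); m <- ncol(image)
  xs <- seq_len(m) - 1; ys <- seq_len(n) - 1
  gx <- matrix(xs, n, m, byrow = TRUE)
  gy <- matrix(ys, n, m)
  # inverse transform: p_src = R^-1 (p_out - t) / s
  Ri <- t(transform$rotation)
  px <- (gx - transform$translation[1]) / transform$scale
  py <- (gy - transform$translation[2]) / transform$scale
  sx <- Ri[1, 1] * px + Ri[1, 2] * py
  sy <- Ri[2, 1] * px + Ri[2, 2] * py
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(yy, xx) {
    ok <- xx >= 0 & xx <= m - 1 & yy >= 0 & yy <= n - 1
    v <- matrix(background, n, m)
    v[ok] <- image[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  (1 - fy) * ((1 - fx) * val(y0, x0) + fx * val(y0, x0 + 1)) +
    fy * ((1 - fx) * val(y0 + 1, x0) + fx * val(y0 + 1, x0 + 1))
}

#' Mask an image through an ellipse
#'
#' Pixels outside the ellipse are set to the background grey value; pixels
#' inside are unchanged.
#'
#' @param image Numeric matrix.
#' @param center Ellipse centre `(x, y)`, 0-based pixels.
#' @param semi_axes Semi-axes `(a, b)` along x and y, pixels.
#' @param background Outside fill value (mid-grey 128).
#' @return Masked image.
#' @export
apply_elliptical_mask <- function(image, center, semi_axes, background = 128) {
  n <- nrow(image); m <- ncol(image)
  if (center[1] - semi_axes[1] < -0.5 || center[1] + semi_axes[1] > m - 0.5 ||
      center[2] - semi_axes[2] < -0.5 || center[2] + semi_axes[2] > n - 0.5) {
    stop("ellipse does not fit inside the image", call. = FALSE)
  }
  out <- elliptical_mask_indicator(n, m, center, semi_axes)
  image[!out] <- background
  image
}

elliptical_mask_indicator <- function(n, m, center, semi_axes) {
  xs <- seq_len(m) - 1; ys <- seq_len(n) - 1
  gx <- matrix(xs, n, m, byrow = TRUE)
  gy <- matrix(ys, n, m)
  ((gx - center[1]) / semi_axes[1])^2 + ((gy - center[2]) / semi_axes[2])^2 <= 1
}

#' Equalise the luminance profile of an image set
#'
#' Histogram-matches each image to the average histogram of the set
#' (SHINE-style): within the mask, the k-th brightest pixel of every image
#' is remapped to the mean of the k-th brightest pixels across images.
#' Rank order within each image is preserved (ties broken by pixel order,
#' deterministically).
#'
#' @param images List of >= 2 numeric matrices of identical size.
#' @param mask Optional logical matrix; only `TRUE` pixels are equalised,
#'   others are left untouched. Default: all pixels.
#' @return List of equalised images.
#' @export
equalize_luminance <- function(images, mask = NULL) {
  stopifnot(is.list(images), length(images) >= 2)
  dims <- dim(images[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  idx <- which(mask)
  vals <- lapply(images, function(im) {
    stopifnot(all(dim(im) == dims))
    v <- im[idx]
    if (stats::var(v) == 0) {
      stop("degenerate input: constant image cannot be equalised", call. = FALSE)
    }
    v
  })
  target <- Reduce(`+`, lapply(vals, sort)) / length(vals)
  purrr::map2(images, vals, function(im, v) {
    rk <- rank(v, ties.method = "first")
    im[idx] <- target[rk]
    im
  })
}

#' Render a stimulus from a feature selection
#'
#' Reconstructs the selected atoms at equal amplitude ([reconstruct()]) and
#' maps the result linearly so every stimulus covers the full 0-255 range
#' (minimum to 0, maximum to 255), quantised to 8 bit
#' (round-half-away-from-zero).
#'
#' @inheritParams reconstruct
#' @return A `dfm_stimulus` object: integer matrix in 0..255 with
#'   attributes `image_id` and `selected` (integer feature indices).
#' @export
render_stimulus <- function(features, selected) {
  idx <- selection_indices(selected, nrow(features))
  if (length(idx) == 0) {
    stop("at least one feature must be selected", call. = FALSE)
  }
  img <- reconstruct(features, idx)
  rng <- range(img)
  if (rng[2] - rng[1] <= 1e-9 * max(1, abs(rng[1]), abs(rng[2]))) {
    stop("rescale error: reconstruction is constant, cannot span 0-255",
         call. = FALSE)
  }
  scaled <- (img - rng[1]) / (rng[2] - rng[1]) * 255
  px <- matrix(as.integer(floor(scaled + 0.5)), nrow(img), ncol(img))
  structure(px, image_id = attr(features, "image_id"), selected = idx,
            class = c("dfm_stimulus", "matrix", "array"))
}

#' @export
print.dfm_stimulus <- function(x, ...) {
  cat("<dfm_stimulus> image '", attr(x, "image_id"), "', ",
      length(attr(x, "selected")), " features, ",
      nrow(x), "x", ncol(x), " px [", min(x), "-", max(x), "]\n", sep = "")
  invisible(x)
}
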