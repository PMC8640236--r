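#' Positional diagnosticity maps
#'
#' Reprojects each feature's participant-averaged FDi to its x-y centre
#' (summing collisions) and smooths the deposit map with a 2-d Gaussian
#' kernel (truncated at 4 sd, renormalised to unit sum, zero-padded
#' borders). Smoothing therefore conserves the deposited mass away from
#' the borders.
#'
#' @param fdi A `dfm_fdi` from [compute_fdi()].
#' @param feature_sets Named list of `dfm_features` aligned with the FDi
#'   image axis.
#' @param smoothing_sd Gaussian kernel sd in pixels (default 10).
#' @return A `dfm_position_maps` object: named list of numeric matrices
#'   (one per image) with attributes `images` and `smoothing_sd`.
#' @export
project_positions <- function(fdi, feature_sets, smoothing_sd = 10) {
  if (smoothing_sd <= 0) stop("smoothing_sd must be > 0", call. = FALSE)
  images <- attr(fdi, "images")
  favg <- fdi_participant_mean(fdi)
  maps <- purrr::map(seq_len(nrow(images)), function(i) {
    fs <- feature_sets[[images$image_id[i]]]
    n <- attr(fs, "config")$image_size
    dep <- matrix(0, n, n)
    pos <- fs$x * n + fs$y + 1L  # column-major linear index
    sums <- rowsum(favg[i, ], pos)
    dep[as.integer(rownames(sums))] <- sums
    gaussian_smooth(dep, smoothing_sd)
  })
  names(maps) <- images$image_id
  structure(maps, images = images, smoothing_sd = smoothing_sd,
            class = "dfm_position_maps")
}

#' @export
print.dfm_position_maps <- function(x, ...) {
  cat("<dfm_position_maps> ", length(x), " maps, ",
      nrow(x[[1]]), "x", ncol(x[[1]]), " px, smoothing sd ",
      attr(x, "smoothing_sd"), " px\n", sep = "")
  invisible(x)
}

# 2-d Gaussian smoothing, kernel truncated at 4 sd and renormalised to
# unit sum; zero-padded (linear, not circular) convolution via FFT
gaussian_smooth <- function(m, sd) {
  n <- nrow(m)
  r <- as.integer(ceiling(4 * sd))
  g <- stats::dnorm(seq(-r, r), 0, sd)
  k <- outer(g, g)
  k <- k / sum(k)
  p <- stats::nextn(n + 2L * r, c(2L, 3L, 5L))
  mp <- matrix(0, p, p); mp[seq_len(n), seq_len(n)] <- m
  kp <- matrix(0, p, p)
  idx <- (seq(-r, r) %% p) + 1L
  kp[idx, idx] <- k
  out <- Re(stats::fft(stats::fft(mp) * stats::fft(kp), inverse = TRUE)) / (p * p)
  out[seq_len(n), seq_len(n)]
}

#' SF and orientation band profiles
#'
#' For each image and each band (the 20 dictionary SF levels or the 12
#' orientation levels), correlates the per-trial sampling of the band with
#' trial correctness, pooling trials of that image across all
#' participants. The default predictor is the *proportion* of the trial's
#' presented features that fall in the band: under staircase control the
#' total feature count varies across trials and itself correlates with
#' accuracy, so raw counts load every populated band with that shared
#' intensity effect, whereas proportions isolate the band's composition.
#' The raw count predictor is available via `predictor = "count"`. A band
#' whose predictor has zero variance gets a 0 coefficient.
#'
#' @param sessions A `dfm_session` or list of them.
#' @param feature_sets Named list of `dfm_features`.
#' @param axis `"sf"` or `"orientation"`.
#' @param predictor `"proportion"` (default) or `"count"`.
#' @return A tibble (class `dfm_band_profiles`) with columns `image_id`,
#'   `category`, `axis`, `band`, `level`, `coefficient`.
#' @export
band_profile <- function(sessions, feature_sets, axis = c("sf", "orientation"),
                         predictor = c("proportion", "count")) {
  axis <- match.arg(axis)
  predictor <- match.arg(predictor)
  if (inherits(sessions, "dfm_session")) sessions <- list(sessions)
  images <- sessions[[1]]$images
  cfg <- attr(feature_sets[[1]], "config")
  levels <- if (axis == "sf") sf_levels(cfg) else orientation_levels(cfg)
  nb <- length(levels)

  # per-image predictor columns pooled over participants
  out <- purrr::map(seq_len(nrow(images)), function(i) {
    id <- images$image_id[i]
    fs <- feature_sets[[id]]
    band_of <- match(if (axis == "sf") fs$sf else fs$orientation, levels)
    bmat <- Matrix::sparseMatrix(i = seq_len(nrow(fs)), j = band_of, x = 1,
                                 dims = c(nrow(fs), nb))
    counts <- NULL
    correct <- NULL
    for (s in sessions) {
      tr <- which(s$log$image_id == id)
      if (!length(tr)) next
      cm <- as.matrix(selection_matrix(s)[tr, , drop = FALSE] %*% bmat)
      if (predictor == "proportion") cm <- cm / pmax(s$log$n_presented[tr], 1)
      counts <- rbind(counts, cm)
      correct <- c(correct, s$log$correct[tr])
    }
    coef <- vapply(seq_len(nb), function(b) {
      x <- counts[, b]
      if (length(x) < 2 || stats::var(x) == 0 || stats::var(correct) == 0) {
        return(0)
      }
      stats::cor(x, as.numeric(correct))
    }, numeric(1))
    tibble::tibble(image_id = id, category = images$category[i],
                   axis = axis, band = seq_len(nb), level = levels,
                   coefficient = coef)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("dfm_band_profiles", class(out))
  out
}

# vectorized two-sample pooled-variance t; x1, x2 are n x L matrices
# (rows = group members). Zero pooled variance -> t = 0, p = 1.
pooled_t <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = unname(t), p = unname(p), df = df, degenerate = unname(se == 0))
}

#' Child-vs-adult contrast of positional maps
#'
#' Unpaired two-sample t-test (pooled variance) at every pixel between
#' the per-image child and adult maps. The sign convention follows the
#' positional-map display: positive t = adult evidence.
#'
#' @param maps A `dfm_position_maps` from [project_positions()].
#' @param alpha Significance level (uncorrected).
#' @return A `dfm_contrast` object: list with `t`, `p`, `significant`
#'   matrices, `df`, `alpha`, `positive` (which category positive t values
#'   indicate) and `degenerate` (zero-variance pixels, flagged t = 0,
#'   p = 1).
#' @export
contrast_maps <- function(maps, alpha = 0.05) {
  images <- attr(maps, "images")
  stack <- function(cat) {
    do.call(rbind, lapply(which(images$category == cat),
                          function(i) as.vector(maps[[i]])))
  }
  child <- stack("child"); adult <- stack("adult")
  res <- pooled_t(adult, child)  # positive = adult evidence
  n <- nrow(maps[[1]])
  shape <- function(v) matrix(v, n, n)
  structure(list(t = shape(res$t), p = shape(res$p),
                 significant = shape(res$p < alpha), df = res$df,
                 alpha = alpha, positive = "adult",
                 degenerate = shape(res$degenerate)),
            class = "dfm_contrast")
}

#' Child-vs-adult contrast of band profiles
#'
#' Unpaired pooled-variance t-test per band between the per-image child
#' and adult coefficients. Sign convention follows the SF/orientation
#' displays: positive t = child evidence.
#'
#' @param profiles A `dfm_band_profiles` from [band_profile()].
#' @param alpha Significance level (uncorrected).
#' @return A tibble (class `dfm_band_contrast`) with columns `axis`,
#'   `band`, `level`, `t`, `p`, `significant`; attributes `df`, `alpha`,
#'   `positive = "child"`.
#' @export
contrast_bands <- function(profiles, alpha = 0.05) {
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = c("image_id", "category"),
                       names_from = "band", values_from = "coefficient")
  mat <- as.matrix(wide[, -(1:2)])
  res <- pooled_t(mat[wide$category == "child", , drop = FALSE],
                  mat[wide$category == "adult", , drop = FALSE])
  meta <- dplyr::distinct(profiles, .data$axis, .data$band, .data$level)
  out <- tibble::tibble(axis = meta$axis, band = meta$band,
                        level = meta$level, t = res$t, p = res$p,
                        significant = res$p < alpha)
  structure(out, df = res$df, alpha = alpha, positive = "child",
            class = c("dfm_band_contrast", class(out)))
}

#' @export
print.dfm_contrast <- function(x, ...) {
  cat("<dfm_contrast> ", nrow(x$t), "x", ncol(x$t), " px, df = ", x$df,
      ", ", sum(x$significant), " significant pixels at alpha = ", x$alpha,
      " (positive t = ", x$positive, " evidence)\n", sep = "")
  invisible(x)
}

#' @export
tidy.dfm_contrast <- function(x, ...) {
  n <- nrow(x$t)
  tibble::tibble(
    x = rep(seq_len(ncol(x$t)) - 1L, each = n),
    y = rep(seq_len(n) - 1L, times = ncol(x$t)),
    t = as.vector(x$t), p = as.vector(x$p),
    significant = as.vector(x$significant)
  )
}

#' @export
glance.dfm_contrast <- function(x, ...) {
  tibble::tibble(df = x$df, alpha = x$alpha, positive = x$positive,
                 n_significant = sum(x$significant),
                 frac_significant = mean(x$p < x$alpha))
}
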