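#' Score pipeline recovery against synthetic ground truth
#'
#' Compares the end-to-end analysis output with the known diagnostic
#' structure injected by the generator:
#'
#' * positions — the fraction of significant contrast pixels that fall
#'   inside the true signal regions (union of 3-sd disks around the
#'   injected atoms);
#' * SF — the rank of each injected child SF band in the child-signed
#'   band contrast, and the sign at the injected child/adult bands;
#' * orientation — likewise over the 12 orientation bands; the primary
#'   child band is the injected orientation carrying the most child atoms;
#' * template — the Pearson correlation between the participant- and
#'   image-averaged FDi vector and the image-averaged ground-truth
#'   absolute-weight vector of the observer.
#'
#' @param face_set The `dfm_face_set` the pipeline ran on.
#' @param observer The `dfm_observer` used (for the ground-truth weights).
#' @param fdi The `dfm_fdi` tensor.
#' @param position_contrast A `dfm_contrast` from [contrast_maps()].
#' @param sf_contrast,orientation_contrast `dfm_band_contrast` objects.
#' @return A `dfm_recovery` list; see the printed summary for fields.
#' @export
recover_ground_truth <- function(face_set, observer, fdi,
                                 position_contrast, sf_contrast,
                                 orientation_contrast) {
  truth <- face_set$truth
  n <- nrow(position_contrast$t)

  # --- positions ---------------------------------------------------------
  region <- matrix(FALSE, n, n)
  xs <- seq_len(n) - 1
  for (i in seq_len(nrow(truth))) {
    r2 <- (3 * truth$envelope_sd[i])^2
    dx <- matrix(xs - truth$x[i], n, n, byrow = TRUE)
    dy <- matrix(xs - truth$y[i], n, n)
    region <- region | (dx^2 + dy^2 <= r2)
  }
  sig <- position_contrast$significant & !position_contrast$degenerate
  frac_sig_pixels <- mean(position_contrast$p < position_contrast$alpha)
  frac_in_truth <- if (any(sig)) mean(region[sig]) else NA_real_

  # --- bands -------------------------------------------------------------
  band_report <- function(con, child_bands, adult_bands) {
    rk <- unname(rank(-con$t, ties.method = "first"))
    list(child_levels = con$level[child_bands],
         child_ranks = rk[child_bands],
         child_sign_ok = all(con$t[child_bands] > 0),
         adult_sign_ok = all(con$t[adult_bands] < 0),
         frac_significant = mean(con$p < attr(con, "alpha")))
  }
  sfr <- band_report(sf_contrast,
                     sort(unique(truth$sf_level[truth$sign > 0])),
                     sort(unique(truth$sf_level[truth$sign < 0])))
  # orientation: primary child band = injected orientation with most atoms
  orir <- band_report(
    orientation_contrast,
    match(sort(unique(truth$orientation[truth$sign > 0])),
          orientation_contrast$level),
    match(sort(unique(truth$orientation[truth$sign < 0])),
          orientation_contrast$level))
  child_ori <- truth$orientation[truth$sign > 0]
  primary_ori <- as.numeric(names(sort(table(child_ori), decreasing = TRUE))[1])
  primary_band <- match(primary_ori, orientation_contrast$level)
  primary_rank <- unname(rank(-orientation_contrast$t,
                              ties.method = "first")[primary_band])

  # --- template ----------------------------------------------------------
  nf <- dim(fdi)[3]
  images <- attr(fdi, "images")
  template <- rep(0, nf)
  for (id in images$image_id) {
    w <- observer$weights[[id]]
    if (!is.null(w) && nrow(w)) {
      template[w$feature] <- template[w$feature] + abs(w$weight)
    }
  }
  template <- template / nrow(images)
  fdi_mean <- colMeans(fdi_participant_mean(fdi))
  template_correlation <-
    if (stats::sd(template) > 0 && stats::sd(fdi_mean) > 0) {
      stats::cor(fdi_mean, template)
    } else NA_real_

  structure(list(
    sf_n_bands = nrow(sf_contrast),
    orientation_n_bands = nrow(orientation_contrast),
    frac_sig_pixels = frac_sig_pixels,
    frac_sig_pixels_in_truth = frac_in_truth,
    truth_region_area = mean(region),
    sf = sfr,
    orientation = orir,
    orientation_primary_level = primary_ori,
    orientation_primary_rank = primary_rank,
    template_correlation = template_correlation
  ), class = "dfm_recovery")
}

#' @export
print.dfm_recovery <- function(x, ...) {
  cat("<dfm_recovery>\n",
      "  significant pixels: ", round(100 * x$frac_sig_pixels, 1), "% (",
      round(100 * x$frac_sig_pixels_in_truth, 1),
      "% of them inside true signal regions)\n",
      "  child SF bands ", paste(signif(x$sf$child_levels, 3), collapse = ", "),
      " cpi -> ranks ", paste(x$sf$child_ranks, collapse = ", "),
      " of ", x$sf_n_bands,
      " (signs ok: ", x$sf$child_sign_ok && x$sf$adult_sign_ok, ")\n",
      "  primary child orientation ", x$orientation_primary_level,
      " deg -> rank ", x$orientation_primary_rank, " of ",
      x$orientation_n_bands, " (signs ok: ",
      x$orientation$child_sign_ok && x$orientation$adult_sign_ok, ")\n",
      "  FDi template correlation: ", round(x$template_correlation, 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.dfm_recovery <- function(x, ...) {
  tibble::tibble(
    frac_sig_pixels = x$frac_sig_pixels,
    frac_sig_pixels_in_truth = x$frac_sig_pixels_in_truth,
    sf_best_child_rank = min(x$sf$child_ranks),
    sf_worst_child_rank = max(x$sf$child_ranks),
    orientation_primary_rank = x$orientation_primary_rank,
    signs_ok = x$sf$child_sign_ok && x$sf$adult_sign_ok &&
      x$orientation$child_sign_ok && x$orientation$adult_sign_ok,
    template_correlation = x$template_correlation
  )
}

#' Empirical significance fraction on a thinned pixel lattice
#'
#' Pixelwise p-values of a smoothed contrast map are spatially correlated;
#' for calibration checks the map is subsampled on a lattice spaced at
#' about 4 smoothing sds so the retained tests are approximately
#' independent. Degenerate (zero-variance) pixels are excluded.
#'
#' @param contrast A `dfm_contrast`.
#' @param spacing Lattice spacing in pixels.
#' @return List with `n` (tests kept) and `frac` (fraction with
#'   `p < alpha`).
#' @export
contrast_typeI_fraction <- function(contrast, spacing) {
  n <- nrow(contrast$t)
  idx <- seq(ceiling(spacing / 2), n, by = spacing)
  p <- contrast$p[idx, idx]
  keep <- !contrast$degenerate[idx, idx]
  list(n = sum(keep), frac = mean(p[keep] < contrast$alpha))
}
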