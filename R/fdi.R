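#' Z-scored accuracy weights of a session
#'
#' The per-trial weights of the reverse-correlation estimator: each
#' trial's correctness, z-scored over all of the participant's trials
#' using the population-sd convention (divide by n). The output sums to
#' zero. A session with no accuracy variance is degenerate: a warning is
#' raised and all-zero weights are returned, which zeroes the
#' participant's FDi slices downstream.
#'
#' @param session A `dfm_session`, or a logical/0-1 vector of per-trial
#'   correctness.
#' @return Numeric vector of per-trial weights.
#' @examples
#' zscore_accuracy(c(TRUE, FALSE))  # +1, -1
#' @export
zscore_accuracy <- function(session) {
  correct <- if (inherits(session, "dfm_session")) session$log$correct
             else as.logical(session)
  if (length(correct) < 2) {
    stop("need at least 2 trials to z-score accuracy", call. = FALSE)
  }
  m <- mean(correct)
  s <- sqrt(mean((correct - m)^2))
  if (s == 0) {
    warning("degenerate session: accuracy has zero variance; ",
            "weights set to zero")
    return(rep(0, length(correct)))
  }
  (correct - m) / s
}

#' Feature Diagnosticity index
#'
#' The core reverse-correlation estimator: for participant p, image i and
#' feature f,
#' `FDi[p, i, f] = sum over p's trials of image i of selected(f) * z`,
#' where `z` is the participant's z-scored accuracy over *all* their
#' trials ([zscore_accuracy()]; one weighting per participant, so FDi is
#' comparable across images). A plain weighted sum is used: no per-trial
#' normalisation by the number of presented features (the staircase keeps
#' that number in a narrow band); set `normalize = TRUE` to divide each
#' trial's indicator by its feature count instead.
#'
#' Participant-image pairs with fewer than 2 trials, and participants with
#' zero accuracy variance, yield all-zero slices.
#'
#' @param sessions A `dfm_session` or list of them (one per participant).
#' @param normalize Divide each trial's indicator by `n_presented`.
#' @return A `dfm_fdi` object: a 3-d array `participants x images x
#'   features` with dimnames, plus an `images` attribute (tibble with
#'   `image_id`, `category`).
#' @export
compute_fdi <- function(sessions, normalize = FALSE) {
  if (inherits(sessions, "dfm_session")) sessions <- list(sessions)
  nf <- unique(vapply(sessions, function(s) s$n_features, integer(1)))
  if (length(nf) != 1) {
    stop("sessions disagree on the number of features", call. = FALSE)
  }
  images <- sessions[[1]]$images
  pids <- vapply(sessions, function(s) s$participant_id, character(1))
  arr <- array(0, dim = c(length(sessions), nrow(images), nf),
               dimnames = list(pids, images$image_id, NULL))
  for (p in seq_along(sessions)) {
    s <- sessions[[p]]
    if (!identical(s$images$image_id, images$image_id)) {
      stop("input error: sessions disagree on the image set", call. = FALSE)
    }
    z <- suppressWarnings(zscore_accuracy(s))
    sm <- selection_matrix(s)
    if (normalize) sm <- sm / pmax(s$log$n_presented, 1)
    for (i in seq_len(nrow(images))) {
      tr <- which(s$log$image_id == images$image_id[i])
      if (length(tr) < 2) next
      arr[p, i, ] <- as.vector(Matrix::crossprod(sm[tr, , drop = FALSE],
                                                 z[tr]))
    }
  }
  structure(arr, images = images, class = "dfm_fdi")
}

#' @export
print.dfm_fdi <- function(x, ...) {
  d <- dim(x)
  cat("<dfm_fdi> ", d[1], " participants x ", d[2], " images x ", d[3],
      " features\n", sep = "")
  invisible(x)
}

#' @export
tidy.dfm_fdi <- function(x, ...) {
  d <- dim(x)
  images <- attr(x, "images")
  tibble::tibble(
    participant_id = rep(dimnames(x)[[1]], times = d[2] * d[3]),
    image_id = rep(rep(dimnames(x)[[2]], each = d[1]), times = d[3]),
    feature = rep(seq_len(d[3]), each = d[1] * d[2]),
    fdi = as.vector(unclass(x))
  ) |>
    dplyr::left_join(images, by = "image_id")
}

# participant-averaged FDi: images x features matrix
fdi_participant_mean <- function(fdi) {
  d <- dim(fdi)
  m <- apply(unclass(fdi), c(2, 3), mean)
  dim(m) <- c(d[2], d[3])
  rownames(m) <- dimnames(fdi)[[2]]
  m
}
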