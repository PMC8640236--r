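#' Read and write greyscale images as 8-bit PNG
#'
#' Images are numeric matrices on the 0-255 grey scale throughout the
#' package; on disk they are 8-bit greyscale PNG.
#'
#' @param image Numeric matrix, values in 0-255.
#' @param path File path.
#' @return `read_image_png()`: numeric matrix in 0-255.
#' @export
write_image_png <- function(image, path) {
  px <- pmin(pmax(image, 0), 255)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}

#' Serialise a feature set
#'
#' JSON carries the full object (dictionary configuration, image id and
#' atom list); CSV carries one row per atom
#' (`index, x, y, sf_cpi, orientation_deg, envelope_sd, phase_rad,
#' fit_score`) for interoperability.
#'
#' @param features A `dfm_features`.
#' @param path File path.
#' @return `read_features_json()`: the restored `dfm_features`.
#' @export
write_features_json <- function(features, path) {
  cfg <- attr(features, "config")
  jsonlite::write_json(
    list(image_id = attr(features, "image_id"),
         config = unclass(cfg),
         atoms = as.data.frame(features)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features_json
#' @export
read_features_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(dfm_config, obj$config[setdiff(names(obj$config), NULL)])
  new_features(tibble::as_tibble(obj$atoms), obj$image_id, cfg)
}

#' @rdname write_features_json
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(
    data.frame(index = features$feature, x = features$x, y = features$y,
               sf_cpi = features$sf, orientation_deg = features$orientation,
               envelope_sd = features$envelope_sd,
               phase_rad = features$phase, fit_score = features$fit_score),
    path, row.names = FALSE)
  invisible(path)
}

#' Serialise a session
#'
#' The trial log is one CSV row per trial; the sampled-feature indicators
#' go to a companion sparse CSV (`trial, feature`).
#'
#' @param session A `dfm_session`.
#' @param log_path,selections_path File paths.
#' @return `read_session_csv()`: a `dfm_session` (without the final QUEST
#'   posterior, which is not serialised; the threshold summary is
#'   retained in the log attributes' stead by recomputation upstream).
#' @export
write_session_csv <- function(session, log_path, selections_path) {
  utils::write.csv(as.data.frame(session$log), log_path, row.names = FALSE)
  lens <- lengths(session$selections)
  utils::write.csv(
    data.frame(trial = rep.int(seq_along(session$selections), lens),
               feature = unlist(session$selections, use.names = FALSE)),
    selections_path, row.names = FALSE)
  invisible(log_path)
}

#' @rdname write_session_csv
#' @param n_features Feature count of the dictionary the log refers to.
#' @param participant_id Identifier for the restored session.
#' @export
read_session_csv <- function(log_path, selections_path, n_features,
                             participant_id = "p1") {
  log <- tibble::as_tibble(utils::read.csv(log_path))
  sel <- utils::read.csv(selections_path)
  selections <- unname(split(as.integer(sel$feature),
                             factor(sel$trial, levels = log$trial)))
  images <- dplyr::distinct(log, .data$image_id, .data$category) |>
    dplyr::arrange(.data$image_id)
  structure(list(log = log, selections = selections, quest = NULL,
                 threshold = NULL, participant_id = participant_id,
                 n_features = as.integer(n_features), images = images,
                 seed = NA_integer_),
            class = "dfm_session")
}

#' @rdname write_session_csv
#' @param landmarks Landmark tibble of a face set.
#' @param path File path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(as.data.frame(
    landmarks[, c("image_id", "point", "x", "y", "group")]),
    path, row.names = FALSE)
  invisible(path)
}

# write all artefacts of a pipeline run; returns relative file names
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  for (i in seq_len(nrow(run$faces$images))) {
    id <- run$faces$images$image_id[i]
    f <- paste0("image_", id, ".png")
    write_image_png(run$faces$images$pixels[[i]], file.path(out_dir, f))
    add(f)
    f <- paste0("features_", id, ".json")
    write_features_json(run$feature_sets[[id]], file.path(out_dir, f))
    add(f)
  }
  write_landmarks_csv(run$faces$landmarks, file.path(out_dir, "landmarks.csv"))
  add("landmarks.csv")
  for (s in run$sessions) {
    lf <- paste0("session_", s$participant_id, ".csv")
    sf <- paste0("selections_", s$participant_id, ".csv")
    write_session_csv(s, file.path(out_dir, lf), file.path(out_dir, sf))
    add(lf); add(sf)
  }
  utils::write.csv(as.data.frame(dplyr::bind_rows(
    run$sf_profiles, run$orientation_profiles)),
    file.path(out_dir, "band_profiles.csv"), row.names = FALSE)
  add("band_profiles.csv")
  utils::write.csv(
    as.data.frame(dplyr::bind_rows(tibble::as_tibble(run$sf_contrast),
                                   tibble::as_tibble(run$orientation_contrast))),
    file.path(out_dir, "band_contrasts.csv"), row.names = FALSE)
  add("band_contrasts.csv")
  add("manifest.json")
  files
}
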