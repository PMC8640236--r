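#' Configuration of a full pipeline run
#'
#' Bundles every stage's parameters and validates them up front, before
#' any compute starts. All randomness in a run flows from `master_seed`
#' through a documented counter scheme (one derived seed per stage and per
#' participant session), so a rerun with the same configuration reproduces
#' bit-identical trial logs and numerically identical analysis outputs.
#'
#' @param master_seed Integer master seed.
#' @param n_participants Number of simulated participants (default 16).
#' @param n_trials Trials per participant (default 2400).
#' @param dictionary A [dfm_config()].
#' @param face_spec A [synthetic_face_spec()]; its seed is overridden by
#'   the derived stage seed.
#' @param observer List of [dfm_observer()] parameters
#'   (`internal_noise_sd`, `criterion`, `lapse_rate`), or the string
#'   `"null"` for a null observer.
#' @param quest List of [quest_init()] overrides (e.g. `prior_mean`,
#'   `beta`).
#' @param smoothing_sd Positional-map smoothing sd, pixels.
#' @param alpha Significance level for the contrasts.
#' @return A `dfm_run_config` list.
#' @export
dfm_run_config <- function(master_seed = 1L, n_participants = 16L,
                           n_trials = 2400L,
                           dictionary = dfm_config(),
                           face_spec = synthetic_face_spec(),
                           observer = list(internal_noise_sd = 1,
                                           criterion = 0, lapse_rate = 0.02),
                           quest = list(),
                           smoothing_sd = 10, alpha = 0.05) {
  stopifnot(n_participants >= 1, n_trials >= 2, smoothing_sd > 0,
            alpha > 0, alpha < 1)
  if (!identical(observer, "null")) {
    stopifnot(is.list(observer))
    do.call(dfm_observer, c(list(weights = tibble::tibble(
      image_id = character(), feature = integer(), weight = numeric())),
      observer))  # validate parameters early
  }
  do.call(quest_init, c(list(n_max = dictionary$n_features), quest))
  structure(list(master_seed = as.integer(master_seed),
                 n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 dictionary = dictionary, face_spec = face_spec,
                 observer = observer, quest = quest,
                 smoothing_sd = smoothing_sd, alpha = alpha),
            class = "dfm_run_config")
}

# documented counter scheme: one seed per (stage, counter) pair,
# kept below 2^31
derive_seed <- function(master, stage, counter = 0L) {
  stage_id <- match(stage, c("synth", "decompose", "simulate", "fdi", "maps"))
  (master %% 65011) * 33013 + stage_id * 257 + counter
}

#' Run the full diagnostic-feature-mapping pipeline
#'
#' Executes synth (generate the synthetic face set) -> decompose (Gabor
#' feature sets) -> simulate (`n_participants` QUEST-controlled sessions)
#' -> fdi -> maps (positional, SF and orientation contrasts plus
#' ground-truth recovery), and assembles a manifest of seeds, trial counts
#' and stage checksums.
#'
#' @param run_config A [dfm_run_config()].
#' @param out_dir Optional directory; when given, images (PNG), landmarks
#'   and logs (CSV), feature sets (JSON), band profiles (CSV) and the
#'   manifest (JSON) are written there and listed in the manifest.
#' @param verbose Print stage progress.
#' @return A `dfm_run` list: `faces`, `feature_sets`, `observer`,
#'   `sessions`, `fdi`, `position_maps`, `position_contrast`,
#'   `sf_profiles`, `sf_contrast`, `orientation_profiles`,
#'   `orientation_contrast`, `recovery`, `manifest`.
#' @export
run_pipeline <- function(run_config, out_dir = NULL, verbose = FALSE) {
  rc <- run_config
  say <- function(...) if (verbose) message(...)
  ms <- rc$master_seed

  say("stage synth")
  spec <- rc$face_spec
  spec$seed <- derive_seed(ms, "synth")
  faces <- tryCatch(generate_faces(spec, rc$dictionary),
                    error = function(e) stop("stage synth failed: ",
                                             conditionMessage(e), call. = FALSE))

  say("stage decompose")
  feature_sets <- purrr::map(seq_len(nrow(faces$images)), function(i) {
    decompose_image(faces$images$pixels[[i]], rc$dictionary,
                    image_id = faces$images$image_id[i])
  })
  names(feature_sets) <- faces$images$image_id

  observer <- if (identical(rc$observer, "null")) {
    null_observer(n_features = rc$dictionary$n_features)
  } else {
    do.call(observer_from_truth,
            c(list(feature_sets = feature_sets, face_set = faces),
              rc$observer))
  }

  say("stage simulate")
  sessions <- purrr::map(seq_len(rc$n_participants), function(p) {
    run_session(observer, faces$images,
                n_features = rc$dictionary$n_features,
                n_trials = rc$n_trials,
                seed = derive_seed(ms, "simulate", p),
                quest = do.call(quest_init,
                                c(list(n_max = rc$dictionary$n_features),
                                  rc$quest)),
                participant_id = sprintf("p%02d", p))
  })

  say("stage fdi")
  fdi <- compute_fdi(sessions)

  say("stage maps")
  pos_maps <- project_positions(fdi, feature_sets, rc$smoothing_sd)
  pos_con <- contrast_maps(pos_maps, rc$alpha)
  sf_prof <- band_profile(sessions, feature_sets, "sf")
  ori_prof <- band_profile(sessions, feature_sets, "orientation")
  sf_con <- contrast_bands(sf_prof, rc$alpha)
  ori_con <- contrast_bands(ori_prof, rc$alpha)
  recovery <- recover_ground_truth(faces, observer, fdi, pos_con,
                                   sf_con, ori_con)

  total_trials <- sum(vapply(sessions, function(s) nrow(s$log), integer(1)))
  manifest <- list(
    config_hash = fnv1a(paste(deparse(rc), collapse = "\n")),
    master_seed = ms,
    seeds = list(
      synth = derive_seed(ms, "synth"),
      sessions = vapply(seq_len(rc$n_participants),
                        function(p) derive_seed(ms, "simulate", p),
                        numeric(1))
    ),
    n_participants = rc$n_participants,
    n_trials_per_participant = rc$n_trials,
    total_trials = total_trials,
    checksums = list(
      faces = fnv1a(num_string(vapply(faces$images$pixels, sum, numeric(1)))),
      features = fnv1a(num_string(vapply(feature_sets,
                                         function(f) sum(f$fit_score),
                                         numeric(1)))),
      sessions = fnv1a(num_string(vapply(sessions,
                                         function(s) mean(s$log$correct),
                                         numeric(1)))),
      fdi = fnv1a(num_string(sum(fdi))),
      maps = fnv1a(num_string(c(sum(pos_con$t), sum(sf_con$t), sum(ori_con$t))))
    ),
    files = character()
  )

  run <- structure(list(
    faces = faces, feature_sets = feature_sets, observer = observer,
    sessions = sessions, fdi = fdi,
    position_maps = pos_maps, position_contrast = pos_con,
    sf_profiles = sf_prof, sf_contrast = sf_con,
    orientation_profiles = ori_prof, orientation_contrast = ori_con,
    recovery = recovery, manifest = manifest, run_config = rc
  ), class = "dfm_run")

  if (!is.null(out_dir)) {
    run$manifest$files <- write_run(run, out_dir)
    manifest <- run$manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

num_string <- function(x) paste(sprintf("%.17g", x), collapse = ",")

# FNV-1a 32-bit hash of a string, returned as 8 hex digits
fnv1a <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # exact 32-bit modular multiply by the FNV prime in double precision
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @export
print.dfm_run <- function(x, ...) {
  cat("<dfm_run> ", x$manifest$n_participants, " participants x ",
      x$manifest$n_trials_per_participant, " trials = ",
      x$manifest$total_trials, " trials; ",
      length(x$feature_sets), " images\n", sep = "")
  print(x$recovery)
  invisible(x)
}

#' @export
glance.dfm_run <- function(x, ...) {
  acc <- vapply(x$sessions, function(s) mean(s$log$correct), numeric(1))
  thr <- vapply(x$sessions, function(s) s$threshold$n_gabors_threshold,
                numeric(1))
  dplyr::bind_cols(
    tibble::tibble(total_trials = x$manifest$total_trials,
                   mean_accuracy = mean(acc),
                   mean_threshold = mean(thr)),
    glance(x$recovery)
  )
}
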