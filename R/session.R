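#' Run one QUEST-controlled categorisation session
#'
#' Simulates one participant's session: on every trial a stimulus image is
#' drawn uniformly at random, the QUEST-recommended number of features is
#' sampled uniformly without replacement from the image's features, the
#' observer is queried, and the staircase is updated with the outcome. The
#' session runs entirely in feature space (no pixel rendering), which is
#' what makes cohort-scale simulation cheap; [render_stimulus()] produces
#' the corresponding pixels for any logged trial when needed.
#'
#' @param observer A [dfm_observer()] or [weibull_observer()].
#' @param images Either a tibble with columns `image_id` and `category`,
#'   or a named list of `dfm_features` whose names are image ids of the
#'   form `"<category>_<k>"` (as produced by the pipeline).
#' @param n_features Features per image (defaults to the observer's
#'   `n_features`, or 2200).
#' @param n_trials Number of trials (default 2400).
#' @param seed Integer seed for the whole session (stimulus order, feature
#'   sampling, observer noise).
#' @param quest A [quest_init()] state; default `quest_init(n_max =
#'   n_features)`.
#' @param participant_id Identifier stored in the log.
#' @return A `dfm_session`: list with `log` (tibble: `trial`, `image_id`,
#'   `category`, `n_presented`, `response`, `correct`,
#'   `quest_recommendation`), `selections` (list of integer vectors, one
#'   per trial), `quest` (final state), `threshold`
#'   ([threshold_estimate()]), `participant_id`, `n_features`.
#' @export
run_session <- function(observer, images, n_features = NULL,
                        n_trials = 2400, seed = 1L, quest = NULL,
                        participant_id = "p1") {
  images <- session_images(images)
  if (is.null(n_features)) {
    n_features <- observer$n_features %||% 2200L
  }
  if (observer$type == "weights" && observer$n_features != n_features) {
    stop("config error: observer and feature sets disagree on the number ",
         "of features", call. = FALSE)
  }
  if (is.null(quest)) quest <- quest_init(n_max = n_features)
  withr::local_seed(seed)

  ni <- nrow(images)
  img_idx <- sample.int(ni, n_trials, replace = TRUE)
  trial_img <- integer(n_trials)
  n_presented <- integer(n_trials)
  response <- character(n_trials)
  correct <- logical(n_trials)
  recommendation <- integer(n_trials)
  selections <- vector("list", n_trials)

  for (t in seq_len(n_trials)) {
    i <- img_idx[t]
    rec <- quest_recommend(quest)
    sel <- sort(sample.int(n_features, rec))
    resp <- observer_respond(observer, sel, images$image_id[i],
                             images$category[i])
    ok <- resp == images$category[i]
    quest <- quest_update(quest, rec, ok)
    trial_img[t] <- i
    n_presented[t] <- rec
    response[t] <- resp
    correct[t] <- ok
    recommendation[t] <- rec
    selections[[t]] <- sel
  }
  log <- tibble::tibble(
    trial = seq_len(n_trials),
    image_id = images$image_id[trial_img],
    category = images$category[trial_img],
    n_presented = n_presented,
    response = response,
    correct = correct,
    quest_recommendation = recommendation
  )
  structure(list(log = log, selections = selections, quest = quest,
                 threshold = threshold_estimate(quest),
                 participant_id = participant_id,
                 n_features = as.integer(n_features),
                 images = images, seed = as.integer(seed)),
            class = "dfm_session")
}

session_images <- function(images) {
  if (is.data.frame(images)) {
    stopifnot(all(c("image_id", "category") %in% names(images)))
    return(images[, c("image_id", "category")])
  }
  ids <- names(images)
  if (is.null(ids)) stop("config error: feature sets must be named by image id",
                         call. = FALSE)
  tibble::tibble(image_id = ids, category = sub("_[0-9]+$", "", ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dfm_session <- function(x, ...) {
  cat("<dfm_session> '", x$participant_id, "': ", nrow(x$log),
      " trials, accuracy ", round(mean(x$log$correct), 3),
      ", threshold ", round(x$threshold$n_gabors_threshold, 1),
      " features\n", sep = "")
  invisible(x)
}

#' @export
tidy.dfm_session <- function(x, ...) x$log

#' @export
glance.dfm_session <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    n_trials = nrow(x$log),
    accuracy = mean(x$log$correct),
    n_gabors_threshold = x$threshold$n_gabors_threshold,
    posterior_sd = x$threshold$posterior_sd
  )
}

# trials x features sparse indicator of the sampled features
selection_matrix <- function(session) {
  lens <- lengths(session$selections)
  Matrix::sparseMatrix(
    i = rep.int(seq_along(session$selections), lens),
    j = unlist(session$selections, use.names = FALSE),
    x = 1,
    dims = c(nrow(session$log), session$n_features)
  )
}
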