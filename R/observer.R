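#' Simulated observers
#'
#' A simulated observer stands in for a human participant. Two decision
#' rules are provided:
#'
#' * **Feature-weight observer** ([dfm_observer()]): on each trial the
#'   evidence is the sum of the ground-truth weights of the sampled
#'   features of the shown image, plus Gaussian internal noise; the
#'   observer responds "child" when evidence exceeds the criterion.
#'   Weights are signed: positive entries are child evidence (child
#'   images' diagnostic features), negative entries adult evidence. With a
#'   probability `lapse_rate` the observer instead responds uniformly at
#'   random. Category-conditional accuracy is non-decreasing (in
#'   expectation) in the number of diagnostic features sampled.
#' * **Psychometric observer** ([weibull_observer()]): responds correctly
#'   with a probability given by a known Weibull psychometric function of
#'   the *number* of presented features, regardless of which features they
#'   are. Its true 75%-correct point equals its `threshold` parameter
#'   exactly, which makes it the reference for staircase-recovery checks.
#'
#' @param weights Tibble with columns `image_id`, `feature`, `weight`
#'   giving the nonzero (diagnostic) weights per image; features absent
#'   from the table have weight 0. An empty tibble gives a null observer
#'   whose responses are independent of the sampled features.
#' @param n_features Number of features per image the weights refer to.
#' @param internal_noise_sd Sd of the Gaussian evidence noise.
#' @param criterion Decision criterion on the evidence axis.
#' @param lapse_rate Probability of a uniform random response, in
#'   `[0, 0.1]`.
#' @return An object of class `dfm_observer`.
#' @export
dfm_observer <- function(weights, n_features = 2200,
                         internal_noise_sd = 1, criterion = 0,
                         lapse_rate = 0.02) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.1, internal_noise_sd >= 0)
  if (nrow(weights) && max(weights$feature) > n_features) {
    stop("weights refer to features beyond n_features", call. = FALSE)
  }
  structure(list(type = "weights",
                 weights = split(weights, weights$image_id),
                 n_features = as.integer(n_features),
                 internal_noise_sd = internal_noise_sd,
                 criterion = criterion, lapse_rate = lapse_rate),
            class = "dfm_observer")
}

#' @rdname dfm_observer
#' @param threshold The number of features at which the observer is 75%
#'   correct.
#' @param beta,gamma,delta Weibull slope, guess rate and lapse rate of the
#'   psychometric function (same parametrisation as [quest_init()]).
#' @param target_p Performance level the `threshold` refers to.
#' @export
weibull_observer <- function(threshold, beta = 3.5, gamma = 0.5,
                             delta = 0.01, target_p = 0.75) {
  stopifnot(threshold >= 1, target_p > gamma, target_p < 1 - delta)
  structure(list(type = "psychometric", threshold = threshold,
                 beta = beta, gamma = gamma, delta = delta,
                 target_p = target_p),
            class = "dfm_observer")
}

#' @rdname dfm_observer
#' @export
null_observer <- function(n_features = 2200, internal_noise_sd = 1) {
  dfm_observer(tibble::tibble(image_id = character(), feature = integer(),
                              weight = numeric()),
               n_features = n_features,
               internal_noise_sd = internal_noise_sd, lapse_rate = 0)
}

#' Build the default observer from a face set's ground truth
#'
#' Gives each image's diagnostic features (signal atoms matched to
#' decomposed features, [diagnostic_indicator()]) a weight equal to the
#' injected sign: +1 on child images, -1 on adult images.
#'
#' @param feature_sets Named list of `dfm_features`, one per image.
#' @param face_set A `dfm_face_set` from [generate_faces()].
#' @param ... Passed on to [dfm_observer()].
#' @return A `dfm_observer`.
#' @export
observer_from_truth <- function(feature_sets, face_set, ...) {
  imgs <- face_set$images
  w <- purrr::map2_dfr(imgs$image_id, imgs$category, function(id, cat) {
    idx <- diagnostic_indicator(feature_sets[[id]], face_set$truth, cat)
    tibble::tibble(image_id = id, feature = as.integer(idx),
                   weight = if (cat == "child") 1 else -1)
  })
  dfm_observer(w, n_features = face_set$config$n_features, ...)
}

# Weibull psychometric with the threshold anchored at target_p:
# p(x; T) = gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - T + eps))))
# with eps chosen so that p(T) = target_p exactly. x, T in log10 units.
weibull_p <- function(x, t, beta, gamma, delta, target_p) {
  eps <- log10(-log(1 - (target_p - gamma) / (1 - gamma - delta))) / beta
  gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - t + eps))))
}

#' Query a simulated observer on one trial
#'
#' Draws from the current RNG stream; seed control is the caller's
#' responsibility (see [run_session()]).
#'
#' @param observer A `dfm_observer`.
#' @param selected Integer indices of the features presented on the trial.
#' @param image_id Identity of the stimulus image.
#' @param category True category of the image (`"child"` or `"adult"`).
#' @return `"child"` or `"adult"`.
#' @export
observer_respond <- function(observer, selected, image_id, category) {
  if (observer$type == "psychometric") {
    p <- weibull_p(log10(max(length(selected), 1)), log10(observer$threshold),
                   observer$beta, observer$gamma, observer$delta,
                   observer$target_p)
    correct <- stats::runif(1) < p
    other <- if (category == "child") "adult" else "child"
    return(if (correct) category else other)
  }
  w <- observer$weights[[image_id]]
  evidence <- if (is.null(w) || !nrow(w)) 0 else sum(w$weight[w$feature %in% selected])
  evidence <- evidence + stats::rnorm(1, 0, observer$internal_noise_sd)
  resp <- if (evidence > observer$criterion) "child" else "adult"
  if (observer$lapse_rate > 0 && stats::runif(1) < observer$lapse_rate) {
    resp <- sample(c("child", "adult"), 1)
  }
  resp
}
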