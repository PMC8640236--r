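test_that("the prior drives the initial recommendation", {
  q <- quest_init()
  expect_equal(quest_recommend(q), 300L)
  # a nearly point prior pins the recommendation to its mean
  q2 <- quest_init(prior_mean = log10(120), prior_sd = 1e-4)
  expect_equal(quest_recommend(q2), 120L)
  expect_error(quest_init(target_p = 0.3), "target_p")
  expect_error(quest_init(target_p = 0.999), "target_p")
})

test_that("the posterior stays normalised and responds to evidence", {
  q <- quest_init()
  m0 <- sum(q$posterior * q$grid)
  expect_lt(abs(sum(q$posterior) - 1), 1e-12)

  # a correct response at the prior mean means 'easier than threshold':
  # the posterior mean moves down
  qc <- quest_update(q, 300, TRUE)
  expect_lt(abs(sum(qc$posterior) - 1), 1e-12)
  expect_lt(sum(qc$posterior * qc$grid), m0)
  # and an error moves it up
  qe <- quest_update(q, 300, FALSE)
  expect_gt(sum(qe$posterior * qe$grid), m0)

  # order independence, but not count independence
  qab <- quest_update(quest_update(q, 200, TRUE), 350, FALSE)
  qba <- quest_update(quest_update(q, 350, FALSE), 200, TRUE)
  expect_equal(qab$posterior, qba$posterior, tolerance = 1e-12)
  q1 <- quest_update(q, 250, TRUE)
  q2 <- quest_update(q1, 250, TRUE)
  expect_false(isTRUE(all.equal(q1$posterior, q2$posterior)))
  expect_equal(q2$trial_count, 2L)
})

test_that("the assumed psychometric function is anchored and monotone", {
  # p(threshold) = target exactly
  p_at_t <- dfmap:::weibull_p(log10(200), log10(200), 3.5, 0.5, 0.01, 0.75)
  expect_equal(p_at_t, 0.75, tolerance = 1e-12)
  # likelihood of a correct response increases with presented_n
  xs <- log10(seq(10, 2000, by = 10))
  ps <- dfmap:::weibull_p(xs, log10(300), 3.5, 0.5, 0.01, 0.75)
  expect_true(all(diff(ps) >= 0))  # saturates at 1 - delta for large n
  expect_true(all(diff(ps[xs < log10(600)]) > 0))
  expect_gt(ps[1], 0.49)
  expect_lte(ps[length(ps)], 1 - 0.01 + 1e-12)
})

test_that("recommendations follow the posterior mean with rounding and clipping", {
  # uniform posterior over [log10 100, log10 400] -> 200 features
  grid <- seq(log10(100), log10(400), length.out = 4001)
  st <- structure(list(grid = grid, posterior = rep(1 / 4001, 4001),
                       n_max = 2200), class = "dfm_quest")
  expect_equal(quest_recommend(st), 200L)

  # posterior concentrated at 156.52 -> 157 after rounding
  st2 <- structure(list(grid = log10(c(100, 156.52, 300)),
                        posterior = c(0, 1, 0), n_max = 2200),
                   class = "dfm_quest")
  expect_equal(quest_recommend(st2), 157L)

  # posterior concentrated above the intensity range -> clipped
  st3 <- structure(list(grid = log10(c(2500, 3000)), posterior = c(0.5, 0.5),
                        n_max = 2200), class = "dfm_quest")
  expect_equal(quest_recommend(st3), 2200L)
  st4 <- structure(list(grid = log10(c(0.2, 0.5)), posterior = c(0.5, 0.5),
                        n_max = 2200), class = "dfm_quest")
  expect_equal(quest_recommend(st4), 1L)
})

test_that("target-rate outcomes at a fixed intensity pull the threshold there", {
  # an observer at exactly 75% correct at intensity 180 has its 75% point
  # there; repeated updates at that intensity must concentrate the
  # posterior around it. (Alternating correct/incorrect — 50% accuracy —
  # is chance performance for 2-AFC and correctly drives the threshold
  # estimate *upwards*, which is also asserted.)
  q <- quest_init()
  withr::with_seed(31, {
    for (i in 1:400) q <- quest_update(q, 180, runif(1) < 0.75)
  })
  est <- threshold_estimate(q)
  expect_lt(abs(est$n_gabors_threshold - 180) / 180, 0.2)
  expect_lt(est$posterior_sd, 0.1)

  q2 <- quest_init()
  for (i in 1:100) {
    q2 <- quest_update(q2, 180, TRUE)
    q2 <- quest_update(q2, 180, FALSE)
  }
  expect_gt(threshold_estimate(q2)$n_gabors_threshold, 400)
})

test_that("a deterministic step observer is located near the Weibull target crossing", {
  # correct iff presented_n >= 200
  q <- quest_init()
  withr::with_seed(6, {
    for (i in 1:400) {
      n <- quest_recommend(q)
      q <- quest_update(q, n, n >= 200)
    }
  })
  est <- threshold_estimate(q)
  expect_lt(abs(est$n_gabors_threshold - 200) / 200, 0.1)
})

test_that("sessions log every trial and track the accuracy target", {
  fx <- small_face_fixture()
  s <- run_session(fx$observer, fx$faces$images,
                   n_features = fx$cfg$n_features, n_trials = 1200,
                   seed = 21)
  expect_equal(nrow(s$log), 1200)
  expect_equal(s$log$n_presented, lengths(s$selections))
  expect_true(all(s$log$n_presented >= 1 &
                    s$log$n_presented <= fx$cfg$n_features))
  expect_true(all(s$log$response %in% c("child", "adult")))
  expect_equal(s$log$correct, s$log$response == s$log$category)
  # long-run accuracy within 0.05 of the 75% target
  expect_lt(abs(mean(s$log$correct[401:1200]) - 0.75), 0.05)
  # determinism
  s2 <- run_session(fx$observer, fx$faces$images,
                    n_features = fx$cfg$n_features, n_trials = 1200,
                    seed = 21)
  expect_identical(s$log, s2$log)
  expect_identical(s$selections, s2$selections)
})

test_that("known-psychometric observers are recovered within tolerance", {
  imgs <- tibble::tibble(image_id = c("child_1", "adult_1"),
                         category = c("child", "adult"))
  for (true_t in c(120, 420)) {
    obs <- weibull_observer(true_t)
    est <- vapply(1:7, function(k) {
      run_session(obs, imgs, n_features = 2200, n_trials = 800,
                  seed = 100 + k)$threshold$n_gabors_threshold
    }, numeric(1))
    expect_lt(abs(stats::median(est) - true_t) / true_t, 0.15)
  }
})

test_that("session/observer feature-count mismatches are caught", {
  fx <- small_face_fixture()
  expect_error(run_session(fx$observer, fx$faces$images, n_features = 55),
               "config error")
})
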