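test_that("noiseless respondents reproduce the target exactly", {
  sess <- build_full_session(seed = 1)
  item <- scored_items(sess)[1, ]
  m <- respondent_model(ability = 0, sigma_dim = 1e-9, p_stick = 0)
  set.seed(1)
  r <- simulate_response(m, item)
  expect_equal(r$final_slider, item$target_slider, tolerance = 1e-6)
  expect_true(r$moved)
})

test_that("p_stick = 1 leaves every slider at the default position", {
  sess <- build_full_session(seed = 1)
  spec <- cohort_spec(n_respondents = 5, p_stick = 1, seed = 2)
  sim <- simulate_cohort(spec, sess)
  expect_true(all(!sim$responses$moved))
  expect_true(all(sim$responses$final_slider == 50))
})

test_that("memory trials are noisier than match trials by construction", {
  sess <- build_full_session(seed = 1)
  item_match <- scored_items(sess)[scored_items(sess)$variant == "match", ][1, ]
  item_mem <- item_match
  item_mem$variant <- "memory"
  m <- respondent_model(ability = 0, sigma_dim = 10, memory_multiplier = 3,
                        p_stick = 0)
  set.seed(3)
  err_match <- replicate(1000, abs(simulate_response(m, item_match)$final_slider -
                                     item_match$target_slider))
  err_mem <- replicate(1000, abs(simulate_response(m, item_mem)$final_slider -
                                   item_mem$target_slider))
  expect_gt(mean(err_mem), mean(err_match))
})

test_that("memory items report a single stimulus playback", {
  sess <- build_full_session(seed = 1)
  sim <- simulate_cohort(cohort_spec(n_respondents = 5, seed = 4), sess)
  mem <- grepl("_mem_", sim$responses$item_id)
  expect_true(all(sim$responses$n_stimulus_playbacks[mem] == 1))
  expect_true(any(sim$responses$n_stimulus_playbacks[!mem] > 1))
})

test_that("cohort simulation is a pure function of the spec seed", {
  sess <- build_full_session(seed = 1)
  a <- simulate_cohort(cohort_spec(n_respondents = 10, seed = 5), sess)
  b <- simulate_cohort(cohort_spec(n_respondents = 10, seed = 5), sess)
  expect_identical(a$responses, b$responses)
  expect_identical(a$abilities, b$abilities)
  c_ <- simulate_cohort(cohort_spec(n_respondents = 10, seed = 6), sess)
  expect_false(identical(a$responses$final_slider,
                         c_$responses$final_slider))
})

test_that("default cohort supports 6 bins on every retained item", {
  sess <- build_full_session(seed = 1)
  sim <- simulate_cohort(cohort_spec(seed = 7), sess)
  sc <- score_responses(sim$responses, sess)
  retained <- setdiff(scored_items(sess)$item_id, sc$flagged)
  expect_setequal(names(sc$bins$boundaries), retained)
  expect_true(all(vapply(sc$bins$boundaries, length, integer(1)) == 5))
})

test_that("kappa = 0 severs the ability-score relation", {
  sess <- build_short_session()
  spec <- cohort_spec(n_respondents = 500, kappa = 0, seed = 8)
  sim <- simulate_cohort(spec, sess)
  sc <- score_responses(sim$responses, sess)
  rs <- sc$report$respondent_scores
  rho <- cor(sim$abilities[rs$respondent_id], rs$overall,
             method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("retest pairs share abilities but draw independent noise", {
  sess <- build_short_session()
  pair <- simulate_retest(cohort_spec(n_respondents = 20, seed = 9), sess)
  expect_false(identical(pair$test$final_slider, pair$retest$final_slider))
  # near-noiseless respondents give retest ICC of 1
  quiet <- simulate_retest(cohort_spec(n_respondents = 20, sigma_dim = 1e-6,
                                       p_stick = 0, seed = 10), sess)
  raw_t <- raw_scores(quiet$test, sess)
  raw_r <- raw_scores(quiet$retest, sess)
  agg_t <- tapply(raw_t$distance, raw_t$respondent_id, mean)
  agg_r <- tapply(raw_r$distance, raw_r$respondent_id, mean)
  # all distances ~0 -> between-subject variance ~0; score-level check
  # instead: simulated slider positions agree across occasions
  expect_equal(unname(agg_t), unname(agg_r), tolerance = 1e-4)
})

test_that("retest ICC tracks the variance-ratio prediction", {
  sess <- build_short_session()
  spec <- cohort_spec(n_respondents = 25, kappa = 1, sigma_dim = 10,
                      p_stick = 0, seed = 11)
  # large-n oracle for the score variance decomposition: between-subject
  # variance of the per-occasion mean raw distance vs within-subject
  # (occasion-to-occasion) variance
  big <- cohort_spec(n_respondents = 400, kappa = 1, sigma_dim = 10,
                     p_stick = 0, seed = 12)
  pair_big <- simulate_retest(big, sess)
  m1 <- tapply(raw_scores(pair_big$test, sess)$distance,
               raw_scores(pair_big$test, sess)$respondent_id, mean)
  m2 <- tapply(raw_scores(pair_big$retest, sess)$distance,
               raw_scores(pair_big$retest, sess)$respondent_id, mean)
  subj <- (m1 + m2) / 2
  var_between <- var(subj) - var(m1 - m2) / 4
  var_within <- var(m1 - m2) / 2
  icc_pred <- var_between / (var_between + var_within)

  iccs <- vapply(1:30, function(i) {
    sp <- cohort_spec(n_respondents = 25, kappa = 1, sigma_dim = 10,
                      p_stick = 0, seed = 100 + i)
    pr <- simulate_retest(sp, sess)
    t1 <- tapply(raw_scores(pr$test, sess)$distance,
                 raw_scores(pr$test, sess)$respondent_id, mean)
    t2 <- tapply(raw_scores(pr$retest, sess)$distance,
                 raw_scores(pr$retest, sess)$respondent_id, mean)
    icc_absolute(t1, t2)$icc
  }, numeric(1))
  expect_equal(mean(iccs), icc_pred, tolerance = 0.07)
})

test_that("single shared ability yields a one-factor match structure", {
  sess <- build_full_session(seed = 1)
  sim <- simulate_cohort(cohort_spec(n_respondents = 95, seed = 13), sess)
  sc <- score_responses(sim$responses, sess)
  rs <- sc$report$respondent_scores
  vars <- rs[, c("envelope_match", "flux_match", "centroid_match")]
  fit <- efa_minres(vars, seed = 14)
  expect_equal(fit$n_factors_parallel, 1)
  expect_equal(fit$n_factors_kaiser, 1)
})

test_that("simulated cohorts show the memory-worse-than-match pattern", {
  sess <- build_full_session(seed = 1)
  sim <- simulate_cohort(cohort_spec(seed = 15), sess)
  raw <- raw_scores(sim$responses, sess)
  items <- scored_items(sess)
  raw$block <- items$block[match(raw$item_id, items$item_id)]
  raw$variant <- items$variant[match(raw$item_id, items$item_id)]
  means <- tapply(raw$distance, list(raw$block, raw$variant), mean)
  expect_true(all(means[, "memory"] > means[, "match"]))
})
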