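test_that("session generation is reproducible and structurally valid", {
  d <- design_spec()
  s1 <- generate_session(d, rw_agent(), seed = 10)
  s2 <- generate_session(d, rw_agent(), seed = 10)
  expect_identical(s1, s2)
  s3 <- generate_session(d, rw_agent(), seed = 11)
  expect_false(identical(s1$trials$chosen, s3$trials$chosen))

  expect_equal(nrow(s1$trials), 96)
  expect_equal(sort(unique(s1$trials$block)), 1:4)
  # balanced pairing: each HR x LR pair 6 times per 24-trial block
  pairs <- table(s1$trials$hr_person, s1$trials$lr_person)
  expect_true(all(pairs == 24))
  # counterbalanced sides
  expect_equal(as.integer(table(s1$trials$side_of_hr)), c(48L, 48L))
  # simulation onset 8 s after trial onset, rating 8 s later
  expect_true(all(s1$trials$sim_onset - s1$trials$choice_onset == 8))
  expect_true(all(s1$trials$rating_onset - s1$trials$sim_onset == 8))
})

test_that("a deterministic always-HR agent yields p(HR) = 1", {
  s <- generate_session(design_spec(), model_params("NULL", bias = 1),
                        seed = 2)
  expect_equal(prob_hr(s), 1)
})

test_that("valence frequencies converge to the design probabilities", {
  # pool >= 10,000 trials from RW agents and check the 0.8 / 0.3 rates
  sessions <- lapply(1:140, function(i)
    generate_session(design_spec(), rw_agent(), seed = 1000 + i))
  trials <- dplyr::bind_rows(lapply(sessions, function(s) s$trials))
  hr_chosen <- trials[trials$chosen %in% c("hr1", "hr2"), ]
  lr_chosen <- trials[trials$chosen %in% c("lr1", "lr2"), ]
  expect_gte(nrow(hr_chosen), 10000)
  expect_equal(mean(hr_chosen$valence == "pleasant"), 0.8, tolerance = 0.0125)
  expect_equal(mean(lr_chosen$valence == "pleasant"), 0.3, tolerance = 0.05)
  # reward is the binarized pleasantness with neutral mapping to 0
  expect_identical(trials$reward[!trials$missed],
                   as.integer(trials$pleasantness[!trials$missed] > 0))
})

test_that("learning is possible in the design: RW agents prefer HR", {
  p_hr <- vapply(1:200, function(i) {
    s <- generate_session(design_spec(),
                          rw_agent(alpha = runif(1, 0.1, 0.9),
                                   beta = runif(1, 1, 10)),
                          seed = 5000 + i)
    prob_hr(s)
  }, numeric(1))
  expect_gt(mean(p_hr), 0.5)
})

test_that("miss_rate marks trials missed without breaking the session", {
  d <- design_spec(miss_rate = 0.1)
  s <- generate_session(d, rw_agent(), seed = 3)
  expect_gt(sum(s$trials$missed), 0)
  expect_true(all(is.na(s$trials$chosen[s$trials$missed])))
  expect_true(all(is.na(s$trials$reward[s$trials$missed])))
  expect_false(anyNA(s$trials$reward[!s$trials$missed]))
})

test_that("cohort generation plants the liking structure", {
  spec <- cohort_spec(n_subjects = 8, seed = 4)
  coh <- generate_cohort(spec)
  expect_length(coh$sessions, 8)
  expect_equal(nrow(coh$subjects), 8)
  expect_identical(generate_cohort(spec), coh)  # determinism

  # no effect, no noise: liking changes are exactly zero
  flat <- generate_cohort(cohort_spec(n_subjects = 4, liking_effect = 0,
                                      liking_noise_sd = 0, seed = 5))
  ch <- liking_change(flat$persons)
  expect_true(all(ch$hr_corrected == 0 & ch$lr_corrected == 0))

  # strong planted effect, no noise: preference and liking update align
  strong <- generate_cohort(cohort_spec(n_subjects = 12, liking_effect = 0.5,
                                        liking_noise_sd = 0, seed = 6))
  ch <- liking_change(strong$persons)
  ch <- ch[order(ch$subject_id), ]
  sub <- strong$subjects[order(strong$subjects$subject_id), ]
  expect_equal(cor(sub$p_hr, ch$hr_vs_lr, method = "spearman"), 1,
               tolerance = 0.01)
})

test_that("pattern generation respects its signal and noise structure", {
  # pure signal: identical person patterns across runs
  pure <- generate_patterns(pattern_spec(n_voxels = 30, noise_sd = 0,
                                         seed = 7))
  p1r1 <- pure$patterns[1, ]
  p1r2 <- pure$patterns[5, ]  # same person, next run
  expect_equal(cor(p1r1, p1r2), 1)

  # pure noise: no same-person advantage on average
  taus <- vapply(1:40, function(i) {
    ps <- generate_patterns(pattern_spec(n_voxels = 40, signal_sd = 0,
                                         seed = 100 + i))
    rsm_agreement(build_model_rsm(ps$labels), neural_rsm(ps))
  }, numeric(1))
  expect_lt(abs(mean(taus)), 0.05)

  # planted person signal: positive model agreement
  strong <- generate_patterns(pattern_spec(n_voxels = 40, signal_sd = 3,
                                           noise_sd = 0.5, seed = 8))
  expect_gt(rsm_agreement(build_model_rsm(strong$labels),
                          neural_rsm(strong)), 0.5)
})
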