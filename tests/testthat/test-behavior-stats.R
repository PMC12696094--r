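test_that("prob_hr counts valid HR choices only", {
  s <- fixture_session(rep(c("hr1", "lr1"), 48), rep(c(1, 0), 48))
  expect_equal(prob_hr(s), 0.5)
  s <- fixture_session(rep("hr1", 10), rep(1, 10))
  expect_equal(prob_hr(s), 1)
  # 3 missed trials, 60 HR of 93 valid
  choices <- c(rep("hr1", 60), rep("lr1", 33), rep(NA, 3))
  rewards <- c(rep(1, 60), rep(0, 33), rep(NA, 3))
  s <- fixture_session(choices, rewards)
  expect_equal(prob_hr(s), 60 / 93)
})

test_that("wilcoxon matches the all-positive worked example", {
  values <- seq(0.51, 0.99, length.out = 49)
  res <- wilcoxon_signed_rank(values, mu = 0.5, alternative = "greater")
  expect_equal(res$W, 49 * 50 / 2)  # 1225
  z_expected <- (1225 - 612.5 - 0.5) / sqrt(49 * 50 * 99 / 24)
  expect_equal(res$z, z_expected)
  expect_equal(round(res$r_effect, 2), 0.87)
  expect_lt(res$p, 0.001)
})

test_that("wilcoxon handles edge cases and agrees with the reference W", {
  # a single positive difference among negatives has rank-sum contribution
  res <- wilcoxon_signed_rank(c(10, -1, -2, -3, -4, -5, -6), mu = 0,
                              alternative = "greater")
  expect_equal(res$W, 7)  # |10| is the largest difference, rank 7
  one_up <- wilcoxon_signed_rank(c(0.6, rep(0.4, 9)), mu = 0.5,
                                 alternative = "greater")
  expect_equal(one_up$W, sum(rank(abs(c(0.6, rep(0.4, 9)) - 0.5))[1]))
  expect_error(wilcoxon_signed_rank(rep(0.5, 10), mu = 0.5), "equal mu")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), mu = 0), "at least 6")

  # W agrees with the standard implementation (no zeros, no ties)
  set.seed(31)
  x <- rnorm(25, 0.2)
  ours <- wilcoxon_signed_rank(x, mu = 0, alternative = "greater")
  ref <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                             alternative = "greater"))
  expect_equal(ours$W, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 0.05)
})

test_that("wilcoxon W is invariant to monotone transforms fixing mu's side", {
  set.seed(32)
  x <- runif(30, 0.2, 0.9)
  w1 <- wilcoxon_signed_rank(x, mu = 0.5)$W
  w2 <- wilcoxon_signed_rank(0.5 + (x - 0.5)^3, mu = 0.5)$W
  expect_equal(w1, w2)
})

test_that("liking_change corrects by baseline and cancels constants", {
  persons <- fixture_persons()
  ch <- liking_change(persons)
  expect_equal(ch$hr_corrected, 0)
  expect_equal(ch$hr_vs_lr, 0)

  persons$liking_post <- persons$liking_pre +
    c(0.2, 0.2, 0, 0, 0.05, 0.05)  # dHR = .2, dLR = 0, dBase = .05
  ch <- liking_change(persons)
  expect_equal(ch$hr_corrected, 0.15)
  expect_equal(ch$lr_corrected, -0.05)
  expect_equal(ch$hr_vs_lr, 0.2)

  shifted <- persons
  shifted$liking_post <- persons$liking_post + 0.1
  ch2 <- liking_change(shifted)
  expect_equal(ch2$hr_corrected, ch$hr_corrected)
  expect_equal(ch2$lr_corrected, ch$lr_corrected)

  expect_error(liking_change(persons[persons$condition != "BASELINE", ]),
               "BASELINE")
})

test_that("skipped_spearman is exact on clean monotone data", {
  res <- skipped_spearman(1:20, (1:20)^2, n_boot = 200, seed = 1)
  expect_equal(res$r, 1)
  expect_false(any(res$outliers))
})

test_that("skipped_spearman removes a planted discordant outlier", {
  x <- c(seq(0, 1, length.out = 20), 5)
  y <- c(seq(0, 1, length.out = 20) + 0.01 * sin(1:20), -5)
  plain <- cor(x, y, method = "spearman")
  res <- skipped_spearman(x, y, n_boot = 200, seed = 2)
  expect_true(res$outliers[21])
  expect_equal(res$r, cor(x[-21], y[-21], method = "spearman"))
  expect_gt(res$r, plain)
})

test_that("skipped_spearman is near zero under independence", {
  set.seed(33)
  x <- rnorm(200)
  y <- rnorm(200)
  res <- skipped_spearman(x, y, n_boot = 200, seed = 3)
  expect_lt(abs(res$r), 0.15)
  expect_true(res$ci[1] < res$r, res$r < res$ci[2])
  expect_error(skipped_spearman(1:5, 1:5), "at least 10")
})

test_that("acquired preference is detectable across an RW cohort", {
  p_hr <- vapply(1:200, function(i) {
    s <- generate_session(design_spec(),
                          rw_agent(alpha = runif(1, 0.1, 0.9),
                                   beta = runif(1, 1, 10)),
                          seed = 7000 + i)
    prob_hr(s)
  }, numeric(1))
  res <- wilcoxon_signed_rank(p_hr, mu = 0.5, alternative = "greater")
  expect_lt(res$p, 0.001)
  expect_gt(res$r_effect, 0.5)
})
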