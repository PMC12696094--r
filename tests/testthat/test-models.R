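test_that("rw_update follows the error-driven learning rule", {
  u <- rw_update(0.5, 1, 0.5)
  expect_equal(u$delta, 0.5)
  expect_equal(u$q_new, 0.75)

  u <- rw_update(0.7, 0, 0)
  expect_equal(u$q_new, 0.7)
  expect_equal(u$delta, -0.7)

  u <- rw_update(0.5, 0, 1)
  expect_equal(u$q_new, 0)
  expect_equal(u$delta, -0.5)

  expect_error(rw_update(0.5, 1, 1.2), "alpha")
})

test_that("values stay in [0,1] for any binary reward sequence", {
  set.seed(11)
  for (rep in 1:20) {
    alpha <- runif(1)
    q <- runif(1)
    for (r in rbinom(50, 1, 0.5)) {
      q <- rw_update(q, r, alpha)$q_new
      expect_gte(q, 0)
      expect_lte(q, 1)
    }
  }
})

test_that("softmax_pair is normalized, stable, and handles limits", {
  expect_equal(softmax_pair(c(0.5, 0.5), 5), c(0.5, 0.5))
  expect_equal(softmax_pair(c(1, 0), 0), c(0.5, 0.5))
  expect_equal(softmax_pair(c(1, 0), log(3)), c(0.75, 0.25))
  # max-subtraction keeps huge scores finite
  p <- softmax_pair(c(1000, 0), 1)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  expect_error(softmax_pair(c(1, 0), -1), "beta")
})

test_that("choice probability of the better option rises monotonically in beta", {
  q <- c(0.8, 0.3)
  betas <- c(0, 0.5, 1, 2, 5, 10, 20)
  p_hi <- vapply(betas, function(b) softmax_pair(q, b)[1], numeric(1))
  expect_true(all(diff(p_hi) > 0))
  expect_gt(p_hi[length(p_hi)], 0.999)
})

test_that("ck_update pushes the chosen kernel up and the others down", {
  expect_equal(ck_update(c(A = 0, B = 0), "A", 1), c(A = 1, B = 0))
  expect_equal(ck_update(c(A = 0.5, B = 0.5), "A", 0), c(A = 0.5, B = 0.5))
  expect_equal(ck_update(c(A = 0.2, B = 0.8), "B", 0.5), c(A = 0.1, B = 0.9))
  expect_error(ck_update(c(A = 0.2), "C", 0.5), "unknown person")
  # kernels remain in [0,1]
  set.seed(5)
  ck <- c(A = 0.3, B = 0.7)
  for (i in 1:50) {
    ck <- ck_update(ck, sample(c("A", "B"), 1), runif(1))
    expect_true(all(ck >= 0 & ck <= 1))
  }
})

test_that("wsls_prob implements the noisy stay/shift rule", {
  expect_equal(wsls_prob("win", TRUE, 0), 1)
  expect_equal(wsls_prob("lose", TRUE, 1), 0.5)
  expect_equal(wsls_prob("win", TRUE, 0.2), 0.9)
  expect_equal(wsls_prob("win", FALSE, 0.2), 0.1)
  expect_equal(wsls_prob("lose", TRUE, 0.2), 0.1)
  expect_equal(wsls_prob("none", TRUE, 0.2), 0.5)
})

test_that("null_prob is a pure history-independent bias", {
  expect_equal(null_prob(TRUE, 0.5), 0.5)
  expect_equal(null_prob(FALSE, 0.8), 0.2)
  expect_equal(null_prob(TRUE, 0.8), 0.8)
})

test_that("model registry has the df structure implied by the BIC identity", {
  expect_equal(model_names(), c("RW", "CK", "RWCK", "WSLS", "NULL"))
  dfs <- vapply(model_names(), model_df, integer(1))
  expect_equal(unname(dfs), c(2L, 2L, 4L, 1L, 1L))
})

test_that("model_params validates names and bounds", {
  expect_error(model_params("RW", alpha = 0.5), "requires exactly")
  expect_error(model_params("RW", alpha = 1.5, beta = 1), "alpha")
  expect_error(model_params("RW", alpha = 0.5, beta = -1), "beta")
  p <- model_params("RWCK", alpha = 0.3, beta = 4, alpha_c = 0.2, beta_c = 1)
  expect_s3_class(p, "model_params")
})

test_that("session likelihood matches closed forms for unbiased models", {
  set.seed(21)
  choices <- sample(c("hr1", "lr1"), 96, replace = TRUE)
  rewards <- rbinom(96, 1, 0.5)
  s <- fixture_session(choices, rewards)
  # p = 0.5 on every trial for a 50/50 bias
  nl <- session_negloglik(model_params("NULL", bias = 0.5), s)
  expect_equal(nl$negll, 96 * log(2), tolerance = 1e-10)
  # beta = 0 makes RW random regardless of alpha
  for (alpha in c(0, 0.3, 1)) {
    nl <- session_negloglik(model_params("RW", alpha = alpha, beta = 0), s)
    expect_equal(nl$negll, 96 * log(2), tolerance = 1e-10)
  }
})

test_that("missed trials contribute no likelihood and freeze the state", {
  choices <- c("hr1", NA, "hr1", "lr1")
  rewards <- c(1, NA, 1, 0)
  s <- fixture_session(choices, rewards)
  params <- rw_agent(alpha = 0.5, beta = 2)
  res <- session_negloglik(params, s)
  expect_true(is.na(res$latents$q_chosen[2]))
  # the missed trial leaves Q untouched: trial 3 sees the post-trial-1 value
  expect_equal(res$latents$q_chosen[3], 0.75)
  # likelihood equals the same session with the missed trial deleted
  s2 <- fixture_session(choices[-2], rewards[-2])
  expect_equal(res$negll, session_negloglik(params, s2)$negll,
               tolerance = 1e-12)
})

test_that("all models assign total probability 1 over all choice sequences", {
  set.seed(7)
  specs <- list(
    model_params("RW", alpha = runif(1), beta = runif(1, 0, 10)),
    model_params("CK", alpha_c = runif(1), beta_c = runif(1, 0, 10)),
    model_params("RWCK", alpha = runif(1), beta = runif(1, 0, 10),
                 alpha_c = runif(1), beta_c = runif(1, 0, 10)),
    model_params("WSLS", epsilon = runif(1)),
    model_params("NULL", bias = runif(1))
  )
  hr <- c("hr1", "hr2", "hr1", "hr2")
  lr <- c("lr1", "lr1", "lr2", "lr2")
  for (params in specs) {
    total <- total_choice_probability(params, 4, alternating_reward,
                                      hr = hr, lr = lr)
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("fitted RWCK never loses to the models it nests", {
  s <- generate_session(design_spec(), rw_agent(), seed = 42)
  f_rw <- fit_subject("RW", s, n_starts = 10, seed = 1)
  f_ck <- fit_subject("CK", s, n_starts = 10, seed = 1)
  f_rwck <- fit_subject("RWCK", s, n_starts = 10, seed = 1)
  expect_lte(f_rwck$negll, f_rw$negll + 1e-6)
  expect_lte(f_rwck$negll, f_ck$negll + 1e-6)
})

test_that("empty or malformed sessions are rejected", {
  expect_error(fixture_session(character(0), numeric(0)), "positive multiple")
  expect_error(
    fixture_session(c("lr2", "hr1"), c(1, 0)),  # lr2 not on offer
    "offered pair"
  )
})
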