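# Deterministic session fixtures and a brute-force likelihood oracle.

fixture_persons <- function() {
  tibble::tibble(
    person_id = c("hr1", "hr2", "lr1", "lr2", "base1", "base2"),
    condition = c("HR", "HR", "LR", "LR", "BASELINE", "BASELINE"),
    liking_pre = 0.5, liking_post = 0.5,
    familiarity_pre = 0.7, familiarity_post = 0.7
  )
}

# Build a session with fully specified choices and rewards. `choices` is a
# character vector of person ids (NA for a missed trial); `rewards` is 0/1
# (NA on missed trials). Offers default to hr1 vs lr1 on every trial.
fixture_session <- function(choices, rewards,
                            hr = rep("hr1", length(choices)),
                            lr = rep("lr1", length(choices)),
                            subject_id = "fix01") {
  n <- length(choices)
  missed <- is.na(choices)
  trial_len <- 24
  onsets <- (seq_len(n) - 1) * trial_len
  trials <- tibble::tibble(
    t = seq_len(n), block = 1L,
    hr_person = hr, lr_person = lr,
    chosen = choices, missed = missed,
    valence = ifelse(missed, NA_character_,
                     ifelse(rewards == 1, "pleasant", "neutral_unpleasant")),
    pleasantness = ifelse(missed, NA_real_, ifelse(rewards == 1, 0.5, -0.25)),
    reward = as.integer(rewards),
    side_of_hr = "left",
    choice_onset = onsets, sim_onset = onsets + 8, rating_onset = onsets + 16
  )
  design <- design_spec(n_trials = n, n_blocks = 1)
  bandit_session(subject_id, fixture_persons(), trials, design)
}

# Enumerate all 2^T choice sequences over the offered pairs and sum the
# model-assigned sequence probabilities exp(-negll). `reward_of(person, t)`
# deterministically maps a hypothetical choice to its reward, so each
# sequence yields a well-defined session. A correctly normalized
# likelihood sums to 1.
total_choice_probability <- function(params, n_trials, reward_of,
                                     hr = rep("hr1", n_trials),
                                     lr = rep("lr1", n_trials)) {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n_trials))
  total <- 0
  for (row in seq_len(nrow(grid))) {
    pick_hr <- unlist(grid[row, ])
    choices <- ifelse(pick_hr, hr, lr)
    rewards <- vapply(seq_len(n_trials),
                      function(t) reward_of(choices[t], t), numeric(1))
    s <- fixture_session(choices, rewards, hr = hr, lr = lr)
    total <- total + exp(-session_negloglik(params, s)$negll)
  }
  total
}

# Reward table used by the normalization tests: HR persons rewarded on odd
# trials, LR persons on even trials.
alternating_reward <- function(person, t) {
  hr_person <- person %in% c("hr1", "hr2")
  as.numeric(hr_person == (t %% 2 == 1))
}

rw_agent <- function(alpha = 0.4, beta = 5) {
  model_params("RW", alpha = alpha, beta = beta)
}
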