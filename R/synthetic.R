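# Synthetic cohorts: sessions, liking ratings, activity patterns ---------

# Truncated-normal draws by inverse-CDF; used for pleasantness ratings.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Probability that a simulated agent picks the HR person of the offered
# pair, given its latent state. Mirrors the likelihood in negll_arrays();
# the two are tied together by the likelihood-normalization property tests.
agent_prob_hr <- function(model, par, state, hr, lr) {
  if (model %in% c("RW", "CK", "RWCK")) {
    dv <- switch(model,
      RW   = par[2] * (state$Q[hr] - state$Q[lr]),
      CK   = par[2] * (state$CK[hr] - state$CK[lr]),
      RWCK = par[2] * (state$Q[hr] - state$Q[lr]) +
             par[4] * (state$CK[hr] - state$CK[lr])
    )
    1 / (1 + exp(-dv))
  } else if (model == "WSLS") {
    pc <- state$prev_chosen
    if (is.na(pc) || (pc != hr && pc != lr)) {
      0.5
    } else {
      p_stay <- if (state$prev_win) 1 - par[1] / 2 else par[1] / 2
      if (pc == hr) p_stay else 1 - p_stay
    }
  } else { # NULL
    par[1]
  }
}

agent_update <- function(model, par, state, chosen, reward) {
  if (model %in% c("RW", "RWCK")) {
    state$Q[chosen] <- state$Q[chosen] + par[1] * (reward - state$Q[chosen])
  }
  if (model %in% c("CK", "RWCK")) {
    ac <- if (model == "CK") par[1] else par[3]
    target <- as.numeric(seq_along(state$CK) == chosen)
    state$CK <- state$CK + ac * (target - state$CK)
  }
  state$prev_chosen <- chosen
  state$prev_win <- reward == 1
  state
}

default_persons <- function() {
  tibble::tibble(
    person_id = c("hr1", "hr2", "lr1", "lr2", "base1", "base2"),
    condition = c("HR", "HR", "LR", "LR", "BASELINE", "BASELINE"),
    liking_pre = stats::runif(6, 0.4, 0.6),
    familiarity_pre = stats::runif(6, 0.5, 0.9)
  ) |>
    dplyr::mutate(liking_post = liking_pre,
                  familiarity_post = familiarity_pre) |>
    dplyr::select(person_id, condition, liking_pre, liking_post,
                  familiarity_pre, familiarity_post)
}

# Balanced HR x LR pairing: each of the 4 possible pairs appears equally
# often within a block (up to remainder), in shuffled order; the HR person's
# side of the screen is counterbalanced within block.
pairing_schedule <- function(n_trials, n_blocks) {
  per_block <- n_trials / n_blocks
  combos <- expand.grid(hr = c("hr1", "hr2"), lr = c("lr1", "lr2"),
                        stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(n_blocks), function(b) {
    idx <- sample(rep_len(seq_len(4), per_block))
    tibble::tibble(
      block = b,
      hr_person = combos$hr[idx],
      lr_person = combos$lr[idx],
      side_of_hr = sample(rep_len(c("left", "right"), per_block))
    )
  })
}

#' Simulate one subject's session
#'
#' Plays the imagined-reward bandit through a simulated agent. Each trial
#' offers one HR and one LR person (balanced pairing, counterbalanced
#' sides); the agent chooses by its own choice rule; the scenario valence is
#' drawn Bernoulli with the design's HR/LR pleasant probabilities; the
#' continuous pleasantness rating is drawn from a valence-conditional
#' truncated normal on \[-1, 1\]; the binary reward is `pleasantness > 0`
#' (the neutral midpoint maps to non-reward). Trials are missed
#' independently with the design's `miss_rate`; missed trials carry no
#' choice or outcome and do not update the agent.
#'
#' Onsets follow the trial structure: choice phase up to 3 s, chosen name
#' 2.5 s, fixation 2.5 s plus choice remainder (simulation starts 8 s after
#' trial onset), simulation 8 s, rating up to 5 s, jittered 2-5 s ITI.
#'
#' @param design A [design_spec()].
#' @param agent A [model_params()] object used as the generating agent.
#' @param seed Integer seed; together with the arguments it fully
#'   determines the session.
#' @param subject_id Subject identifier.
#' @param pleasant_mean,pleasant_sd,unpleasant_mean,unpleasant_sd
#'   Parameters of the truncated-normal pleasantness distributions for
#'   pleasant and neutral-to-unpleasant scenarios.
#' @return A `bandit_session`.
#' @export
#' @examples
#' s <- generate_session(design_spec(), model_params("RW", alpha = 0.4, beta = 5),
#'                       seed = 1)
#' prob_hr(s)
generate_session <- function(design, agent, seed, subject_id = "s01",
                             pleasant_mean = 0.5, pleasant_sd = 0.25,
                             unpleasant_mean = -0.25, unpleasant_sd = 0.25) {
  stopifnot(inherits(design, "design_spec"), inherits(agent, "model_params"))
  withr::with_seed(as.integer(seed), {
    persons <- default_persons()
    schedule <- pairing_schedule(design$n_trials, design$n_blocks)
    n <- design$n_trials
    par <- unlist(agent$params)
    state <- list(Q = rep(0.5, 4), CK = rep(0, 4),
                  prev_chosen = NA_integer_, prev_win = NA)
    idx_of <- stats::setNames(1:4, c("hr1", "hr2", "lr1", "lr2"))

    chosen <- character(n); missed <- logical(n)
    valence <- character(n); pleasantness <- numeric(n); reward <- integer(n)
    choice_onset <- sim_onset <- rating_onset <- numeric(n)
    t0 <- 0
    for (t in seq_len(n)) {
      choice_onset[t] <- t0
      sim_onset[t] <- t0 + 8
      rating_onset[t] <- t0 + 16
      t0 <- t0 + 21 + stats::runif(1, 2, 5)
      if (stats::runif(1) < design$miss_rate) {
        missed[t] <- TRUE
        chosen[t] <- NA_character_
        valence[t] <- NA_character_
        pleasantness[t] <- NA_real_
        reward[t] <- NA_integer_
        state$prev_chosen <- NA_integer_
        state$prev_win <- NA
        next
      }
      hr <- idx_of[[schedule$hr_person[t]]]
      lr <- idx_of[[schedule$lr_person[t]]]
      p_hr <- agent_prob_hr(agent$model, par, state, hr, lr)
      pick_hr <- stats::runif(1) < p_hr
      ch <- if (pick_hr) hr else lr
      p_pleasant <- if (pick_hr) design$p_pleasant_hr else design$p_pleasant_lr
      pleasant <- stats::runif(1) < p_pleasant
      pl <- if (pleasant) {
        rtrunc_norm(1, pleasant_mean, pleasant_sd, -1, 1)
      } else {
        rtrunc_norm(1, unpleasant_mean, unpleasant_sd, -1, 1)
      }
      chosen[t] <- names(idx_of)[ch]
      valence[t] <- if (pleasant) "pleasant" else "neutral_unpleasant"
      pleasantness[t] <- pl
      reward[t] <- as.integer(pl > 0)
      state <- agent_update(agent$model, par, state, ch, reward[t])
    }

    trials <- tibble::tibble(
      t = seq_len(n), block = schedule$block,
      hr_person = schedule$hr_person, lr_person = schedule$lr_person,
      chosen = chosen, missed = missed, valence = valence,
      pleasantness = pleasantness, reward = reward,
      side_of_hr = schedule$side_of_hr,
      choice_onset = choice_onset, sim_onset = sim_onset,
      rating_onset = rating_onset
    )
    bandit_session(subject_id, persons, trials, design)
  })
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 49).
#' @param design A [design_spec()].
#' @param agent_model Generating model name (default `"RW"`).
#' @param param_dists Named list of `c(lower, upper)` uniform sampling
#'   ranges, one per agent parameter; defaults to
#'   [default_param_dists()] for `agent_model`. A degenerate range fixes
#'   the parameter.
#' @param liking_effect Planted liking update of HR persons per unit of
#'   acquired preference above chance: post-task HR liking = pre +
#'   `liking_effect * (p(HR) - 0.5)` + noise (default 0.3 on the \[0,1\]
#'   liking scale).
#' @param liking_noise_sd SD of the per-person rating noise added to every
#'   post-task liking rating (default 0.04).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 49, design = design_spec(),
                        agent_model = "RW", param_dists = NULL,
                        liking_effect = 0.3, liking_noise_sd = 0.04,
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  agent_model <- match.arg(agent_model, model_names())
  if (is.null(param_dists)) param_dists <- default_param_dists(agent_model)
  if (!setequal(names(param_dists), model_param_names(agent_model))) {
    stop("param_dists must cover exactly the agent model's parameters",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), design = design,
         agent_model = agent_model, param_dists = param_dists,
         liking_effect = liking_effect, liking_noise_sd = liking_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default parameter sampling ranges
#'
#' Uniform ranges used when simulating agents: learning rates, lapse and
#' bias on \[0.1, 0.9\] and inverse temperatures on \[1, 10\], keeping
#' simulated agents away from the fitting bounds where recovery is
#' ill-posed.
#'
#' @inheritParams model_param_names
#' @return Named list of `c(lower, upper)` ranges.
#' @export
default_param_dists <- function(model) {
  pn <- model_param_names(model)
  out <- lapply(pn, function(p) {
    if (p %in% c("beta", "beta_c")) c(1, 10) else c(0.1, 0.9)
  })
  stats::setNames(out, pn)
}

draw_params <- function(model, param_dists) {
  vals <- lapply(param_dists, function(rng) stats::runif(1, rng[1], rng[2]))
  do.call(model_params, c(list(model = model), vals))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic cohort
#'
#' Simulates one session per subject with agent parameters drawn from the
#' spec's ranges, then fills in post-task liking ratings: HR persons gain
#' `liking_effect * (p(HR) - 0.5)` plus rating noise, LR and baseline
#' persons change by rating noise only. This plants an across-subject
#' correlation between the acquired preference p(HR) and the
#' baseline-corrected HR liking update, the structure the robust
#' correlation analysis is meant to detect.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `sessions` (named list of `bandit_session`),
#'   `persons` (cohort persons tibble with `subject_id`), and `subjects`
#'   (tibble of true agent parameters and realized `p_hr` per subject).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 4, seed = 7))
#' coh$subjects
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max, n + 1))
  ids <- sprintf("s%02d", seq_len(n))
  agents <- withr::with_seed(seeds[n + 1],
                             lapply(seq_len(n), function(i)
                               draw_params(spec$agent_model, spec$param_dists)))
  sessions <- vector("list", n)
  persons <- vector("list", n)
  p_hr <- numeric(n)
  for (i in seq_len(n)) {
    s <- generate_session(spec$design, agents[[i]], seed = seeds[i],
                          subject_id = ids[i])
    p_hr[i] <- prob_hr(s)
    pers <- withr::with_seed(seeds[i] %% 1000000L + 17L, {
      noise <- stats::rnorm(nrow(s$persons), 0, spec$liking_noise_sd)
      planted <- ifelse(s$persons$condition == "HR",
                        spec$liking_effect * (p_hr[i] - 0.5), 0)
      dplyr::mutate(s$persons,
                    liking_post = clamp01(liking_pre + planted + noise))
    })
    s$persons <- pers
    sessions[[i]] <- s
    persons[[i]] <- dplyr::mutate(pers, subject_id = ids[i], .before = 1)
  }
  names(sessions) <- ids
  subjects <- tibble::as_tibble(
    purrr::map_dfr(agents, ~ tibble::as_tibble(.x$params))
  )
  subjects <- dplyr::mutate(subjects, subject_id = ids, p_hr = p_hr,
                            .before = 1)
  list(sessions = sessions, persons = dplyr::bind_rows(persons),
       subjects = subjects)
}

# Activity patterns for the RSA ------------------------------------------

#' Specify synthetic person x run activity patterns
#'
#' @param n_voxels Number of voxels per pattern (default 60).
#' @param n_persons Number of persons (4: two HR, two LR).
#' @param n_runs Number of functional runs (default 4).
#' @param signal_sd SD of the person-specific pattern component shared
#'   across runs.
#' @param noise_sd SD of the independent run-specific noise.
#' @param seed Integer seed.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(n_voxels = 60, n_persons = 4, n_runs = 4,
                         signal_sd = 1, noise_sd = 1, seed = 1L) {
  if (n_voxels < 2) stop("n_voxels must be >= 2", call. = FALSE)
  if (n_persons != 4 || n_runs != 4) {
    stop("the person-representation design uses 4 persons x 4 runs",
         call. = FALSE)
  }
  structure(
    list(n_voxels = as.integer(n_voxels), n_persons = 4L, n_runs = 4L,
         signal_sd = signal_sd, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "pattern_spec"
  )
}

#' Generate labeled activity patterns
#'
#' Each person gets a fixed random voxel pattern (the person-specific
#' signal); the observed pattern in each run is that signal plus
#' independent noise, so patterns are person-consistent across runs up to
#' noise. Two persons are labeled HR, two LR.
#'
#' @param spec A [pattern_spec()].
#' @return A list with `patterns` (16 x n_voxels matrix, rows ordered
#'   person-within-run labels as in `labels`) and `labels` (tibble with
#'   `person_id`, `run`, `condition`).
#' @export
generate_patterns <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  withr::with_seed(spec$seed, {
    persons <- c("hr1", "hr2", "lr1", "lr2")
    conditions <- c("HR", "HR", "LR", "LR")
    labels <- tidyr::expand_grid(run = 1:4,
                                 tibble::tibble(person_id = persons,
                                                condition = conditions))
    signal <- matrix(stats::rnorm(4 * spec$n_voxels, 0, spec$signal_sd),
                     nrow = 4, dimnames = list(persons, NULL))
    patterns <- t(vapply(seq_len(nrow(labels)), function(i) {
      signal[labels$person_id[i], ] +
        stats::rnorm(spec$n_voxels, 0, spec$noise_sd)
    }, numeric(spec$n_voxels)))
    rownames(patterns) <- paste(labels$person_id, labels$run, sep = "_run")
    list(patterns = patterns, labels = labels[c("person_id", "run", "condition")])
  })
}

#' Pattern-set round trip as plain text
#'
#' The pattern matrix is written as a TSV of numbers (one row per
#' person-run pattern) with a sidecar label table (`person_id`, `run`,
#' `condition`).
#'
#' @param pattern_set List as returned by [generate_patterns()].
#' @param matrix_path,labels_path File paths.
#' @return `write_patterns()` returns `matrix_path` invisibly;
#'   `read_patterns()` the pattern-set list.
#' @export
write_patterns <- function(pattern_set, matrix_path, labels_path) {
  utils::write.table(pattern_set$patterns, matrix_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  readr::write_tsv(pattern_set$labels, labels_path)
  invisible(matrix_path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(matrix_path, labels_path) {
  patterns <- as.matrix(utils::read.table(matrix_path, sep = "\t"))
  dimnames(patterns) <- NULL
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE,
                            progress = FALSE)
  rownames(patterns) <- paste(labels$person_id, labels$run, sep = "_run")
  list(patterns = patterns, labels = labels)
}
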