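# Trial-wise regressors for model-based fMRI -----------------------------

#' Rescorla-Wagner latent trajectories over a session
#'
#' Forward pass of the RW model at fixed parameters: per valid trial, the
#' chosen person's value before the update (`q_chosen`), the prediction
#' error (`delta`), and the probability the model assigned to the made
#' choice (`p_choice`). Missed trials yield no rows and trigger no
#' updates. Internally this is the same forward pass as
#' [session_negloglik()], so the two can never disagree.
#'
#' @param session A `bandit_session`.
#' @param alpha Learning rate in \[0,1\].
#' @param beta Inverse temperature, non-negative.
#' @return A tibble with `t`, `q_chosen`, `delta`, `p_choice` for valid
#'   trials only.
#' @export
latent_trajectories <- function(session, alpha, beta) {
  params <- model_params("RW", alpha = alpha, beta = beta)
  lat <- session_negloglik(params, session)$latents
  lat[lat$valid, c("t", "q_chosen", "delta", "p_choice")]
}

#' Population-median model parameters
#'
#' Median of each fitted parameter across subjects for one model. Using
#' one set of median parameters for every subject's regressors avoids the
#' noise of unregularized per-subject estimates. Even subject counts take
#' the midpoint of the central pair (the `stats::median()` convention).
#'
#' @param fit_table Output of [fit_cohort()].
#' @param model Model name (default `"RW"`).
#' @return Named list of parameter medians.
#' @export
population_median_params <- function(fit_table, model = "RW") {
  model_name <- match.arg(model, model_names())
  rows <- dplyr::filter(fit_table, model == model_name)
  if (nrow(rows) == 0L) stop("no fits for this model", call. = FALSE)
  pn <- model_param_names(model_name)
  stats::setNames(lapply(pn, function(p) stats::median(rows[[p]])), pn)
}

#' Export a BIDS-style events table with parametric modulators
#'
#' One row per event: the 8-s simulation period of each valid trial
#' (modulated by the trial's prediction error), the choice presentation
#' (duration 0, modulated by the chosen person's value), the rating onset
#' (duration 0), and — when present — missed-trial onsets (duration 0).
#' Modulators are mean-centered within event type, the standard
#' parametric-modulation convention.
#'
#' @param session A `bandit_session` with onset columns.
#' @param trajectories Output of [latent_trajectories()] for the same
#'   session.
#' @return A tibble with columns `onset`, `duration`, `trial_type`,
#'   `modulation`, sorted by onset.
#' @export
export_events <- function(session, trajectories) {
  tr <- session$trials
  onset_cols <- c("choice_onset", "sim_onset", "rating_onset")
  if (any(!onset_cols %in% names(tr)) ||
      any(is.na(unlist(tr[onset_cols])))) {
    stop("session lacks event onsets", call. = FALSE)
  }
  valid <- tr[!tr$missed, ]
  if (!identical(trajectories$t, valid$t)) {
    stop("trajectories do not match the session's valid trials",
         call. = FALSE)
  }
  center <- function(x) x - mean(x)
  ev <- dplyr::bind_rows(
    tibble::tibble(onset = valid$sim_onset, duration = 8,
                   trial_type = "simulation",
                   modulation = center(trajectories$delta)),
    tibble::tibble(onset = valid$choice_onset, duration = 0,
                   trial_type = "choice",
                   modulation = center(trajectories$q_chosen)),
    tibble::tibble(onset = valid$rating_onset, duration = 0,
                   trial_type = "rating", modulation = NA_real_)
  )
  if (any(tr$missed)) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      onset = tr$choice_onset[tr$missed], duration = 0,
      trial_type = "missed", modulation = NA_real_
    ))
  }
  dplyr::arrange(ev, onset, trial_type)
}

#' Write an events table to TSV
#'
#' @param events Output of [export_events()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}
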