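# Session container and TSV round-trip -----------------------------------

#' Design of the imagined-reward bandit task
#'
#' @param n_trials Number of trials (default 96, divisible by `n_blocks`).
#' @param n_blocks Number of blocks/functional runs (default 4).
#' @param p_pleasant_hr Probability that a trial with a chosen high-reward
#'   (HR) person features a pleasant scenario (default 0.8).
#' @param p_pleasant_lr Same for low-reward (LR) persons (default 0.3).
#' @param miss_rate Probability that a trial is missed (default 0).
#' @param seed Integer seed stored with the design.
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' design_spec()
design_spec <- function(n_trials = 96, n_blocks = 4,
                        p_pleasant_hr = 0.8, p_pleasant_lr = 0.3,
                        miss_rate = 0, seed = 1L) {
  probs <- c(p_pleasant_hr, p_pleasant_lr, miss_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_trials < 1 || n_trials %% n_blocks != 0) {
    stop("n_trials must be a positive multiple of n_blocks", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), n_blocks = as.integer(n_blocks),
         p_pleasant_hr = p_pleasant_hr, p_pleasant_lr = p_pleasant_lr,
         miss_rate = miss_rate, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Assemble a session object
#'
#' A session bundles one subject's ordered trial records with the persons
#' table and the design. Usually produced by [generate_session()] or
#' [read_session_tsv()]; exposed for constructing fixtures.
#'
#' @param subject_id Subject identifier.
#' @param persons Tibble with columns `person_id`, `condition` (one of
#'   `"HR"`, `"LR"`, `"BASELINE"`), `liking_pre`, `liking_post`,
#'   `familiarity_pre`, `familiarity_post` (ratings in \[0,1\]).
#' @param trials Tibble of trial records ordered by `t` with columns
#'   `t`, `block`, `hr_person`, `lr_person`, `chosen`, `missed`, `valence`,
#'   `pleasantness`, `reward`, `side_of_hr`, `choice_onset`, `sim_onset`,
#'   `rating_onset`.
#' @param design A [design_spec()].
#' @return An object of class `bandit_session`.
#' @export
bandit_session <- function(subject_id, persons, trials, design) {
  stopifnot(inherits(design, "design_spec"))
  persons <- tibble::as_tibble(persons)
  trials <- tibble::as_tibble(trials)
  if (!all(persons$condition %in% c("HR", "LR", "BASELINE"))) {
    stop("person conditions must be HR, LR or BASELINE", call. = FALSE)
  }
  rate_cols <- intersect(
    c("liking_pre", "liking_post", "familiarity_pre", "familiarity_post"),
    names(persons)
  )
  for (col in rate_cols) {
    v <- persons[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("'%s' ratings must lie in [0, 1]", col), call. = FALSE)
    }
  }
  if (nrow(trials) != design$n_trials) {
    stop("trial count does not match design$n_trials", call. = FALSE)
  }
  if (is.unsorted(trials$t, strictly = TRUE)) {
    stop("trials must be strictly ordered by t", call. = FALSE)
  }
  ok <- trials$missed | (trials$chosen == trials$hr_person |
                           trials$chosen == trials$lr_person)
  if (!all(ok)) {
    stop("chosen person must be one of the offered pair", call. = FALSE)
  }
  if (any(!trials$missed & is.na(trials$reward)) ||
      any(trials$missed & !is.na(trials$reward))) {
    stop("reward must be defined exactly on non-missed trials", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, persons = persons, trials = trials,
         design = design),
    class = "bandit_session"
  )
}

#' @export
print.bandit_session <- function(x, ...) {
  cat(sprintf(
    "<bandit_session> subject %s: %d trials in %d blocks, %d missed\n",
    x$subject_id, nrow(x$trials), x$design$n_blocks, sum(x$trials$missed)
  ))
  invisible(x)
}

SESSION_TSV_COLS <- c(
  "subject_id", "t", "block", "hr_person", "lr_person", "chosen", "missed",
  "valence", "pleasantness", "reward", "side_of_hr",
  "choice_onset", "sim_onset", "rating_onset"
)

#' Write sessions to a trial-wise TSV
#'
#' One row per trial; missed trials carry `chosen = "MISSED"` and empty
#' valence/pleasantness/reward fields.
#'
#' @param sessions A `bandit_session` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_tsv <- function(sessions, path) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  rows <- purrr::map_dfr(sessions, function(s) {
    dplyr::mutate(
      s$trials,
      subject_id = s$subject_id,
      chosen = dplyr::if_else(missed, "MISSED", chosen),
      missed = as.integer(missed)
    )
  })
  readr::write_tsv(rows[SESSION_TSV_COLS], path)
  invisible(path)
}

#' Read sessions back from a trial-wise TSV
#'
#' @param path Path written by [write_session_tsv()].
#' @param persons Persons table covering all subjects in the file (with a
#'   `subject_id` column when it holds several subjects), e.g. from
#'   [read_persons_tsv()].
#' @param design A [design_spec()] describing the sessions.
#' @return A named list of `bandit_session` objects, one per subject.
#' @export
read_session_tsv <- function(path, persons, design) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(SESSION_TSV_COLS, names(raw))
  if (length(missing)) {
    stop("session TSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  persons <- tibble::as_tibble(persons)
  by_subject <- split(raw, raw$subject_id)
  sessions <- lapply(by_subject, function(tr) {
    sid <- tr$subject_id[1]
    pers <- if ("subject_id" %in% names(persons)) {
      dplyr::select(dplyr::filter(persons, subject_id == sid), -subject_id)
    } else {
      persons
    }
    trials <- dplyr::mutate(
      dplyr::select(tr, -subject_id),
      missed = missed == 1L,
      chosen = dplyr::if_else(missed, NA_character_, chosen)
    )
    bandit_session(sid, pers, trials, design)
  })
  sessions[order(names(sessions))]
}

PERSONS_TSV_COLS <- c(
  "person_id", "condition", "liking_pre", "liking_post",
  "familiarity_pre", "familiarity_post"
)

#' Persons-table TSV round trip
#'
#' @param persons Persons tibble (optionally with a `subject_id` column for
#'   cohort tables).
#' @param path File path.
#' @return `write_persons_tsv()` returns `path` invisibly;
#'   `read_persons_tsv()` the tibble.
#' @export
write_persons_tsv <- function(persons, path) {
  cols <- c(intersect("subject_id", names(persons)), PERSONS_TSV_COLS)
  readr::write_tsv(tibble::as_tibble(persons)[cols], path)
  invisible(path)
}

#' @rdname write_persons_tsv
#' @export
read_persons_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
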