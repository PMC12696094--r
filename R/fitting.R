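# Maximum-likelihood fitting and BIC -------------------------------------

#' Bayesian Information Criterion
#'
#' `BIC = ln(n) * df + 2 * NegLL`, where `n` is the number of data points
#' (non-missed trials) and `df` the number of free parameters. Lower is
#' better.
#'
#' @param negll Minimized negative log-likelihood.
#' @param n Number of data points, at least 1.
#' @param df Number of free parameters, non-negative.
#' @return The BIC value.
#' @export
#' @examples
#' bic(26.52, 96, 2)  # 62.17
bic <- function(negll, n, df) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(df < 0)) stop("df must be >= 0", call. = FALSE)
  log(n) * df + 2 * negll
}

# Latin-hypercube start points inside the bounds, kept off the boundary.
multistart_points <- function(bounds, n_starts) {
  k <- ncol(bounds)
  u <- lhs::randomLHS(n_starts, k)
  lo <- bounds["lower", ]; hi <- bounds["upper", ]
  margin <- 0.02 * (hi - lo)
  lo_m <- matrix(lo + margin, n_starts, k, byrow = TRUE)
  span <- matrix(hi - lo - 2 * margin, n_starts, k, byrow = TRUE)
  lo_m + u * span
}

fit_result_row <- function(subject_id, model, par, negll, n_valid,
                           n_starts, best_start, converged) {
  all_params <- unique(unlist(MODEL_PARAM_NAMES))
  vals <- stats::setNames(rep(NA_real_, length(all_params)), all_params)
  vals[model_param_names(model)] <- par
  tibble::tibble(
    subject_id = subject_id, model = model, !!!as.list(vals),
    negll = negll, n_valid = as.integer(n_valid),
    df = model_df(model),
    bic = bic(negll, n_valid, model_df(model)),
    n_starts = as.integer(n_starts), best_start = as.integer(best_start),
    converged = converged
  )
}

#' Fit one model to one subject's session
#'
#' Minimizes the session's negative log-likelihood by bounded L-BFGS-B
#' from `n_starts` Latin-hypercube initial points within the parameter
#' bounds, and returns the best start (ties broken by lowest start index).
#' The returned row also carries the BIC computed with `n` equal to the
#' subject's number of non-missed trials.
#'
#' @param model Model name, one of [model_names()].
#' @param session A `bandit_session`.
#' @param n_starts Number of random starts (default 10).
#' @param seed Integer seed for the start points.
#' @return A one-row tibble with `subject_id`, `model`, one column per
#'   parameter in the full model space (`NA` where not applicable),
#'   `negll`, `n_valid`, `df`, `bic`, `n_starts`, `best_start`,
#'   `converged`. If every start fails, the row is flagged
#'   `converged = FALSE` with `NA` estimates rather than dropped silently.
#' @export
#' @examples
#' s <- generate_session(design_spec(), model_params("RW", alpha = 0.4, beta = 5),
#'                       seed = 1)
#' fit_subject("RW", s, n_starts = 5, seed = 1)
fit_subject <- function(model, session, n_starts = 10, seed = 1L) {
  model <- match.arg(model, model_names())
  arr <- session_arrays(session)
  n_valid <- sum(arr$valid)
  if (n_valid < 1) stop("session has no valid trials", call. = FALSE)
  bounds <- model_bounds(model)
  obj <- function(par) negll_arrays(model, par, arr)
  starts <- withr::with_seed(as.integer(seed),
                             multistart_points(bounds, n_starts))
  best <- NULL
  best_start <- NA_integer_
  any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = bounds["lower", ], upper = bounds["upper", ]),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_start <- i
    }
  }
  if (!any_ok) {
    return(fit_result_row(session$subject_id, model,
                          rep(NA_real_, ncol(bounds)), NA_real_, n_valid,
                          n_starts, NA_integer_, FALSE))
  }
  # store the exact negll at the returned parameters
  negll <- obj(best$par)
  fit_result_row(session$subject_id, model, best$par, negll, n_valid,
                 n_starts, best_start, best$convergence == 0)
}

#' Fit several models to a cohort of sessions
#'
#' @param sessions A list of `bandit_session` objects.
#' @param models Character vector of model names (default: all five).
#' @param n_starts Random starts per fit (default 10).
#' @param seed Integer seed; per-fit seeds are derived deterministically.
#' @return A tibble with one row per subject x model (see [fit_subject()]).
#' @export
fit_cohort <- function(sessions, models = model_names(), n_starts = 10,
                       seed = 1L) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (length(sessions) < 1) stop("need at least one session", call. = FALSE)
  models <- match.arg(models, model_names(), several.ok = TRUE)
  fit_seeds <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(.Machine$integer.max, length(sessions) * length(models)),
           nrow = length(sessions))
  )
  purrr::map_dfr(seq_along(sessions), function(i) {
    purrr::map_dfr(seq_along(models), function(j) {
      fit_subject(models[j], sessions[[i]], n_starts = n_starts,
                  seed = fit_seeds[i, j])
    })
  })
}

#' Group-level fit summary
#'
#' Mean, standard error of the mean, and sum of the negative
#' log-likelihoods and BICs per model — the layout of a model-comparison
#' table.
#'
#' @param fit_table Output of [fit_cohort()].
#' @return A tibble with one row per model.
#' @export
fit_summary <- function(fit_table) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  fit_table |>
    dplyr::group_by(model) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      negll_mean = mean(negll), negll_sem = sem(negll),
      negll_sum = sum(negll),
      bic_mean = mean(bic), bic_sem = sem(bic), bic_sum = sum(bic),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(model, model_names()))
}

#' Write a fit table to TSV
#'
#' @param fit_table Output of [fit_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit_table, path) {
  readr::write_tsv(fit_table, path)
  invisible(path)
}
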