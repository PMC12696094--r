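# Fixed-effects and random-effects model selection -----------------------

#' Per-subject BIC differences relative to a reference model
#'
#' `delta_bic(subject, m) = BIC_ref(subject) - BIC_m(subject)`, so the
#' reference column is identically zero and negative values mean the
#' reference fits better.
#'
#' @param fit_table Output of [fit_cohort()] containing the reference model
#'   for every subject.
#' @param reference Reference model name (default `"RW"`).
#' @return A tibble with `subject_id`, `model`, `delta_bic`.
#' @export
delta_bic <- function(fit_table, reference = "RW") {
  reference <- match.arg(reference, model_names())
  ref <- dplyr::filter(fit_table, model == reference)
  if (!setequal(ref$subject_id, unique(fit_table$subject_id))) {
    stop("reference model missing for some subjects", call. = FALSE)
  }
  ref <- dplyr::select(ref, subject_id, bic_ref = bic)
  fit_table |>
    dplyr::select(subject_id, model, bic) |>
    dplyr::left_join(ref, by = "subject_id") |>
    dplyr::mutate(delta_bic = bic_ref - bic) |>
    dplyr::select(subject_id, model, delta_bic)
}

#' Number of subjects favoring each model
#'
#' Each subject contributes one count to the model with their minimal BIC;
#' exact ties go to the first tied model in canonical [model_names()]
#' order, so counts always sum to the number of subjects.
#'
#' @param fit_table Output of [fit_cohort()] with every model fitted for
#'   every subject.
#' @return A named integer vector over the models present, in canonical
#'   order.
#' @export
count_favoring <- function(fit_table) {
  models <- intersect(model_names(), unique(fit_table$model))
  per_model <- lapply(models, function(m) {
    dplyr::filter(fit_table, model == m) |>
      dplyr::arrange(subject_id) |>
      dplyr::pull(bic)
  })
  bics <- do.call(cbind, per_model)
  if (anyNA(bics) || length(unique(table(fit_table$model))) != 1L) {
    stop("every subject must have a BIC for every model", call. = FALSE)
  }
  winner <- apply(bics, 1, which.min)  # which.min takes the first tie
  counts <- tabulate(winner, nbins = length(models))
  stats::setNames(as.integer(counts), models)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects and
#' estimates the population frequencies of the models by variational
#' Bayes on a Dirichlet-multinomial model: subject-wise model
#' responsibilities are computed from the current Dirichlet digammas and
#' the subjects' log model evidences, Dirichlet counts are updated from
#' the responsibilities, and the scheme is iterated to convergence. The
#' exceedance probability — the posterior probability that a model is the
#' most frequent one in the population — is estimated by Monte Carlo over
#' Dirichlet draws.
#'
#' @param log_evidence Subjects x models matrix of log model evidences
#'   (finite; column names are taken as model names). For BIC-based
#'   selection use `-bic/2` (see [bms_from_fits()]).
#' @param prior_alpha Dirichlet prior mass per model (default 1).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol Convergence tolerance on the Dirichlet parameters
#'   (default 1e-6).
#' @return An object of class `bms_result`: list with `dirichlet_alpha`,
#'   `expected_frequency`, `exceedance_prob` (all named per model),
#'   `responsibilities` (subjects x models), `n_samples`, `seed`.
#' @export
#' @examples
#' lev <- matrix(c(0, -5), 10, 2, byrow = TRUE,
#'               dimnames = list(NULL, c("A", "B")))
#' bms(lev, n_samples = 1e5, seed = 1)
bms <- function(log_evidence, prior_alpha = 1, n_samples = 1e6, seed = 1L,
                tol = 1e-6) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence))) {
    stop("log evidences must be finite", call. = FALSE)
  }
  k <- ncol(log_evidence)
  n <- nrow(log_evidence)
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("m", seq_len(k))
  alpha0 <- rep(prior_alpha, k)
  alpha <- alpha0
  g <- matrix(1 / k, n, k)
  if (n > 0) {
    repeat {
      lg <- digamma(alpha) - digamma(sum(alpha))
      u <- sweep(log_evidence, 2, lg, `+`)
      u <- u - apply(u, 1, max)
      g <- exp(u)
      g <- g / rowSums(g)
      alpha_new <- alpha0 + colSums(g)
      if (max(abs(alpha_new - alpha)) < tol) {
        alpha <- alpha_new
        break
      }
      alpha <- alpha_new
    }
  }
  ef <- alpha / sum(alpha)
  xp <- withr::with_seed(as.integer(seed), {
    draws <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws, ties.method = "first"), nbins = k) / n_samples
  })
  structure(
    list(dirichlet_alpha = stats::setNames(alpha, models),
         expected_frequency = stats::setNames(ef, models),
         exceedance_prob = stats::setNames(xp, models),
         responsibilities = `colnames<-`(g, models),
         n_samples = n_samples, seed = as.integer(seed)),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  print(tibble::tibble(
    model = names(x$expected_frequency),
    dirichlet_alpha = unname(x$dirichlet_alpha),
    expected_frequency = unname(x$expected_frequency),
    exceedance_prob = unname(x$exceedance_prob)
  ))
  invisible(x)
}

#' BMS from a fit table
#'
#' Convenience wrapper: approximates each subject's log model evidence as
#' `-BIC/2` (the standard Laplace-style surrogate) and runs [bms()].
#'
#' @inheritParams bms
#' @param fit_table Output of [fit_cohort()] with all models per subject.
#' @return A `bms_result`.
#' @export
bms_from_fits <- function(fit_table, prior_alpha = 1, n_samples = 1e6,
                          seed = 1L) {
  wide <- fit_table |>
    dplyr::select(subject_id, model, bic) |>
    tidyr::pivot_wider(names_from = model, values_from = bic)
  models <- intersect(model_names(), names(wide))
  lev <- -as.matrix(wide[models]) / 2
  bms(lev, prior_alpha = prior_alpha, n_samples = n_samples, seed = seed)
}

#' Write a BMS report to TSV
#'
#' @param result A `bms_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bms_tsv <- function(result, path) {
  readr::write_tsv(tibble::tibble(
    model = names(result$expected_frequency),
    dirichlet_alpha = unname(result$dirichlet_alpha),
    expected_frequency = unname(result$expected_frequency),
    exceedance_prob = unname(result$exceedance_prob)
  ), path)
  invisible(path)
}
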