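# Parameter- and model-recovery studies ----------------------------------

#' Parameter recovery for one model
#'
#' Repeatedly draws generating parameters from `param_dists`, simulates a
#' session with that agent, refits the same model, and records true and
#' recovered values side by side. Failed fits are kept as flagged rows.
#'
#' @param model Model name.
#' @param n_sims Number of simulations (default 100, at least 2).
#' @param param_dists Named list of `c(lower, upper)` sampling ranges
#'   (default [default_param_dists()]).
#' @param design A [design_spec()].
#' @param n_starts Random starts per fit (default 5; these bounded 1- to
#'   4-parameter problems reproduce the denser-start optimum well within
#'   the optimizer tolerance).
#' @param seed Integer seed.
#' @return A tibble with one row per simulation: `sim`, `true_<param>` and
#'   `fit_<param>` columns, `negll`, `converged`.
#' @export
#' @examples
#' parameter_recovery("NULL", n_sims = 5, seed = 1)
parameter_recovery <- function(model, n_sims = 100, param_dists = NULL,
                               design = design_spec(), n_starts = 5,
                               seed = 1L) {
  model <- match.arg(model, model_names())
  if (n_sims < 2) stop("n_sims must be >= 2", call. = FALSE)
  if (is.null(param_dists)) param_dists <- default_param_dists(model)
  pn <- model_param_names(model)
  seeds <- withr::with_seed(as.integer(seed),
                            matrix(sample.int(.Machine$integer.max,
                                              3 * n_sims), ncol = 3))
  purrr::map_dfr(seq_len(n_sims), function(i) {
    true <- withr::with_seed(seeds[i, 1], draw_params(model, param_dists))
    session <- generate_session(design, true, seed = seeds[i, 2],
                                subject_id = sprintf("sim%03d", i))
    fit <- fit_subject(model, session, n_starts = n_starts,
                       seed = seeds[i, 3])
    out <- tibble::tibble(sim = i)
    for (p in pn) out[[paste0("true_", p)]] <- true$params[[p]]
    for (p in pn) out[[paste0("fit_", p)]] <- fit[[p]]
    out$negll <- fit$negll
    out$converged <- fit$converged
    out
  })
}

#' Per-parameter recovery correlations
#'
#' @param recovery_table Output of [parameter_recovery()].
#' @return A tibble with `param`, `pearson`, `spearman` across converged
#'   simulations.
#' @export
recovery_correlations <- function(recovery_table) {
  ok <- recovery_table$converged & !is.na(recovery_table$negll)
  tab <- recovery_table[ok, ]
  params <- sub("^true_", "", grep("^true_", names(tab), value = TRUE))
  purrr::map_dfr(params, function(p) {
    x <- tab[[paste0("true_", p)]]
    y <- tab[[paste0("fit_", p)]]
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
    tibble::tibble(
      param = p,
      pearson = if (degenerate) NA_real_ else stats::cor(x, y),
      spearman = if (degenerate) NA_real_ else
        stats::cor(x, y, method = "spearman")
    )
  })
}

#' Model recovery confusion matrix
#'
#' For each generating model, simulates sessions from parameters drawn
#' from that model's ranges, fits all candidate models, and identifies the
#' best-fitting model by minimal BIC (ties broken in canonical model
#' order). Cell (g, f) is the fraction of simulations generated by model g
#' that were best fit by model f; rows sum to 1.
#'
#' @param models Character vector of models to simulate from and fit
#'   (default: all five).
#' @param n_sims_per_model Simulations per generating model (default 50).
#' @param param_dists Optional named list (per model) of sampling-range
#'   lists; defaults to [default_param_dists()] per model.
#' @param design A [design_spec()].
#' @param n_starts Random starts per fit (default 5).
#' @param seed Integer seed.
#' @return A row-normalized matrix (generating model x best-fit model).
#' @export
model_recovery <- function(models = model_names(), n_sims_per_model = 50,
                           param_dists = NULL, design = design_spec(),
                           n_starts = 5, seed = 1L) {
  models <- match.arg(models, model_names(), several.ok = TRUE)
  if (is.null(param_dists)) {
    param_dists <- stats::setNames(lapply(models, default_param_dists), models)
  }
  confusion <- matrix(0, length(models), length(models),
                      dimnames = list(generator = models, best_fit = models))
  seeds <- withr::with_seed(
    as.integer(seed),
    array(sample.int(.Machine$integer.max,
                     length(models) * n_sims_per_model * 2),
          dim = c(length(models), n_sims_per_model, 2))
  )
  for (g in seq_along(models)) {
    for (i in seq_len(n_sims_per_model)) {
      true <- withr::with_seed(seeds[g, i, 1],
                               draw_params(models[g], param_dists[[models[g]]]))
      session <- generate_session(design, true, seed = seeds[g, i, 2],
                                  subject_id = sprintf("%s%03d", models[g], i))
      fits <- fit_cohort(list(session), models = models,
                         n_starts = n_starts, seed = seeds[g, i, 1])
      best <- fits$model[which.min(fits$bic)]  # fits are in canonical order
      confusion[g, best] <- confusion[g, best] + 1
    }
  }
  confusion / n_sims_per_model
}
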