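# Model registry ---------------------------------------------------------

# Canonical model order; used for tie-breaking in model counts and recovery.
MODEL_NAMES <- c("RW", "CK", "RWCK", "WSLS", "NULL")

# Free parameters per model. The degrees of freedom are pinned down by the
# BIC identity BIC = ln(n) df + 2 NegLL applied to the published group
# means at n = 96 trials: RW = 2, CK = 2, RWCK = 4, WSLS = 1, NULL = 1.
MODEL_PARAM_NAMES <- list(
  RW   = c("alpha", "beta"),
  CK   = c("alpha_c", "beta_c"),
  RWCK = c("alpha", "beta", "alpha_c", "beta_c"),
  WSLS = "epsilon",
  `NULL` = "bias"
)

# Box bounds for every parameter. Learning rates, the WSLS lapse and the
# null bias live on [0,1] by definition; inverse temperatures are capped at
# 20 because with values bounded in [0,1] the softmax is effectively
# deterministic well below that.
PARAM_BOUNDS <- list(
  alpha   = c(0, 1),
  beta    = c(0, 20),
  alpha_c = c(0, 1),
  beta_c  = c(0, 20),
  epsilon = c(0, 1),
  bias    = c(0, 1)
)

# Probabilities are floored before taking logs so that a deterministic
# model (e.g. WSLS with epsilon = 0) assigns a large but finite penalty to
# a choice it rules out.
PROB_FLOOR <- 1e-12

#' Names of the candidate models
#'
#' The model space contains five models of choice behavior in the imagined-
#' reward bandit task: `"RW"` (Rescorla-Wagner value learning), `"CK"`
#' (choice kernel, reward-blind perseveration), `"RWCK"` (additive
#' combination of both), `"WSLS"` (noisy win-stay-lose-shift on person
#' identity) and `"NULL"` (a fixed choice bias, no learning).
#'
#' @return Character vector of model names in canonical order.
#' @export
#' @examples
#' model_names()
model_names <- function() MODEL_NAMES

#' Free parameters and degrees of freedom of a model
#'
#' @param model Model name, one of [model_names()].
#' @return `model_param_names()` returns the parameter names; `model_df()`
#'   their count, i.e. the degrees of freedom entering the BIC.
#' @export
#' @examples
#' model_param_names("RWCK")
#' model_df("RW")
model_param_names <- function(model) {
  model <- match.arg(model, MODEL_NAMES)
  MODEL_PARAM_NAMES[[model]]
}

#' @rdname model_param_names
#' @export
model_df <- function(model) length(model_param_names(model))

#' Bounds of a model's parameters
#'
#' @inheritParams model_param_names
#' @return A two-row matrix with rows `lower` and `upper`, one column per
#'   parameter.
#' @export
model_bounds <- function(model) {
  pn <- model_param_names(model)
  b <- vapply(pn, function(p) PARAM_BOUNDS[[p]], numeric(2))
  rownames(b) <- c("lower", "upper")
  b
}

#' Construct and validate a parameter set
#'
#' @param model Model name, one of [model_names()].
#' @param ... Named parameter values, e.g. `alpha = 0.4, beta = 5` for the
#'   RW model. All of the model's parameters must be supplied and lie
#'   within [model_bounds()].
#' @return An object of class `model_params`: a named list with elements
#'   `model` and `params`.
#' @export
#' @examples
#' model_params("RW", alpha = 0.4, beta = 5)
model_params <- function(model, ...) {
  model <- match.arg(model, MODEL_NAMES)
  values <- list(...)
  pn <- model_param_names(model)
  if (!setequal(names(values), pn)) {
    stop(sprintf(
      "model '%s' requires exactly the parameters: %s",
      model, paste(pn, collapse = ", ")
    ), call. = FALSE)
  }
  values <- values[pn]
  for (p in pn) {
    v <- values[[p]]
    b <- PARAM_BOUNDS[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < b[1] || v > b[2]) {
      stop(sprintf("parameter '%s' must be a finite scalar in [%g, %g]",
                   p, b[1], b[2]), call. = FALSE)
    }
  }
  structure(list(model = model, params = lapply(values, as.numeric)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", x$model, ": ",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Elementary update rules -------------------------------------------------

#' Rescorla-Wagner value update
#'
#' Error-driven update of the chosen option's expected value:
#' `delta = reward - Q` and `Q' = Q + alpha * delta`. With binary rewards
#' and `alpha` in \[0,1\], values initialized in \[0,1\] remain there.
#'
#' @param q Current value of the chosen option.
#' @param reward Binarized reward, 0 or 1.
#' @param alpha Learning rate in \[0,1\].
#' @return A list with elements `q_new` and `delta` (the prediction error).
#' @export
#' @examples
#' rw_update(0.5, 1, 0.5)  # q_new = 0.75, delta = 0.5
rw_update <- function(q, reward, alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (!reward %in% c(0, 1)) stop("reward must be 0 or 1", call. = FALSE)
  delta <- reward - q
  list(q_new = q + alpha * delta, delta = delta)
}

#' Softmax choice probabilities for an offered pair
#'
#' Converts the two offered options' values into choice probabilities with
#' inverse temperature `beta`. Computed with max-subtraction so large
#' `beta * Q` cannot overflow.
#'
#' @param q Numeric vector of length 2, the values of the offered options.
#' @param beta Inverse temperature, finite and non-negative; 0 is random
#'   choice, large values approach deterministic choice of the higher value.
#' @return Numeric vector of length 2 of probabilities summing to 1.
#' @export
#' @examples
#' softmax_pair(c(1, 0), log(3))  # c(0.75, 0.25)
softmax_pair <- function(q, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("beta must be a finite non-negative scalar", call. = FALSE)
  }
  if (length(q) != 2L) stop("q must have length 2", call. = FALSE)
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Choice-kernel update
#'
#' The choice kernel tracks a running average of past choices: the chosen
#' person's kernel moves toward 1, every other person's toward 0, each at
#' rate `alpha_c`. Kernels initialized in \[0,1\] remain there.
#'
#' @param ck Named numeric vector of kernel values, one per person.
#' @param chosen Name of the chosen person (must be a name of `ck`).
#' @param alpha_c Kernel learning rate in \[0,1\].
#' @return Updated named numeric vector.
#' @export
#' @examples
#' ck_update(c(A = 0.2, B = 0.8), "B", 0.5)  # A: 0.1, B: 0.9
ck_update <- function(ck, chosen, alpha_c) {
  if (!is.numeric(alpha_c) || alpha_c < 0 || alpha_c > 1) {
    stop("alpha_c must lie in [0, 1]", call. = FALSE)
  }
  if (!chosen %in% names(ck)) {
    stop(sprintf("unknown person '%s'", chosen), call. = FALSE)
  }
  target <- as.numeric(names(ck) == chosen)
  ck + alpha_c * (target - ck)
}

#' Noisy win-stay-lose-shift choice probability
#'
#' After a rewarded trial the previous choice is repeated with probability
#' `1 - epsilon/2`; after a non-rewarded trial it is avoided with the same
#' probability. With no usable history (first trial, after a missed trial,
#' or when the previously chosen person is not on offer) both options get
#' probability 0.5.
#'
#' @param prev_outcome One of `"win"`, `"lose"`, `"none"`.
#' @param is_prev_choice Logical; is the candidate option the previously
#'   chosen person?
#' @param epsilon Lapse parameter in \[0,1\]; 0 is deterministic WSLS, 1 is
#'   fully random.
#' @return Probability of choosing the candidate option.
#' @export
#' @examples
#' wsls_prob("win", TRUE, 0.2)  # 0.9
wsls_prob <- function(prev_outcome, is_prev_choice, epsilon) {
  prev_outcome <- match.arg(prev_outcome, c("win", "lose", "none"))
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  if (prev_outcome == "none") return(0.5)
  p_stay <- if (prev_outcome == "win") 1 - epsilon / 2 else epsilon / 2
  if (is_prev_choice) p_stay else 1 - p_stay
}

#' Null-model choice probability
#'
#' A fixed, history-independent bias toward the high-reward person.
#'
#' @param is_hr Logical; is the candidate the HR option?
#' @param b Bias parameter in \[0,1\], the probability of choosing HR.
#' @return `b` for the HR option, `1 - b` otherwise.
#' @export
#' @examples
#' null_prob(FALSE, 0.8)  # 0.2
null_prob <- function(is_hr, b) {
  if (!is.numeric(b) || b < 0 || b > 1) stop("b must lie in [0, 1]", call. = FALSE)
  if (is_hr) b else 1 - b
}

# Session likelihood ------------------------------------------------------

# Flatten a session into integer/numeric vectors for fast likelihood loops.
# Person indices run over the choosable (HR + LR) persons in the order they
# appear in session$persons. Sufficient statistics of the WSLS and null
# likelihoods depend only on the data, so they are precomputed here once.
session_arrays <- function(session) {
  stopifnot(inherits(session, "bandit_session"))
  trials <- session$trials
  if (nrow(trials) == 0L) stop("session has no trials", call. = FALSE)
  choosable <- session$persons$person_id[session$persons$condition != "BASELINE"]
  hr <- match(trials$hr_person, choosable)
  lr <- match(trials$lr_person, choosable)
  chosen <- match(trials$chosen, choosable)
  valid <- !trials$missed
  if (any(is.na(hr)) || any(is.na(lr)) || any(is.na(chosen[valid]))) {
    stop("trials reference persons absent from the persons table", call. = FALSE)
  }
  unchosen <- ifelse(chosen == hr, lr, hr)
  # WSLS trial categories: no usable history / consistent with WSLS
  # (stay after win, shift after loss) / inconsistent.
  n_none <- n_consistent <- n_inconsistent <- 0L
  prev_chosen <- NA_integer_
  prev_win <- NA
  for (t in seq_len(nrow(trials))) {
    if (!valid[t]) {
      prev_chosen <- NA_integer_
      prev_win <- NA
      next
    }
    ch <- chosen[t]
    if (is.na(prev_chosen) || (prev_chosen != hr[t] && prev_chosen != lr[t])) {
      n_none <- n_none + 1L
    } else {
      stayed <- ch == prev_chosen
      if (stayed == prev_win) n_consistent <- n_consistent + 1L
      else n_inconsistent <- n_inconsistent + 1L
    }
    prev_chosen <- ch
    prev_win <- trials$reward[t] == 1
  }
  list(
    n = nrow(trials),
    n_persons = length(choosable),
    person_ids = choosable,
    hr = hr, lr = lr,
    chosen = chosen, unchosen = unchosen,
    reward = trials$reward,
    valid = valid, valid_idx = which(valid),
    n_hr_chosen = sum(chosen[valid] == hr[valid]),
    n_valid = sum(valid),
    wsls_counts = c(none = n_none, consistent = n_consistent,
                    inconsistent = n_inconsistent)
  )
}

log_floor <- function(p) log(pmax(p, PROB_FLOOR))

# Tight minimized-quantity paths, one per model.
negll_rw_fast <- function(par, arr) {
  a <- par[1]; b <- par[2]
  Q <- rep(0.5, arr$n_persons)
  ch <- arr$chosen; un <- arr$unchosen; r <- arr$reward
  nll <- 0
  for (t in arr$valid_idx) {
    k <- ch[t]
    p <- 1 / (1 + exp(-b * (Q[k] - Q[un[t]])))
    if (p < PROB_FLOOR) p <- PROB_FLOOR
    nll <- nll - log(p)
    Q[k] <- Q[k] + a * (r[t] - Q[k])
  }
  nll
}

negll_ck_fast <- function(par, arr) {
  ac <- par[1]; bc <- par[2]
  CK <- rep(0, arr$n_persons)
  ch <- arr$chosen; un <- arr$unchosen
  nll <- 0
  for (t in arr$valid_idx) {
    k <- ch[t]
    p <- 1 / (1 + exp(-bc * (CK[k] - CK[un[t]])))
    if (p < PROB_FLOOR) p <- PROB_FLOOR
    nll <- nll - log(p)
    CK <- CK * (1 - ac)
    CK[k] <- CK[k] + ac
  }
  nll
}

negll_rwck_fast <- function(par, arr) {
  a <- par[1]; b <- par[2]; ac <- par[3]; bc <- par[4]
  Q <- rep(0.5, arr$n_persons)
  CK <- rep(0, arr$n_persons)
  ch <- arr$chosen; un <- arr$unchosen; r <- arr$reward
  nll <- 0
  for (t in arr$valid_idx) {
    k <- ch[t]; u <- un[t]
    p <- 1 / (1 + exp(-(b * (Q[k] - Q[u]) + bc * (CK[k] - CK[u]))))
    if (p < PROB_FLOOR) p <- PROB_FLOOR
    nll <- nll - log(p)
    Q[k] <- Q[k] + a * (r[t] - Q[k])
    CK <- CK * (1 - ac)
    CK[k] <- CK[k] + ac
  }
  nll
}

negll_wsls_fast <- function(par, arr) {
  cnt <- arr$wsls_counts
  -(cnt[["none"]] * log(0.5) +
      cnt[["consistent"]] * log_floor(1 - par[1] / 2) +
      cnt[["inconsistent"]] * log_floor(par[1] / 2))
}

negll_null_fast <- function(par, arr) {
  n_hr <- arr$n_hr_chosen
  -(n_hr * log_floor(par[1]) +
      (arr$n_valid - n_hr) * log_floor(1 - par[1]))
}

negll_fast_fn <- function(model) {
  switch(model,
         RW = negll_rw_fast, CK = negll_ck_fast, RWCK = negll_rwck_fast,
         WSLS = negll_wsls_fast, `NULL` = negll_null_fast)
}

# Tight per-model negative log-likelihood loops over a session_arrays()
# structure. `par` is the numeric parameter vector in model_param_names()
# order. When `latents` is TRUE, per-trial Q_chosen, delta and p_choice are
# recorded (NA on missed trials).
negll_arrays <- function(model, par, arr, latents = FALSE) {
  if (!latents) return(negll_fast_fn(model)(par, arr))
  n <- arr$n
  q_chosen <- delta <- p_choice <- if (latents) rep(NA_real_, n) else NULL
  nll <- 0
  Q <- rep(0.5, arr$n_persons)   # values start neutral
  CK <- rep(0, arr$n_persons)    # kernels start empty
  prev_chosen <- NA_integer_
  prev_win <- NA
  for (t in seq_len(n)) {
    if (!arr$valid[t]) {
      # missed trial: no likelihood term, no update; WSLS history resets
      prev_chosen <- NA_integer_
      prev_win <- NA
      next
    }
    hr <- arr$hr[t]; lr <- arr$lr[t]
    ch <- arr$chosen[t]
    un <- if (ch == hr) lr else hr
    r <- arr$reward[t]
    if (model == "RW" || model == "RWCK" || model == "CK") {
      dv <- switch(model,
        RW   = par[2] * (Q[ch] - Q[un]),
        CK   = par[2] * (CK[ch] - CK[un]),
        RWCK = par[2] * (Q[ch] - Q[un]) + par[4] * (CK[ch] - CK[un])
      )
      # logistic form of the pairwise softmax; dv is bounded so no overflow
      p <- 1 / (1 + exp(-dv))
    } else if (model == "WSLS") {
      if (is.na(prev_chosen) || (prev_chosen != ch && prev_chosen != un)) {
        p <- 0.5
      } else {
        p_stay <- if (prev_win) 1 - par[1] / 2 else par[1] / 2
        p <- if (ch == prev_chosen) p_stay else 1 - p_stay
      }
    } else { # NULL
      p <- if (ch == hr) par[1] else 1 - par[1]
    }
    p <- max(p, PROB_FLOOR)
    nll <- nll - log(p)
    if (latents) {
      q_chosen[t] <- Q[ch]
      delta[t] <- r - Q[ch]
      p_choice[t] <- p
    }
    # state updates
    if (model == "RW" || model == "RWCK") {
      Q[ch] <- Q[ch] + par[1] * (r - Q[ch])
    }
    if (model == "CK" || model == "RWCK") {
      ac <- if (model == "CK") par[1] else par[3]
      CK <- CK + ac * (as.numeric(seq_along(CK) == ch) - CK)
    }
    prev_chosen <- ch
    prev_win <- r == 1
  }
  if (latents) {
    list(negll = nll,
         latents = tibble::tibble(
           t = seq_len(n), valid = arr$valid,
           q_chosen = q_chosen, delta = delta, p_choice = p_choice
         ))
  } else {
    nll
  }
}

#' Negative log-likelihood of a session under a model
#'
#' Sums `-log p(made choice)` over all non-missed trials. Missed trials
#' contribute no likelihood term and trigger no value or kernel update (and
#' reset the WSLS history). Values start at 0.5 for all persons (persons are
#' approximately neutral before the task), choice kernels at 0. The RWCK
#' model combines `beta * Q + beta_c * CK` inside a single softmax.
#'
#' @param params A [model_params()] object.
#' @param session A `bandit_session` (see [generate_session()] or
#'   [read_session_tsv()]).
#' @return A list with `negll` (the minimized quantity) and `latents`, a
#'   tibble of per-trial `q_chosen`, `delta` (prediction error) and
#'   `p_choice` (probability assigned to the made choice); latent columns
#'   are `NA` on missed trials.
#' @export
session_negloglik <- function(params, session) {
  stopifnot(inherits(params, "model_params"))
  arr <- session_arrays(session)
  negll_arrays(params$model, unlist(params$params), arr, latents = TRUE)
}
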