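# Behavioral statistics ---------------------------------------------------

#' Acquired preference: probability of choosing the HR person
#'
#' Fraction of valid (non-missed) trials on which the chosen person was
#' the high-reward option.
#'
#' @param session A `bandit_session`.
#' @return A probability in \[0,1\].
#' @export
prob_hr <- function(session) {
  stopifnot(inherits(session, "bandit_session"))
  tr <- session$trials[!session$trials$missed, ]
  if (nrow(tr) == 0L) stop("session has no valid trials", call. = FALSE)
  mean(tr$chosen == tr$hr_person)
}

#' Wilcoxon signed-rank test with normal approximation and effect size
#'
#' One-sample signed-rank test of `values` against `mu`. Zero differences
#' are dropped; `W` is the sum of the ranks of the positive differences of
#' `|value - mu|` (ties get average ranks); the z statistic uses the
#' normal approximation with continuity correction and the tie correction
#' of the rank variance; the effect size is `r = z / sqrt(n)` with `n` the
#' number of non-zero differences.
#'
#' @param values Numeric vector (at least 6 non-zero differences).
#' @param mu Null location.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A list with `W`, `z`, `p`, `r_effect` and `n`.
#' @export
#' @examples
#' wilcoxon_signed_rank(seq(0.55, 0.95, length.out = 49), mu = 0.5)
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all values equal mu", call. = FALSE)
  if (n < 6L) stop("need at least 6 non-zero differences", call. = FALSE)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mean_w <- n * (n + 1) / 4
  ties <- table(rk)
  var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- switch(alternative,
               greater = -0.5, less = 0.5,
               two.sided = -sign(W - mean_w) * 0.5)
  z <- (W - mean_w + cc) / sqrt(var_w)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(W = W, z = z, p = min(p, 1), r_effect = z / sqrt(n), n = n)
}

#' Baseline-corrected liking change scores
#'
#' Per condition, the change in liking is the mean of `post - pre` over
#' its two persons; the HR and LR changes are corrected by subtracting the
#' baseline condition's change (removing generic test-retest shifts). The
#' HR-vs-LR contrast `delta_hr - delta_lr` is returned alongside.
#'
#' @param persons Persons tibble with `condition`, `liking_pre`,
#'   `liking_post`, and optionally `subject_id` for cohort tables.
#' @return A tibble with one row per subject: `delta_hr`, `delta_lr`,
#'   `delta_baseline`, `hr_corrected`, `lr_corrected`, `hr_vs_lr`.
#' @export
liking_change <- function(persons) {
  persons <- tibble::as_tibble(persons)
  if (!"subject_id" %in% names(persons)) persons$subject_id <- "s01"
  if (!all(c("HR", "LR", "BASELINE") %in% persons$condition)) {
    stop("persons table must contain HR, LR and BASELINE persons",
         call. = FALSE)
  }
  persons |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(delta = mean(liking_post - liking_pre),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = delta) |>
    dplyr::transmute(
      subject_id,
      delta_hr = HR, delta_lr = LR, delta_baseline = BASELINE,
      hr_corrected = HR - BASELINE,
      lr_corrected = LR - BASELINE,
      hr_vs_lr = HR - LR
    )
}

# Ideal-fourths quartiles (Wilcox), the basis of the box rule used for
# outlier detection in the skipped correlation.
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  q1 <- (1 - h) * x[j] + h * x[j + 1]
  k <- n - j + 1
  q3 <- (1 - h) * x[k] + h * x[k - 1]
  c(q1, q3)
}

#' Robust skipped Spearman correlation
#'
#' Flags bivariate outliers by the projection method: centering the data
#' at the coordinate-wise median, projecting all points onto the direction
#' of each data point, and flagging any point whose projection falls
#' outside the box rule (ideal-fourths quartiles +/- 1.5 IQR) along any
#' direction. The Spearman correlation is then computed on the retained
#' pairs, with a seeded percentile-bootstrap confidence interval.
#'
#' @param x,y Paired numeric vectors, at least 10 observations.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A list with `r` (skipped Spearman), `ci` (percentile bootstrap),
#'   `outliers` (logical flags), `n_retained`.
#' @export
#' @examples
#' skipped_spearman(1:20, (1:20)^2, n_boot = 200, seed = 1)
skipped_spearman <- function(x, y, n_boot = 1000, seed = 1L, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 paired observations", call. = FALSE)
  center <- c(stats::median(x), stats::median(y))
  D <- cbind(x - center[1], y - center[2])
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) next
    proj <- as.numeric(D %*% (d / nd))
    q <- ideal_fourths(proj)
    iqr <- q[2] - q[1]
    flag <- flag | (proj > q[2] + 1.5 * iqr | proj < q[1] - 1.5 * iqr)
  }
  keep <- !flag
  if (sum(keep) < 3) stop("fewer than 3 pairs retained", call. = FALSE)
  xs <- x[keep]; ys <- y[keep]
  r <- stats::cor(xs, ys, method = "spearman")
  boot <- withr::with_seed(as.integer(seed), {
    m <- length(xs)
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      suppressWarnings(stats::cor(xs[idx], ys[idx], method = "spearman"))
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  list(r = r, ci = ci, outliers = flag, n_retained = sum(keep))
}
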