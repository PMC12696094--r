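# Representational similarity: model RSM, neural RSM, agreement ----------

new_rsm <- function(values, include, labels) {
  stopifnot(nrow(values) == 16L, ncol(values) == 16L,
            identical(dim(values), dim(include)))
  structure(list(values = values, include = include,
                 labels = tibble::as_tibble(labels)),
            class = "rsm")
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("<rsm> 16 x 16, %d included lower-triangle cells\n",
              sum(x$include[lower.tri(x$include)])))
  invisible(x)
}

validate_rsm_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  if (nrow(labels) != 16L ||
      !all(c("person_id", "run", "condition") %in% names(labels))) {
    stop("labels must have 16 rows with person_id, run, condition",
         call. = FALSE)
  }
  counts <- table(labels$person_id, labels$run)
  if (length(unique(labels$person_id)) != 4L ||
      length(unique(labels$run)) != 4L || any(counts != 1L)) {
    stop("labels must cover 4 persons x 4 runs exactly once", call. = FALSE)
  }
  cond_by_person <- unique(labels[c("person_id", "condition")])
  if (nrow(cond_by_person) != 4L ||
      !all(sort(table(cond_by_person$condition)) == c(2L, 2L))) {
    stop("each person needs one condition; 2 persons per condition",
         call. = FALSE)
  }
  labels
}

#' Hypothesis (model) representational similarity matrix
#'
#' Builds the 16 x 16 model RSM over 4 persons x 4 runs encoding person
#' identity: same-person different-run pairs are coded +1, different-person
#' different-run pairs from the same reward condition are coded -1. All
#' other cells — the diagonal, same-run pairs, and cross-condition pairs —
#' are excluded by the inclusion mask, so condition differences cannot
#' masquerade as person coding and only across-run replication counts.
#'
#' @param labels Tibble with 16 rows and columns `person_id`, `run`,
#'   `condition` (2 persons per condition), e.g. from
#'   [generate_patterns()].
#' @return An `rsm` object: `values`, `include` mask and `labels`.
#' @export
#' @examples
#' rsm <- build_model_rsm(generate_patterns(pattern_spec())$labels)
#' sum(rsm$include[lower.tri(rsm$include)])  # 48
build_model_rsm <- function(labels) {
  labels <- validate_rsm_labels(labels)
  same_person <- outer(labels$person_id, labels$person_id, `==`)
  same_run <- outer(labels$run, labels$run, `==`)
  same_cond <- outer(labels$condition, labels$condition, `==`)
  include <- !same_run & same_cond
  values <- matrix(0, 16, 16)
  values[same_person & !same_run] <- 1
  values[!same_person & same_cond & !same_run] <- -1
  new_rsm(values, include, labels)
}

#' Neural (data) representational similarity matrix
#'
#' Pairwise Kendall rank correlations between the 16 person x run activity
#' patterns, with the same labels and inclusion mask as the model RSM.
#'
#' @param pattern_set List with `patterns` (16 x voxels matrix) and
#'   `labels`, as returned by [generate_patterns()] or [read_patterns()].
#' @return An `rsm` object.
#' @export
neural_rsm <- function(pattern_set) {
  patterns <- pattern_set$patterns
  labels <- validate_rsm_labels(pattern_set$labels)
  if (nrow(patterns) != 16L || ncol(patterns) < 2L) {
    stop("need 16 patterns of at least 2 voxels", call. = FALSE)
  }
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant pattern: rank correlation undefined", call. = FALSE)
  }
  values <- suppressWarnings(stats::cor(t(patterns), method = "kendall"))
  dimnames(values) <- NULL
  model <- build_model_rsm(labels)
  new_rsm(values, model$include, labels)
}

# Kendall tau-a: concordant minus discordant pairs over all n(n-1)/2
# pairs, with ties counting as neither. Unlike tau-b this does not adjust
# the denominator for ties, which is the appropriate choice when one of
# the matrices is a heavily tied model RSM.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  lt <- lower.tri(sx)
  sum(sx[lt] * sy[lt]) / (n * (n - 1) / 2)
}

#' Model-data RSM agreement
#'
#' Kendall tau-a between the included lower-triangle cells of the model
#' and neural RSMs. Positive values mean same-person (across-run)
#' similarity exceeds different-person similarity, i.e. the patterns carry
#' person identity. Because tau-a does not adjust for the model RSM's
#' ties, the attainable maximum against a two-level model matrix is below
#' 1 (0.511 for the 24/24 design), which is immaterial for sign-based
#' group inference.
#'
#' @param model,neural `rsm` objects with identical labels and masks.
#' @return Kendall tau-a, in \[-1, 1\].
#' @export
rsm_agreement <- function(model, neural) {
  stopifnot(inherits(model, "rsm"), inherits(neural, "rsm"))
  if (!identical(model$include, neural$include) ||
      !identical(model$labels, neural$labels)) {
    stop("model and neural RSMs must share labels and inclusion mask",
         call. = FALSE)
  }
  cells <- model$include & lower.tri(model$include)
  kendall_tau_a(model$values[cells], neural$values[cells])
}

#' Write an RSM (and its mask) as TSV
#'
#' @param rsm An `rsm` object.
#' @param values_path,mask_path File paths for the value matrix and the
#'   0/1 inclusion mask.
#' @return `values_path`, invisibly.
#' @export
write_rsm_tsv <- function(rsm, values_path, mask_path) {
  utils::write.table(rsm$values, values_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(rsm$include * 1L, mask_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(values_path)
}
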