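#' Sensitivity analysis of a fitted network
#'
#' For each model input, the sensitivity quotient is the ratio of the
#' model's scaled RMSE when that input is made uninformative — replaced,
#' in every case of the evaluation partition, by its training-partition
#' mean — to the full model's scaled RMSE on the same partition.
#' Quotients above 1 mark inputs whose removal degrades the model, i.e.
#' important variables.  Rows are ranked by descending quotient with
#' stable tie-breaking (see [rank_quotients()]).
#'
#' The default evaluation partition is validation; an interpolating model
#' cannot be analysed on its own training set (baseline error zero).
#'
#' @param model A fitted `rbf_model` (it carries the training means used
#'   for substitution).
#' @param features A `feature_set` covering the cohort.
#' @param split A `data_split`.
#' @param partition One of `"validation"`, `"training"`, `"testing"`.
#' @return Data.frame `variable`, `quotient`, `rank` in rank order.
#' @export
sensitivity_analysis <- function(model, features, split,
                                 partition = c("validation", "training",
                                               "testing")) {
  partition <- match.arg(partition)
  ids <- switch(partition, validation = split$valid,
                training = split$train, testing = split$test)
  fr <- feature_rows(features, ids)
  x <- fr$x[, model$input_names, drop = FALSE]
  base <- rmse_scaled(model, x, fr$y)
  if (base < 1e-12)
    stop("baseline RMSE is zero on the ", partition,
         " partition (interpolating model); choose another partition",
         call. = FALSE)
  q <- vapply(model$input_names, function(nm) {
    xs <- x
    xs[, nm] <- model$input_means[[nm]]
    rmse_scaled(model, xs, fr$y) / base
  }, numeric(1))
  rank_quotients(q)
}

#' Rank sensitivity quotients
#'
#' Sorts variables by descending quotient and assigns ranks 1..n.  Ties
#' are broken stably: of two equal quotients, the variable listed earlier
#' in the input keeps the smaller rank.
#'
#' @param quotients Named numeric vector (variable -> quotient).
#' @return Data.frame `variable`, `quotient`, `rank` in rank order.
#' @export
#' @examples
#' rank_quotients(c(X07 = 1.01, X05 = 0.99, X14 = 1.01))
rank_quotients <- function(quotients) {
  if (!length(quotients)) stop("empty quotient mapping", call. = FALSE)
  if (is.null(names(quotients)) || any(!nzchar(names(quotients))))
    stop("quotients must be named", call. = FALSE)
  ord <- order(-quotients)  # radix sort: stable for numeric input
  data.frame(variable = names(quotients)[ord],
             quotient = unname(quotients[ord]),
             rank = seq_along(quotients),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prune weak inputs and retrain
#'
#' The tuning step: inputs whose sensitivity quotient falls below
#' `threshold` are dropped (default 1.0 — a quotient above 1 marks an
#' input the model relies on) and a fresh network is fitted on the
#' retained inputs, ordered by sensitivity rank.  The hidden count is
#' kept unless it exceeds the number of training cases.  Note that final
#' published models may deliberately keep slightly sub-threshold inputs,
#' so the threshold is a parameter, not a constant.
#'
#' @param model The fitted `rbf_model` being tuned.
#' @param report Sensitivity report for `model` (from
#'   [sensitivity_analysis()]).
#' @param features A `feature_set` covering the cohort (must contain all
#'   retained inputs).
#' @param split A `data_split`.
#' @param threshold Pruning threshold on the quotient (> 0).
#' @param seed Seed for the retrain's center selection.
#' @param ridge,spread Passed to [fit_rbf()].
#' @return The retrained `rbf_model` with updated topology string.
#' @export
prune_and_retrain <- function(model, report, features, split,
                              threshold = 1.0, seed = 1L,
                              ridge = 1e-8, spread = 2) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  stopifnot(all(c("variable", "quotient") %in% names(report)))
  retained <- report$variable[report$quotient >= threshold]
  if (!length(retained))
    stop("pruning at threshold ", threshold,
         " would drop every input; refusing", call. = FALSE)
  tr <- feature_rows(features, split$train)
  x <- tr$x[, retained, drop = FALSE]
  H <- min(length(model$widths), nrow(x))
  fit_rbf(x, tr$y, H = H, seed = seed, ridge = ridge, spread = spread)
}
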