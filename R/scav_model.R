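#' Fit a SCAV voting ensemble on training scores
#'
#' The model-fitting entry point of the package. Given a training score
#' matrix (base models x training samples, mutant pseudo-probabilities)
#' and the training labels, this
#' 1. ranks the base models by their individual training AUC;
#' 2. keeps the top `n_members` as ensemble members ([rank_members()]);
#' 3. for `voting = "scav"`, tunes the count threshold `t` on the training
#'    data by maximizing the training AUC of the ensemble score
#'    ([select_threshold()]).
#'
#' Nothing from any test set may enter `scores`/`labels`: the member set
#' and the threshold are part of the fitted model.
#'
#' @param scores training [score_matrix()].
#' @param labels training labels (both classes present).
#' @param voting `"scav"`, `"average"` or `"maximum"`.
#' @param n_members ensemble size; defaults to all models. The study
#'   design this package supports uses top 5, 10 or 20 of a 32-model bank.
#' @return An object of class `scav_ensemble` with components `voting`,
#'   `members` (row indices into `scores`), `member_ids`, `t` (SCAV count
#'   threshold, `NA` otherwise), `member_aucs` (training AUCs of all
#'   models), `train_auc` (training AUC of the fitted ensemble score).
#' @seealso [predict.scav_ensemble()], [scav_vote()]
#' @examples
#' lab <- rep(c(1, 0), c(5, 20))
#' sc <- simulate_score_matrix(lab, n_models = 6, seed = 2)
#' fit <- scav_ensemble(sc, lab, n_members = 4)
#' fit
#' predict(fit, sc[, 1:3])
#' @export
scav_ensemble <- function(scores, labels,
                          voting = c("scav", "average", "maximum"),
                          n_members = nrow(scores)) {
  voting <- match.arg(voting)
  scores <- score_matrix(scores)
  y <- as_mutation_label(labels)
  if (ncol(scores) != length(y)) stop("one label per score column required")
  if (length(unique(y)) < 2) stop("training labels must contain both classes")
  member_aucs <- apply(scores, 1, function(s) auc_score(y, s))
  members <- rank_members(member_aucs, n_members)
  sub <- scores[members, , drop = FALSE]
  t <- NA_integer_
  auc_by_t <- NULL
  if (voting == "scav") {
    sel <- select_threshold(sub, y)
    t <- sel$t
    auc_by_t <- sel$auc_by_t
  }
  train_score <- vote_with(sub, voting, t)$score
  structure(list(
    voting = voting,
    members = members,
    member_ids = rownames(scores)[members],
    t = t,
    auc_by_t = auc_by_t,
    member_aucs = member_aucs,
    train_auc = auc_score(y, train_score),
    n_train = length(y)
  ), class = "scav_ensemble")
}

vote_with <- function(scores, voting, t = NA) {
  switch(voting,
    scav = scav_vote(scores, t),
    average = average_vote(scores),
    maximum = maximum_vote(scores)
  )
}

#' Predict mutation status with a fitted SCAV ensemble
#'
#' Applies the fitted voting rule (member set and, for SCAV, the tuned
#' count threshold) to a new score matrix. The matrix must contain the
#' member models: rows are matched by model id when the new matrix has
#' rownames matching the training ids, otherwise by position.
#'
#' @param object a fitted [scav_ensemble()].
#' @param newdata score matrix (models x samples) for the new samples.
#' @param ... unused.
#' @return A `data.frame` with `sample_id`, `label`, `score`, `votes` per
#'   sample (the ensemble's voting result).
#' @export
predict.scav_ensemble <- function(object, newdata, ...) {
  newdata <- score_matrix(newdata)
  rows <- if (!is.null(rownames(newdata)) &&
              all(object$member_ids %in% rownames(newdata))) {
    object$member_ids
  } else {
    if (max(object$members) > nrow(newdata)) {
      stop("'newdata' lacks the fitted member models")
    }
    object$members
  }
  vote_with(newdata[rows, , drop = FALSE], object$voting, object$t)
}

#' @export
print.scav_ensemble <- function(x, ...) {
  cat(sprintf("scav_ensemble: %s voting, %d members%s\n",
              x$voting, length(x$members),
              if (x$voting == "scav") sprintf(", count threshold t = %d", x$t)
              else ""))
  cat(sprintf("  training AUC %.3f (best single member %.3f)\n",
              x$train_auc, max(x$member_aucs)))
  invisible(x)
}

#' @export
summary.scav_ensemble <- function(object, ...) {
  cat(sprintf("SCAV ensemble fit (%s voting)\n", object$voting))
  cat(sprintf("  trained on %d samples, %d candidate models\n",
              object$n_train, length(object$member_aucs)))
  cat("  members (by training AUC):\n")
  print(data.frame(model = object$member_ids,
                   train_auc = round(object$member_aucs[object$members], 4)))
  if (object$voting == "scav") {
    cat(sprintf("  count threshold t = %d of %d (>= t mutant votes => mutant)\n",
                object$t, length(object$members)))
    cat("  training AUC by t:",
        paste(round(object$auc_by_t, 3), collapse = " "), "\n")
  }
  cat(sprintf("  ensemble training AUC %.4f\n", object$train_auc))
  invisible(object)
}

#' Threshold-tuning profile of a SCAV fit
#'
#' Plots the training AUC of the SCAV ensemble score against every
#' candidate count threshold, marking the selected one.
#'
#' @param x a fitted [scav_ensemble()] with `voting = "scav"`.
#' @param ... passed to [plot()].
#' @export
plot.scav_ensemble <- function(x, ...) {
  if (x$voting != "scav" || is.null(x$auc_by_t)) {
    stop("threshold profile exists only for SCAV fits")
  }
  plot(seq_along(x$auc_by_t), x$auc_by_t, type = "b",
       xlab = "count threshold t", ylab = "training AUC", ...)
  graphics::points(x$t, x$auc_by_t[x$t], pch = 19)
  invisible(x)
}
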