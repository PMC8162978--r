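#' Score matrices
#'
#' A score matrix holds one row per base model and one column per sample;
#' every entry is the model's minority-class (mutant) pseudo-probability
#' for that sample. This is the substrate all voting schemes operate on.
#'
#' @param scores numeric matrix in \[0, 1\], models x samples.
#' @return The validated matrix with model/sample dimnames filled in.
#' @export
score_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1 || ncol(scores) < 1) stop("empty score matrix")
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must be pseudo-probabilities in [0, 1]")
  }
  if (is.null(rownames(scores))) {
    rownames(scores) <- sprintf("m_%02d", seq_len(nrow(scores)))
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("s_%04d", seq_len(ncol(scores)))
  }
  scores
}

voting_result <- function(score, votes, sample_ids) {
  data.frame(
    sample_id = sample_ids,
    label = factor(ifelse(score >= 0.5, "mutant", "wildtype"),
                   levels = c("wildtype", "mutant")),
    score = score,
    votes = votes,
    row.names = NULL
  )
}

#' Selective Class Average Voting (SCAV)
#'
#' The voting rule at the core of this package, designed for imbalanced
#' problems where the positive (mutant) class is rare. Per sample:
#' 1. each model votes mutant iff its pseudo-probability is >= 0.5;
#' 2. the mutant votes are counted (`v`);
#' 3. if `v >= t` the sample is labelled mutant and its ensemble score is
#'    the average pseudo-probability over the mutant-voting models only;
#'    otherwise it is labelled wildtype and the score is the average over
#'    the wildtype-voting models only (nonempty whenever `v < t <= m`).
#'
#' The final label always agrees with thresholding the ensemble score at
#' 0.5: the mutant branch averages values >= 0.5, the wildtype branch
#' values < 0.5. Unlike plain average voting, a handful of confident
#' mutant votes can carry a sample even when most models — as models
#' trained on rare positives tend to — score it low.
#'
#' The count threshold is inclusive (`v >= t`), so `t = 1` is the
#' "any model votes mutant" rule and `t = m` requires unanimity.
#'
#' @param scores a [score_matrix()] (models x samples).
#' @param t count threshold, `1 <= t <= nrow(scores)`. Tune it on training
#'   data with [select_threshold()] or [scav_ensemble()].
#' @return A `data.frame` with one row per sample: `sample_id`, `label`,
#'   `score` (ensemble mutant pseudo-probability), `votes`.
#' @examples
#' m <- rbind(c(0.6, 0.4), c(0.7, 0.3), c(0.2, 0.6))
#' scav_vote(m, t = 2)
#' @export
scav_vote <- function(scores, t) {
  scores <- score_matrix(scores)
  m <- nrow(scores)
  if (t < 1 || t > m) stop("'t' must lie in 1..number of models")
  vote <- scores >= 0.5
  v <- colSums(vote)
  score <- vapply(seq_len(ncol(scores)), function(j) {
    if (v[j] >= t) mean(scores[vote[, j], j]) else mean(scores[!vote[, j], j])
  }, numeric(1))
  voting_result(score, v, colnames(scores))
}

#' Average voting
#'
#' The ensemble score of a sample is the mean pseudo-probability over all
#' models; the label is mutant iff the mean is >= 0.5.
#'
#' @inheritParams scav_vote
#' @return As [scav_vote()].
#' @export
average_vote <- function(scores) {
  scores <- score_matrix(scores)
  voting_result(colMeans(scores), colSums(scores >= 0.5), colnames(scores))
}

#' Maximum-confidence voting
#'
#' Per sample, the model with the highest confidence
#' `max(p, 1 - p)` is selected (ties go to the lowest model index) and its
#' pseudo-probability alone decides the sample.
#'
#' @inheritParams scav_vote
#' @return As [scav_vote()].
#' @export
maximum_vote <- function(scores) {
  scores <- score_matrix(scores)
  conf <- pmax(scores, 1 - scores)
  best <- apply(conf, 2, which.max)        # ties -> lowest index
  score <- scores[cbind(best, seq_len(ncol(scores)))]
  voting_result(score, colSums(scores >= 0.5), colnames(scores))
}

#' Tune the SCAV count threshold on training data
#'
#' Evaluates [scav_vote()] for every threshold `t` in `1..m`, computes the
#' training AUC of the ensemble score against the training labels, and
#' returns the `t` with the highest AUC (ties broken towards the smallest
#' `t`). The threshold must be tuned on training data only and then applied
#' unchanged to test data.
#'
#' @param scores training [score_matrix()].
#' @param labels training labels, both classes present.
#' @return A list with `t` (selected threshold) and `auc_by_t` (training
#'   AUC for every candidate).
#' @export
select_threshold <- function(scores, labels) {
  scores <- score_matrix(scores)
  y <- as_mutation_label(labels)
  if (length(unique(y)) < 2) stop("training labels must contain both classes")
  m <- nrow(scores)
  aucs <- vapply(seq_len(m), function(t) {
    auc_score(y, scav_vote(scores, t)$score)
  }, numeric(1))
  list(t = which.max(aucs), auc_by_t = aucs)
}

#' Select ensemble members by training AUC
#'
#' Returns the indices of the `k` models with the largest training AUCs,
#' in decreasing AUC order; AUC ties are broken towards the lower model
#' index, so the selection is stable.
#'
#' @param training_aucs per-model training AUCs.
#' @param k number of members, `k <= length(training_aucs)`.
#' @return Integer vector of member indices.
#' @examples
#' rank_members(c(0.7, 0.6, 0.8), 2) # 3, 1
#' @export
rank_members <- function(training_aucs, k) {
  m <- length(training_aucs)
  if (k > m) stop("'k' exceeds the number of models")
  order(-training_aucs, seq_len(m))[seq_len(k)]
}
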