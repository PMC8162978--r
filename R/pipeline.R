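#' Leakage-free stratified cross-validated base-model bank
#'
#' Runs the experiment-1 workflow: the samples are split into stratified
#' folds; within each fold, feature selection, optional SMOTE balancing and
#' classifier fitting all see the training rows only, and the fitted model
#' scores the held-out rows. Pooling the held-out scores of every
#' configuration yields an out-of-fold score matrix (configs x samples) —
#' the substrate for [scav_ensemble()] — plus, per configuration, the mean
#' across folds of the fold-training AUC (used to rank ensemble members).
#'
#' The stage order inside a fold is fixed: selection first, then SMOTE on
#' the selected training columns, then fitting. Stratification keeps the
#' per-fold mutant counts within one of each other, which matters at 14%
#' prevalence where unstratified folds are frequently mutant-free.
#'
#' @param table a [feature_table()].
#' @param configs list of [base_model_config()]s (see [config_grid()]).
#' @param folds number of folds (default 10); the mutant count must be at
#'   least the fold count.
#' @param seed integer seed driving fold assignment, SMOTE and any
#'   stochastic adapter.
#' @return A list of class `cv_result`: `score_matrix` (configs x samples,
#'   pooled out-of-fold), `mean_train_auc` (per config), `fold_scores`
#'   (per fold: train/test indices and the configs x fold-train score
#'   matrix, for training-side ensemble tuning), `labels`, `metrics`
#'   (per-config pooled test metrics), `fold_of` (fold id per sample).
#' @export
run_cv <- function(table, configs, folds = 10, seed = 1) {
  stopifnot(folds >= 2)
  y <- is_minority(table)
  n <- nrow(table)
  if (sum(y) < folds) stop("mutant class too small to stratify across folds")
  rng <- local_rng(seed)
  fold_of <- integer(n)
  # minority spread first; majority then fills the emptiest folds so fold
  # sizes stay within one of each other
  idx_min <- sample(which(y))
  fold_of[idx_min] <- rep_len(seq_len(folds), length(idx_min))
  idx_maj <- sample(which(!y))
  fill_order <- order(tabulate(fold_of[idx_min], folds), seq_len(folds))
  fold_of[idx_maj] <- rep_len(fill_order, length(idx_maj))
  n_cfg <- length(configs)
  cfg_names <- vapply(configs, `[[`, character(1), "name")
  pooled <- matrix(NA_real_, n_cfg, n,
                   dimnames = list(cfg_names, table$sample_id))
  train_auc <- matrix(NA_real_, n_cfg, folds)
  fold_scores <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    train <- table[tr_idx, , drop = FALSE]
    class(train) <- class(table)
    test <- table[te_idx, , drop = FALSE]
    class(test) <- class(table)
    tr_mat <- matrix(NA_real_, n_cfg, length(tr_idx),
                     dimnames = list(cfg_names, table$sample_id[tr_idx]))
    selected_f <- vector("list", n_cfg)
    for (ci in seq_len(n_cfg)) {
      fitted <- fit_base_model(train, test, configs[[ci]],
                               seed = seed * 1000L + f * 100L + ci)
      tr_mat[ci, ] <- fitted$train_scores
      pooled[ci, te_idx] <- fitted$test_scores
      train_auc[ci, f] <- fitted$train_auc
      selected_f[[ci]] <- fitted$selected
    }
    names(selected_f) <- cfg_names
    fold_scores[[f]] <- list(train_idx = tr_idx, test_idx = te_idx,
                             train_scores = tr_mat, selected = selected_f)
  }
  metrics <- lapply(seq_len(n_cfg), function(ci) {
    metrics_report(table$label, pooled[ci, ] >= 0.5, pooled[ci, ])
  })
  names(metrics) <- cfg_names
  structure(list(
    score_matrix = pooled,
    mean_train_auc = stats::setNames(rowMeans(train_auc), cfg_names),
    fold_train_auc = train_auc,
    fold_scores = fold_scores,
    fold_of = fold_of,
    labels = table$label,
    sample_ids = table$sample_id,
    metrics = metrics
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d configs x %d samples, %d folds\n",
              nrow(x$score_matrix), ncol(x$score_matrix),
              length(x$fold_scores)))
  cat("  pooled out-of-fold AUC range:",
      paste(round(range(vapply(x$metrics, `[[`, numeric(1), "auc")), 3),
            collapse = " .. "), "\n")
  invisible(x)
}

#' Fit one base-model configuration on a training table
#'
#' The single-fold stage of the experiment-1 workflow, used by [run_cv()]
#' inside every fold and directly useful for a fixed train/test split:
#' feature selection on the training rows, optional SMOTE balancing of the
#' selected training columns, classifier fitting, then scoring of both the
#' training and the test rows. Nothing from `test` influences selection,
#' balancing or fitting.
#'
#' @param train,test [feature_table()]s with identical feature columns.
#' @param config a [base_model_config()].
#' @param seed integer seed for SMOTE and stochastic adapters.
#' @return List with `selected` (feature names), `train_scores`,
#'   `test_scores` (mutant pseudo-probabilities), `train_auc`.
#' @export
fit_base_model <- function(train, test, config, seed = 1) {
  sel <- rank_features(train, config$k, config$selector)
  fit_table <- train[, c("sample_id", "patient_id", "label", "synthetic",
                         sel$selected), drop = FALSE]
  class(fit_table) <- class(train)
  if (config$smote) {
    fit_table <- smote(fit_table,
                       k_neighbors = min(5, sum(is_minority(fit_table)) - 1),
                       seed = seed)
  }
  model <- config$adapter$fit(feature_matrix(fit_table),
                              is_minority(fit_table), seed = seed)
  sc_tr <- config$adapter$score(
    model, feature_matrix(train)[, sel$selected, drop = FALSE])
  sc_te <- config$adapter$score(
    model, feature_matrix(test)[, sel$selected, drop = FALSE])
  if (anyNA(c(sc_tr, sc_te)) || any(c(sc_tr, sc_te) < 0 | c(sc_tr, sc_te) > 1)) {
    stop("adapter '", config$adapter$name, "' returned out-of-range scores")
  }
  list(selected = sel$selected, train_scores = sc_tr, test_scores = sc_te,
       train_auc = auc_score(train$label, sc_tr))
}

#' Ensemble experiment on a cross-validated model bank
#'
#' Completes the experiment: ensemble members are the `n_members` base
#' configurations with the highest mean fold-training AUC
#' ([rank_members()]); within each fold the voting rule is fitted on that
#' fold's training scores (for SCAV the count threshold is tuned there,
#' training rows only) and applied to the fold's held-out columns; the
#' pooled held-out ensemble scores yield the test metrics.
#'
#' @param cv a [run_cv()] result.
#' @param n_members ensemble size (e.g. 5, 10, 20).
#' @param voting `"scav"`, `"average"` or `"maximum"`.
#' @return A list of class `ensemble_experiment`: `metrics`
#'   (a `metrics_report` on the pooled out-of-fold ensemble predictions),
#'   `result` (per-sample voting results), `members` (config names),
#'   `t_by_fold` (tuned SCAV thresholds, `NA` for other schemes).
#' @export
run_ensemble_experiment <- function(cv, n_members,
                                    voting = c("scav", "average", "maximum")) {
  voting <- match.arg(voting)
  stopifnot(inherits(cv, "cv_result"))
  if (n_members > nrow(cv$score_matrix)) {
    stop("'n_members' exceeds the number of configurations")
  }
  members <- rank_members(cv$mean_train_auc, n_members)
  n <- length(cv$labels)
  score <- numeric(n)
  votes <- integer(n)
  t_by_fold <- rep(NA_integer_, length(cv$fold_scores))
  for (f in seq_along(cv$fold_scores)) {
    fs <- cv$fold_scores[[f]]
    tr <- fs$train_scores[members, , drop = FALSE]
    t <- NA_integer_
    if (voting == "scav") {
      t <- select_threshold(tr, cv$labels[fs$train_idx])$t
      t_by_fold[f] <- t
    }
    te <- cv$score_matrix[members, fs$test_idx, drop = FALSE]
    res <- vote_with(te, voting, t)
    score[fs$test_idx] <- res$score
    votes[fs$test_idx] <- res$votes
  }
  result <- voting_result(score, votes, cv$sample_ids)
  structure(list(
    metrics = metrics_report(cv$labels, result$label, result$score),
    result = result,
    members = rownames(cv$score_matrix)[members],
    voting = voting,
    t_by_fold = t_by_fold
  ), class = "ensemble_experiment")
}

#' @export
print.ensemble_experiment <- function(x, ...) {
  cat(sprintf("ensemble_experiment: %s voting, %d members%s\n",
              x$voting, length(x$members),
              if (x$voting == "scav")
                sprintf(", t per fold: %s", paste(x$t_by_fold, collapse = " "))
              else ""))
  print(x$metrics)
  invisible(x)
}
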