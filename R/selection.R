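#' Rank features by class association
#'
#' Ranks every feature column of a feature table on the labelled samples
#' and returns the ranking plus the top-`k` set. Two rankers are available:
#'
#' * `"mann_whitney"` — two-sided Wilcoxon rank-sum p-value of each feature
#'   between the two classes, sorted ascending (most discriminative first).
#'   The p-value is exact when the smaller class has at most 8 samples and
#'   there are no ties, and uses the normal approximation with tie and
#'   continuity correction otherwise; a constant feature gets p = 1.
#' * `"relieff"` — deterministic all-instances ReliefF: every sample is
#'   visited once; for each, the `n_neighbors` nearest same-class (hits)
#'   and other-class (misses) neighbours are found by Euclidean distance on
#'   range-normalized features, and each feature's weight accumulates
#'   (miss diffs − hit diffs) / (n * n_neighbors). Weights are sorted
#'   descending.
#'
#' Ties in the score are broken lexicographically by feature name, so
#' selections are reproducible.
#'
#' @param table a [feature_table()] containing both classes (training rows
#'   only — never let test rows into selection).
#' @param k number of features to retain (e.g. 5, 10, 15 or 20).
#' @param method `"mann_whitney"` or `"relieff"`.
#' @param n_neighbors ReliefF neighbour count (default 10); each class
#'   must have more than `n_neighbors` samples.
#' @return A list of class `selection_result` with `ranked_features`
#'   (all features, best first), `scores` (in ranked order), `selected`
#'   (top-`k` names), `method`, `k`.
#' @export
rank_features <- function(table, k, method = c("mann_whitney", "relieff"),
                          n_neighbors = 10) {
  method <- match.arg(method)
  feats <- feature_names(table)
  if (k < 1 || k > length(feats)) stop("'k' must be in 1..number of features")
  y <- is_minority(table)
  if (!any(y) || all(y)) stop("both classes must be present")
  x <- feature_matrix(table)
  scores <- switch(method,
    mann_whitney = apply(x, 2, function(v) mw_pvalue(v[y], v[!y])),
    relieff = relieff_weights(x, y, n_neighbors)
  )
  decreasing <- method == "relieff"
  ord <- order(scores, colnames(x), decreasing = c(decreasing, FALSE),
               method = "radix")
  res <- list(
    ranked_features = colnames(x)[ord],
    scores = unname(scores[ord]),
    selected = colnames(x)[ord][seq_len(k)],
    method = method,
    k = as.integer(k)
  )
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): top %d of %d features\n",
              x$method, x$k, length(x$ranked_features)))
  print(utils::head(data.frame(feature = x$ranked_features,
                               score = x$scores), x$k))
  invisible(x)
}

#' @export
as.data.frame.selection_result <- function(x, ...) {
  data.frame(feature = x$ranked_features, score = x$scores,
             rank = seq_along(x$ranked_features),
             selected = seq_along(x$ranked_features) <= x$k)
}

# two-sided rank-sum p-value; exact for small tie-free samples,
# normal approximation with tie/continuity correction otherwise
mw_pvalue <- function(a, b) {
  if (length(unique(c(a, b))) == 1) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

relieff_weights <- function(x, y, n_neighbors) {
  n <- nrow(x)
  if (min(sum(y), sum(!y)) < n_neighbors + 1) {
    stop("each class needs at least n_neighbors + 1 samples")
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1                    # constant features contribute 0 anyway
  xs <- sweep(sweep(x, 2, apply(x, 2, min), `-`), 2, rng, `/`)
  d2 <- as.matrix(stats::dist(xs))^2
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    hits <- which(y == y[i])
    hits <- hits[hits != i]
    misses <- which(y != y[i])
    # deterministic: distance ties broken by sample index
    nh <- hits[order(d2[i, hits], hits)][seq_len(n_neighbors)]
    nm <- misses[order(d2[i, misses], misses)][seq_len(n_neighbors)]
    diff_h <- abs(sweep(xs[nh, , drop = FALSE], 2, xs[i, ], `-`))
    diff_m <- abs(sweep(xs[nm, , drop = FALSE], 2, xs[i, ], `-`))
    w <- w + colSums(diff_m) - colSums(diff_h)
  }
  stats::setNames(w / (n * n_neighbors), colnames(x))
}
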