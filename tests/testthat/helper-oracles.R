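# Independent oracles used across tests. These deliberately re-derive
# results by different algorithms than the package uses.

# Naive per-sample SCAV: literal transcription of the voting rule, scalar
# loops, no shared code with scav_vote().
naive_scav <- function(scores, t) {
  n <- ncol(scores)
  out_label <- character(n)
  out_score <- numeric(n)
  for (j in seq_len(n)) {
    p <- scores[, j]
    minority_models <- which(p >= 0.5)
    if (length(minority_models) >= t) {
      s <- mean(p[minority_models])
    } else if (length(minority_models) == 0) {
      s <- mean(p)
    } else {
      s <- mean(p[-minority_models])
    }
    out_score[j] <- s
    out_label[j] <- if (s >= 0.5) "mutant" else "wildtype"
  }
  list(label = out_label, score = out_score)
}

# Trapezoidal ROC area, built from the ROC curve itself.
trapezoid_auc <- function(labels, scores) {
  y <- as.numeric(labels == "mutant" | labels == 1 | labels == TRUE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Connected-component sizes via igraph: voxels of a logical array are graph
# nodes, 26-neighbour pairs are edges.
igraph_zone_sizes <- function(sel) {
  d <- dim(sel)
  idx <- which(sel)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  id_of <- stats::setNames(seq_along(idx), idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    present <- lin %in% idx
    edges <- c(edges, rbind(which(ok)[present], id_of[as.character(lin[present])]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  sort(igraph::components(g)$csize)
}

# The adversarial leakage fixture: a giveaway feature with zero signal on
# the training rows (constant) that equals the label on the test rows.
leakage_fixture <- function(seed, n = 800, n_train = 400,
                            minority_fraction = 0.24, p_noise = 30) {
  set.seed(seed)
  n_min <- round(minority_fraction * n)
  lab <- rep(c("mutant", "wildtype"), c(n_min, n - n_min))[sample(n)]
  x <- matrix(stats::rnorm(n * p_noise), n, p_noise)
  colnames(x) <- sprintf("f_%04d", seq_len(p_noise))
  giveaway <- rep(0, n)
  test_rows <- (n_train + 1):n
  giveaway[test_rows] <- as.numeric(lab[test_rows] == "mutant")
  tab <- feature_table(cbind(x, giveaway = giveaway), lab)
  list(train = tab[seq_len(n_train), ], test = tab[test_rows, ],
       test_labels = lab[test_rows])
}

random_score_matrix <- function(m, n) {
  matrix(stats::runif(m * n), m, n)
}
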