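#' SMOTE minority oversampling
#'
#' Balances a feature table by synthesizing minority (mutant) samples:
#' each synthetic sample is `x_i + g * (x_nn - x_i)` with `g ~ Uniform(0,1)`
#' and `x_nn` one of the `k_neighbors` nearest minority neighbours of the
#' minority sample `x_i` (Euclidean distance on features standardized by
#' the table's mean/sd; synthetic values are de-standardized afterwards, so
#' each synthetic row is still an exact convex combination of two original
#' minority rows). Synthesis repeats until the minority count reaches
#' `target_ratio` times the majority count (within one sample). Original
#' rows pass through unchanged; synthetic rows carry `synthetic = TRUE`,
#' fresh sample ids, and the patient id of their base sample.
#'
#' Only oversampling is performed; the majority class is never touched.
#' Apply this to training rows only — oversampling before a train/test
#' split leaks synthetic copies of test information.
#'
#' @param table a [feature_table()] with at least 2 minority samples.
#' @param k_neighbors neighbours considered per minority sample (default
#'   5); must be smaller than the minority count.
#' @param target_ratio desired minority/majority ratio in (0, 1.5];
#'   default 1 (balanced).
#' @param seed integer seed; output is reproducible.
#' @return A [feature_table()] with the original rows first, synthetic
#'   rows appended.
#' @export
smote <- function(table, k_neighbors = 5, target_ratio = 1, seed = 1) {
  stopifnot(k_neighbors >= 1)
  if (target_ratio <= 0 || target_ratio > 1.5) {
    stop("'target_ratio' must lie in (0, 1.5]")
  }
  y <- is_minority(table)
  n_min <- sum(y)
  n_maj <- sum(!y)
  if (n_min < 2) stop("need at least 2 minority samples")
  if (k_neighbors >= n_min) stop("'k_neighbors' must be < minority count")
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0) return(table)

  x <- feature_matrix(table)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  min_idx <- which(y)
  xm <- xs[min_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xm))^2
  diag(d2) <- Inf
  nn <- matrix(apply(d2, 1, function(r) order(r)[seq_len(k_neighbors)]),
               nrow = n_min, ncol = k_neighbors, byrow = TRUE)

  rng <- local_rng(seed)
  base <- sample(rep_len(seq_len(n_min), n_new))
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  g <- stats::runif(n_new)
  xnew_s <- xm[base, , drop = FALSE] +
    g * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  xnew <- sweep(sweep(xnew_s, 2, sdv, `*`), 2, mu, `+`)

  synth <- feature_table(
    xnew,
    labels = rep("mutant", n_new),
    sample_id = sprintf("synth_%04d", seq_len(n_new)),
    patient_id = table$patient_id[min_idx[base]],
    synthetic = TRUE
  )
  out <- rbind(as.data.frame(table), as.data.frame(synth))
  class(out) <- c("feature_table", "data.frame")
  out
}
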