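#' Simulate an imbalanced radiomic feature table
#'
#' Generates a two-class feature table emulating a radiogenomic cohort in
#' which mutant tumors are rare. Exactly `round(n_samples *
#' minority_fraction)` samples are labelled `"mutant"`. The first
#' `n_informative` features are class-conditional Gaussians with unit
#' variance and a standardized mean shift of `effect_size` between classes
#' (mutant mean higher); the remaining features are class-independent
#' standard normals. Each sample belongs to its own patient.
#'
#' Defaults follow the mutation prevalences typical of non-small-cell lung
#' cancer cohorts: ~14% of patients carry an EGFR mutation and ~24% a KRAS
#' mutation; `minority_fraction = 0.14` is the default.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_features total number of features.
#' @param n_informative number of class-informative features
#'   (`<= n_features`).
#' @param minority_fraction fraction of mutant samples, in (0, 0.5).
#' @param effect_size standardized mean shift of informative features
#'   between classes (>= 0).
#' @param seed integer seed; identical arguments + seed give identical
#'   tables.
#' @return A [feature_table()].
#' @examples
#' tab <- simulate_feature_table(100, n_features = 20, seed = 1)
#' table(tab$label)
#' @export
simulate_feature_table <- function(n_samples = 83, n_features = 266,
                                   n_informative = min(10, n_features),
                                   minority_fraction = 0.14,
                                   effect_size = 1, seed = 1) {
  stopifnot(n_features >= 1, n_informative >= 0,
            n_informative <= n_features, effect_size >= 0)
  if (minority_fraction <= 0 || minority_fraction >= 0.5) {
    stop("'minority_fraction' must lie in (0, 0.5)")
  }
  n_minority <- round(n_samples * minority_fraction)
  if (n_samples < 10 || n_minority < 2) {
    stop("table too small: need n_samples >= 10 and at least 2 minority samples")
  }
  rng <- local_rng(seed)
  labels <- rep("wildtype", n_samples)
  labels[sample.int(n_samples, n_minority)] <- "mutant"
  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  if (n_informative > 0) {
    shift <- ifelse(labels == "mutant", effect_size, 0)
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
  }
  colnames(x) <- sprintf("f_%04d", seq_len(n_features))
  feature_table(x, labels,
                sample_id = sprintf("s_%04d", seq_len(n_samples)),
                patient_id = sprintf("p_%04d", seq_len(n_samples)))
}

#' Simulate a bank of correlated probabilistic classifiers
#'
#' Produces a score matrix (models x samples) of minority-class
#' pseudo-probabilities from a shared-latent construction:
#' \deqn{p_{ij} = \mathrm{logistic}(d \cdot u_j + e_{ij})}
#' where the per-sample latent \eqn{u_j} is \eqn{-0.5} for mutant and
#' \eqn{-2} for wildtype samples, `d` is `discrimination` and
#' \eqn{e_{ij} \sim N(0, \mathrm{model\_noise\_sd}^2)} is independent
#' per-model noise. The latent offsets are deliberately negative: classifiers
#' trained on a rare positive class tend to under-call it, so even true
#' mutant samples sit near (slightly below) the 0.5 vote line while wildtype
#' samples sit well below it. Model diversity — what voting exploits — is
#' controlled solely by `model_noise_sd`.
#'
#' With `discrimination = 0` and no noise every entry is exactly 0.5; with
#' noise 0 and any positive discrimination each model ranks every mutant
#' above every wildtype sample (AUC 1).
#'
#' @param labels label vector (anything [feature_table()] accepts); both
#'   classes must be present.
#' @param n_models number of models (rows).
#' @param discrimination per-model signal strength (>= 0).
#' @param model_noise_sd standard deviation of the per-model noise (>= 0).
#' @param seed integer seed.
#' @return Numeric matrix (models x samples) in \[0, 1\] with model ids as
#'   rownames and sample ids (`s_0001`, ... or the names of `labels`) as
#'   colnames.
#' @export
simulate_score_matrix <- function(labels, n_models = 10, discrimination = 0.5,
                                  model_noise_sd = 1, seed = 1) {
  lab <- as_mutation_label(labels)
  if (length(lab) == 0 || length(unique(lab)) < 2) {
    stop("'labels' must be nonempty and contain both classes")
  }
  if (n_models < 1) stop("'n_models' must be >= 1")
  stopifnot(discrimination >= 0, model_noise_sd >= 0)
  rng <- local_rng(seed)
  n <- length(lab)
  u <- ifelse(lab == "mutant", -0.5, -2)
  e <- matrix(stats::rnorm(n_models * n, sd = model_noise_sd), n_models, n)
  p <- stats::plogis(sweep(e, 2, discrimination * u, `+`))
  sample_ids <- names(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("s_%04d", seq_len(n))
  dimnames(p) <- list(sprintf("m_%02d", seq_len(n_models)), sample_ids)
  p
}

#' Simulate a textured ellipsoidal tumor volume
#'
#' Builds a 3D intensity grid plus binary segmentation mask: the mask is a
#' discretized ellipsoid centered in the grid, intensities inside the mask
#' are a smooth radially decreasing base profile plus Gaussian texture noise
#' of standard deviation `texture_sd`, and the background outside the mask
#' is a constant.
#'
#' @param shape integer grid extent `(nx, ny, nz)`.
#' @param axes ellipsoid semi-axes in voxels, each >= 1; the ellipsoid must
#'   fit inside the grid.
#' @param texture_sd standard deviation of intensity texture inside the
#'   mask (>= 0).
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param base_intensity,background intensity of the tumor core and of the
#'   background.
#' @param profile `"flat"` (constant base, so `texture_sd = 0` gives a
#'   perfectly homogeneous tumor) or `"radial"` (base falls off towards
#'   the rim, mimicking a denser core).
#' @param seed integer seed.
#' @return A [tumor_volume()].
#' @examples
#' vol <- simulate_tumor_volume(axes = c(10, 10, 10), seed = 1)
#' sum(vol$mask)
#' @export
simulate_tumor_volume <- function(shape = c(48, 48, 48), axes = c(12, 10, 8),
                                  texture_sd = 10, spacing = c(1, 1, 1),
                                  base_intensity = 100, background = -100,
                                  profile = c("flat", "radial"), seed = 1) {
  profile <- match.arg(profile)
  stopifnot(length(shape) == 3, length(axes) == 3)
  if (any(axes < 1)) stop("every semi-axis must be at least 1 voxel")
  if (any(2 * axes + 1 > shape)) stop("ellipsoid does not fit inside the grid")
  rng <- local_rng(seed)
  center <- (shape + 1) / 2
  cx <- (seq_len(shape[1]) - center[1]) / axes[1]
  cy <- (seq_len(shape[2]) - center[2]) / axes[2]
  cz <- (seq_len(shape[3]) - center[3]) / axes[3]
  # normalized squared ellipsoidal radius on the full grid
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  mask <- r2 <= 1
  img <- array(background, dim = shape)
  base <- if (profile == "radial") {
    base_intensity * (1 - 0.5 * r2[mask])
  } else {
    base_intensity
  }
  img[mask] <- base + stats::rnorm(sum(mask), sd = texture_sd)
  tumor_volume(img, mask, spacing = spacing)
}

# Seed scoping: set the RNG locally, restoring the caller's state when the
# *calling* function exits (the restore expression is registered in its frame).
local_rng <- function(seed, envir = parent.frame()) {
  restore <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call("on.exit", list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}
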