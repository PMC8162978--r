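#' Shape features of a segmented tumor
#'
#' From the spacing-weighted covariance of the masked voxel coordinates
#' with eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}:
#' * `flatness` = \eqn{\sqrt{\lambda_3/\lambda_1}} (1 for a sphere, small
#'   for a pancake);
#' * `asymmetry` = \eqn{1 - \sqrt{\mu_2/\mu_1}} computed from the 2D
#'   coordinate covariance of the largest-area axial slice (0 for a
#'   circular cross-section) — kept two-dimensional so it measures
#'   something flatness does not;
#' * `orientation_deg` = angle in degrees, in \[0, 90\], between the
#'   principal (\eqn{\lambda_1}) eigenvector and the z axis;
#' * `surface_to_volume` = surface area / volume in physical units. The
#'   surface is estimated from exposed voxel faces with the isotropic
#'   (Crofton-type) 2/3 normalization, so a digital sphere of radius r
#'   comes out near the analytic 3/r rather than the 4.5/r a raw face
#'   count converges to.
#'
#' @param volume a [tumor_volume()] with at least 4 masked voxels and a
#'   non-degenerate coordinate covariance.
#' @return Named numeric vector `flatness`, `asymmetry`,
#'   `orientation_deg`, `surface_to_volume`.
#' @export
shape_features <- function(volume) {
  stopifnot(inherits(volume, "tumor_volume"))
  d <- dim(volume$mask)
  idx <- which(volume$mask)
  if (length(idx) < 4) stop("degenerate mask: need at least 4 voxels")
  sp <- volume$spacing
  co <- arrayInd(idx, d)
  phys <- sweep(co, 2, sp, `*`)
  cv <- stats::cov(phys)
  eg <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  if (lambda[1] <= 0) stop("degenerate mask: zero principal variance")
  flatness <- sqrt(lambda[3] / lambda[1])
  v1 <- eg$vectors[, 1]
  orientation <- acos(min(1, abs(v1[3]))) * 180 / pi

  areas <- tabulate(co[, 3], nbins = d[3])
  zc <- which.max(areas)                      # ties -> lowest z
  sl <- co[co[, 3] == zc, 1:2, drop = FALSE]
  if (nrow(sl) < 3) {
    asymmetry <- NA_real_
  } else {
    cv2 <- stats::cov(sweep(sl, 2, sp[1:2], `*`))
    mu <- pmax(eigen(cv2, symmetric = TRUE, only.values = TRUE)$values, 0)
    asymmetry <- if (mu[1] > 0) 1 - sqrt(mu[2] / mu[1]) else NA_real_
  }

  surf <- (2 / 3) * exposed_face_area(volume$mask, sp)
  vol <- length(idx) * prod(sp)
  c(flatness = flatness, asymmetry = asymmetry,
    orientation_deg = orientation, surface_to_volume = surf / vol)
}

# total area of mask voxel faces exposed to background (or grid boundary)
exposed_face_area <- function(mask, sp) {
  d <- dim(mask)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    mp <- aperm(mask, perm)
    n <- dim(mp)[1]
    x <- matrix(mp, nrow = n)
    pad <- matrix(FALSE, 1, ncol(x))
    xp <- rbind(pad, x, pad)
    exposed <- sum(x & !xp[seq_len(n), , drop = FALSE]) +
      sum(x & !xp[2 + seq_len(n), , drop = FALSE])
    total <- total + exposed * face_area[axis]
  }
  total
}

#' Histogram features of the masked intensities
#'
#' Order statistics of the intensities inside the mask. Percentiles use
#' linear interpolation between closest ranks (the default convention of
#' [stats::quantile()], type 7).
#'
#' @param volume a [tumor_volume()].
#' @return Named numeric vector `mean`, `sd`, `p10`, `p50`, `p90`.
#' @export
histogram_features <- function(volume) {
  stopifnot(inherits(volume, "tumor_volume"))
  x <- volume$img[volume$mask]
  q <- stats::quantile(x, probs = c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    p10 = q[1], p50 = q[2], p90 = q[3])
}

#' Extract the full radiomic feature vector of a tumor volume
#'
#' Concatenates the histogram, GLSZM, run-length, Laws, wavelet and shape
#' families into one named vector (one row of a feature table). Feature
#' names are stable: `hist_*`, `glszm_*`, `glrlm_avg_gln`, `laws_*`,
#' `wavelet_*`, `shape_*`.
#'
#' @param volume a [tumor_volume()].
#' @param n_levels grey levels used for texture quantization (default 32).
#' @param families character vector selecting feature families; any of
#'   `"histogram"`, `"glszm"`, `"glrlm"`, `"laws"`, `"wavelet"`, `"shape"`.
#' @return Named numeric vector; all values finite for a valid volume.
#' @export
extract_features <- function(volume, n_levels = 32,
                             families = c("histogram", "glszm", "glrlm",
                                          "laws", "wavelet", "shape")) {
  stopifnot(inherits(volume, "tumor_volume"))
  families <- match.arg(families, several.ok = TRUE)
  out <- numeric(0)
  if (any(families %in% c("glszm", "glrlm"))) {
    q <- quantize(volume, n_levels)
  }
  if ("histogram" %in% families) {
    h <- histogram_features(volume)
    names(h) <- paste0("hist_", names(h))
    out <- c(out, h)
  }
  if ("glszm" %in% families) {
    g <- glszm_features(glszm(q, volume$mask))
    names(g) <- paste0("glszm_", names(g))
    out <- c(out, g)
  }
  if ("glrlm" %in% families) {
    out <- c(out, glrlm_avg_gln = unname(glrlm_gln(q, volume$mask)))
  }
  if ("laws" %in% families) out <- c(out, laws_energy_3d(volume))
  if ("wavelet" %in% families) out <- c(out, wavelet_energy_3d(volume))
  if ("shape" %in% families) {
    s <- shape_features(volume)
    names(s) <- paste0("shape_", names(s))
    out <- c(out, s)
  }
  out
}
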