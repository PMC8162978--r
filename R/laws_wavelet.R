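#' 3D Laws texture energies
#'
#' Applies all 125 separable outer products of the five 1D Laws kernels
#' L5 (level), E5 (edge), S5 (spot), R5 (ripple), W5 (wave) to the volume
#' and reports, for each filter, the mean absolute response over the masked
#' voxels. Filtering is separable cross-correlation with zero padding at
#' the grid borders; every kernel except L5 sums to zero, so filters with
#' at least one non-L5 component annihilate constant regions.
#'
#' @param volume a [tumor_volume()]; each axis must exceed the kernel
#'   length (5).
#' @return Named numeric vector of 125 energies, named
#'   `laws_<X><Y><Z>` (e.g. `laws_L5E5S5` for L5 along x, E5 along y,
#'   S5 along z).
#' @export
laws_energy_3d <- function(volume) {
  stopifnot(inherits(volume, "tumor_volume"))
  if (any(dim(volume$img) <= 5)) stop("volume smaller than the 5-voxel kernel")
  kernels <- list(
    L5 = c(1, 4, 6, 4, 1),
    E5 = c(-1, -2, 0, 2, 1),
    S5 = c(-1, 0, 2, 0, -1),
    R5 = c(1, -4, 6, -4, 1),
    W5 = c(-1, 2, 0, -2, 1)
  )
  kn <- names(kernels)
  # build responses incrementally: x-axis (5), then y (25), then z (125)
  rx <- lapply(kernels, function(k) conv_axis(volume$img, k, 1))
  out <- numeric(0)
  msk <- volume$mask
  for (ix in kn) {
    rxy <- lapply(kernels, function(k) conv_axis(rx[[ix]], k, 2))
    for (iy in kn) {
      for (iz in kn) {
        resp <- conv_axis(rxy[[iy]], kernels[[iz]], 3)
        out[paste0("laws_", ix, iy, iz)] <- mean(abs(resp[msk]))
      }
    }
  }
  out
}

# 1D cross-correlation along one axis of a 3D array, zero-padded, "same" size
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- prod(dim(ap)[2:3])
  x <- matrix(ap, nrow = n, ncol = m)
  half <- (length(kern) - 1) / 2
  xp <- rbind(matrix(0, half, m), x, matrix(0, half, m))
  y <- matrix(0, n, m)
  for (k in seq_along(kern)) {
    y <- y + kern[k] * xp[(k - 1) + seq_len(n), , drop = FALSE]
  }
  aperm(array(y, dim = dim(ap)), order(perm))
}

#' 3D Haar wavelet subband energies
#'
#' One-level separable 3D Haar decomposition into the eight subbands
#' LLL..HHH (L = approximation, H = detail; axis order x, y, z), using the
#' orthonormal Haar pair \eqn{(1/\sqrt2)(1, 1)} and \eqn{(1/\sqrt2)(1, -1)}
#' with downsampling by two. Odd axes are extended by replicating the last
#' sample. The energy of a subband is the mean squared coefficient over the
#' mask-covered region (a coefficient is covered when any voxel of its
#' 2x2x2 support is masked).
#'
#' @param volume a [tumor_volume()] with each axis >= 2 voxels.
#' @return Named numeric vector of 8 energies `wavelet_LLL` ... `wavelet_HHH`.
#' @export
wavelet_energy_3d <- function(volume) {
  stopifnot(inherits(volume, "tumor_volume"))
  if (any(dim(volume$img) < 2)) stop("degenerate axis: each axis needs >= 2 voxels")
  cur <- stats::setNames(list(volume$img), "")
  for (axis in 1:3) {
    nxt <- list()
    for (i in seq_along(cur)) {
      h <- haar_axis(cur[[i]], axis)
      nxt[[2 * i - 1]] <- h$low
      nxt[[2 * i]] <- h$high
      names(nxt)[(2 * i - 1):(2 * i)] <- paste0(names(cur)[i], c("L", "H"))
    }
    cur <- nxt
  }
  cover <- mask_cover(volume$mask)
  out <- vapply(cur, function(b) mean(b[cover]^2), numeric(1))
  names(out) <- paste0("wavelet_", names(cur))
  out
}

# one-level Haar split along an axis (replicate-pad odd lengths)
haar_axis <- function(a, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- prod(dim(ap)[2:3])
  x <- matrix(ap, nrow = n, ncol = m)
  if (n %% 2 == 1) {
    x <- rbind(x, x[n, , drop = FALSE])
    n <- n + 1
  }
  odd <- x[seq(1, n, by = 2), , drop = FALSE]
  even <- x[seq(2, n, by = 2), , drop = FALSE]
  newd <- c(n / 2, dim(ap)[2:3])
  list(
    low = aperm(array((odd + even) / sqrt(2), dim = newd), order(perm)),
    high = aperm(array((odd - even) / sqrt(2), dim = newd), order(perm))
  )
}

# half-resolution cover of the mask: TRUE where any voxel of the 2x2x2
# support block is masked
mask_cover <- function(mask) {
  m <- mask
  for (axis in 1:3) {
    d <- dim(m)
    perm <- c(axis, setdiff(1:3, axis))
    mp <- aperm(m, perm)
    n <- dim(mp)[1]
    x <- matrix(mp, nrow = n)
    if (n %% 2 == 1) {
      x <- rbind(x, x[n, , drop = FALSE])
      n <- n + 1
    }
    y <- x[seq(1, n, by = 2), , drop = FALSE] | x[seq(2, n, by = 2), , drop = FALSE]
    m <- aperm(array(y, dim = c(n / 2, dim(mp)[2:3])), order(perm))
  }
  m
}
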