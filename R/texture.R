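#' Grey-level size-zone matrix (GLSZM)
#'
#' Counts connected zones of equal grey level by size. Entry `(g, s)` of the
#' matrix is the number of connected zones of level `g` and size `s` voxels.
#' Connectivity is 26 (faces, edges and corners) in 3D and 8 in 2D; a 2D
#' grid is any grid with a singleton third extent.
#'
#' @param quantized integer array of grey levels in `0..n_levels`
#'   (0 = outside mask), as produced by [quantize()]; a 2D matrix is
#'   treated as a single-slice 3D grid.
#' @param mask logical array of the same extent; defaults to
#'   `quantized > 0`.
#' @param connectivity 26 (3D) or 8 (2D).
#' @return A `texture_matrix`: list with `counts` (levels x sizes), `n_levels`
#'   and `kind = "GLSZM"`. The counts sum to the total number of zones.
#' @export
glszm <- function(quantized, mask = NULL, connectivity = 26) {
  quantized <- as_grid3d(quantized)
  if (is.null(mask)) mask <- quantized > 0L
  mask <- as_grid3d(mask)
  if (!identical(dim(quantized), dim(mask))) {
    stop("grid and mask extents differ")
  }
  if (!connectivity %in% c(8, 26)) stop("connectivity must be 8 or 26")
  if (connectivity == 8 && dim(quantized)[3] != 1) {
    stop("8-connectivity applies to 2D grids only")
  }
  q <- quantized
  q[!mask] <- 0L
  levels_present <- sort(unique(q[q > 0L]))
  if (length(levels_present) == 0) stop("mask is empty")
  n_levels <- max(levels_present)
  zone <- lapply(levels_present, function(g) zone_sizes(q == g))
  max_size <- max(unlist(zone))
  counts <- matrix(0L, nrow = n_levels, ncol = max_size,
                   dimnames = list(level = seq_len(n_levels),
                                   size = seq_len(max_size)))
  for (i in seq_along(levels_present)) {
    tab <- tabulate(zone[[i]], nbins = max_size)
    counts[levels_present[i], ] <- as.integer(tab)
  }
  structure(list(counts = counts, n_levels = n_levels, kind = "GLSZM"),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("%s: %d grey levels, %d zones/runs\n", x$kind,
              x$n_levels, sum(x$counts)))
  invisible(x)
}

# Sizes of 26-connected components of a logical 3D array.
# BFS over a zero-padded copy so neighbour offsets never wrap.
zone_sizes <- function(sel) {
  d <- dim(sel)
  pd <- d + 2L
  p <- array(FALSE, dim = pd)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sel
  seeds <- which(p)
  if (length(seeds) == 0) return(integer(0))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  remaining <- p
  sizes <- integer(0)
  for (s in seeds) {
    if (!remaining[s]) next
    remaining[s] <- FALSE
    frontier <- s
    size <- 0L
    while (length(frontier) > 0) {
      size <- size + length(frontier)
      cand <- unique(rep(frontier, each = length(loff)) + loff)
      cand <- cand[remaining[cand]]
      remaining[cand] <- FALSE
      frontier <- cand
    }
    sizes <- c(sizes, size)
  }
  sizes
}

as_grid3d <- function(a) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (length(dim(a)) != 3) stop("expected a 2D or 3D grid")
  a
}

#' GLSZM summary features
#'
#' Standard size-zone statistics from a [glszm()] matrix, with
#' `p(g,s) = counts(g,s) / N_z` and `N_z` the total zone count:
#' grey-level variance `GLV = sum p(g,s) (g - mu)^2` with
#' `mu = sum p(g,s) g`; small-zone low-grey-level emphasis
#' `SZLGE = sum p(g,s) / (g^2 s^2)`; grey-level non-uniformity
#' `GLN = sum_g (sum_s counts(g,s))^2 / N_z`.
#'
#' @param m a `texture_matrix` from [glszm()].
#' @return Named numeric vector with elements `grey_level_variance`,
#'   `small_zone_low_grey_level_emphasis`, `grey_level_non_uniformity`.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"))
  counts <- m$counts
  nz <- sum(counts)
  if (nz < 1) stop("texture matrix has zero total count")
  g <- as.numeric(seq_len(nrow(counts)))
  s <- as.numeric(seq_len(ncol(counts)))
  p <- counts / nz
  mu <- sum(p * g)                    # g recycles down columns
  glv <- sum(p * (g - mu)^2)
  szlge <- sum(sweep(p / g^2, 2, s^2, `/`))
  gln <- sum(rowSums(counts)^2) / nz
  c(grey_level_variance = glv,
    small_zone_low_grey_level_emphasis = szlge,
    grey_level_non_uniformity = gln)
}

#' Average run-length grey-level non-uniformity (GLRLM GLN)
#'
#' Computes the grey-level run-length matrix separately for each direction
#' (13 unique directions in 3D, 4 in 2D), evaluates grey-level
#' non-uniformity `GLN = sum_g (sum_r counts(g,r))^2 / N_runs` per
#' direction, and averages over directions. Runs are maximal straight
#' stretches of equal grey level within the mask.
#'
#' @inheritParams glszm
#' @return Named numeric vector with element `avg_gln`.
#' @export
glrlm_gln <- function(quantized, mask = NULL) {
  quantized <- as_grid3d(quantized)
  if (is.null(mask)) mask <- quantized > 0L
  mask <- as_grid3d(mask)
  if (!identical(dim(quantized), dim(mask))) stop("grid and mask extents differ")
  if (!any(mask)) stop("mask is empty")
  d <- dim(quantized)
  dirs <- run_directions(two_d = d[3] == 1)
  idx <- which(mask)
  ci <- arrayInd(idx, d)
  lev <- quantized[idx]
  gln_dir <- vapply(seq_len(nrow(dirs)), function(k) {
    o <- dirs[k, ]
    step <- sum(o^2)
    t <- drop(ci %*% o)
    # line key: projection of the coordinate onto the plane orthogonal to o
    lk <- ci * step - outer(t, o)
    ord <- order(lk[, 1], lk[, 2], lk[, 3], t)
    same_line <- c(FALSE, diff(lk[ord, 1]) == 0 & diff(lk[ord, 2]) == 0 &
                     diff(lk[ord, 3]) == 0)
    contiguous <- c(FALSE, diff(t[ord]) == step)
    same_level <- c(FALSE, diff(lev[ord]) == 0)
    run_id <- cumsum(!(same_line & contiguous & same_level))
    run_level <- lev[ord][!duplicated(run_id)]
    n_runs <- max(run_id)
    sum(tabulate(run_level)^2) / n_runs
  }, numeric(1))
  c(avg_gln = mean(gln_dir))
}

# Unique run/offset directions up to sign: 13 in 3D, 4 in 2D (z frozen).
run_directions <- function(two_d = FALSE) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = if (two_d) 0 else -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep one representative of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(o) o[match(TRUE, o != 0)] > 0)
  g[keep, , drop = FALSE]
}
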