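#' Grey-level quantization inside the tumor mask
#'
#' Bins the masked intensities into `1..n_levels` by equal-width bins over
#' the masked intensity range. Bins are right-closed: with range
#' `[lo, hi]` and width `w = (hi - lo)/n_levels`, a value `x` maps to level
#' `ceiling((x - lo)/w)`, and `x = lo` maps to level 1. A constant region
#' (zero range) maps entirely to level 1. Voxels outside the mask are
#' assigned level 0.
#'
#' @param volume a [tumor_volume()].
#' @param n_levels number of grey levels (>= 2); 32 is a common radiomics
#'   default and the default here.
#' @return Integer array of the volume's extent with levels in
#'   `0..n_levels` (0 = outside mask).
#' @export
quantize <- function(volume, n_levels = 32) {
  stopifnot(inherits(volume, "tumor_volume"), n_levels >= 2)
  x <- volume$img[volume$mask]
  lo <- min(x)
  hi <- max(x)
  q <- array(0L, dim = dim(volume$img))
  if (hi == lo) {
    q[volume$mask] <- 1L
    return(q)
  }
  lev <- ceiling((x - lo) / (hi - lo) * n_levels)
  lev[lev < 1L] <- 1L
  lev[lev > n_levels] <- n_levels
  q[volume$mask] <- as.integer(lev)
  q
}
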