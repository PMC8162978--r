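#' Select tumor ROI slices from a segmented volume
#'
#' Implements the image-branch slice selection: the axial slice with the
#' largest tumor area is the central slice (ties go to the lowest z); the
#' slices at `z +/- offset` are candidates (immediately adjacent slices
#' are skipped as too similar to the central one), and a candidate is
#' discarded when its tumor area falls below `min_area_fraction` of the
#' central area (no clear piece of tumor). Each kept slice is cropped to a
#' `size x size` ROI centered on that slice's mask centroid, padded with
#' `pad_value` where the crop overruns the grid.
#'
#' @param volume a [tumor_volume()] with nonempty mask.
#' @param offset slice offset from the central slice (default 2).
#' @param min_area_fraction minimum candidate area as a fraction of the
#'   central slice's area (default 0.1).
#' @param size ROI side length in pixels (default 128).
#' @param pad_value intensity used outside the grid; defaults to the
#'   minimum intensity of the volume.
#' @return A list of 1 to 3 ROIs ordered by z; each is a list with `img`
#'   and `mask` (`size x size` matrices) and `z` (slice index).
#' @export
select_slices <- function(volume, offset = 2, min_area_fraction = 0.1,
                          size = 128, pad_value = NULL) {
  stopifnot(inherits(volume, "tumor_volume"))
  if (is.null(pad_value)) pad_value <- min(volume$img)
  d <- dim(volume$mask)
  areas <- vapply(seq_len(d[3]), function(z) sum(volume$mask[, , z]), integer(1))
  zc <- which.max(areas)                 # ties -> lowest z
  zs <- zc
  for (z in c(zc - offset, zc + offset)) {
    if (z >= 1 && z <= d[3] && areas[z] >= min_area_fraction * areas[zc] &&
        areas[z] > 0) {
      zs <- c(zs, z)
    }
  }
  zs <- sort(unique(as.integer(zs)))
  lapply(zs, function(z) {
    msk <- volume$mask[, , z]
    cen <- round(colMeans(which(msk, arr.ind = TRUE)))
    half <- floor(size / 2)
    rows <- (cen[1] - half + 1):(cen[1] - half + size)
    cols <- (cen[2] - half + 1):(cen[2] - half + size)
    crop <- function(a, fill) {
      out <- matrix(fill, size, size)
      rin <- rows >= 1 & rows <= d[1]
      cin <- cols >= 1 & cols <= d[2]
      out[rin, cin] <- a[rows[rin], cols[cin]]
      out
    }
    list(img = crop(volume$img[, , z], pad_value),
         mask = crop(msk, FALSE), z = z)
  })
}

#' Patient-grouped stratified train/validation/test split
#'
#' Assigns whole patients to the training, validation and test sets so
#' that no patient contributes samples to more than one set — every slice
#' or sample of a patient inherits the patient's assignment. Within each
#' label class, patients are shuffled under `seed` and allotted to the
#' three sets in the given proportions (largest-remainder rounding), so
#' the split is label-stratified whenever class counts permit.
#'
#' @param patient_ids patient identifiers (one entry per patient).
#' @param labels per-patient labels (`"mutant"`/`"wildtype"` conventions
#'   of [feature_table()]).
#' @param fractions train/validation/test fractions summing to 1;
#'   default `c(0.65, 0.15, 0.20)`.
#' @param seed integer seed.
#' @return A `data.frame` with `patient_id` and `split` (factor
#'   `train`/`validation`/`test`).
#' @export
grouped_split <- function(patient_ids, labels,
                          fractions = c(0.65, 0.15, 0.20), seed = 1) {
  if (length(patient_ids) < 5) stop("need at least 5 patients")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stop("'fractions' must be three values summing to 1")
  }
  if (anyDuplicated(patient_ids)) stop("'patient_ids' must be unique")
  y <- as_mutation_label(labels)
  if (length(y) != length(patient_ids)) stop("one label per patient required")
  rng <- local_rng(seed)
  split_names <- c("train", "validation", "test")
  out <- character(length(patient_ids))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    nc <- length(idx)
    if (nc == 0) next
    counts <- diff(c(0, round(cumsum(fractions) * nc)))
    # every set gets at least one patient of the class when counts permit
    while (nc >= 3 && any(counts == 0)) {
      counts[which.max(counts)] <- max(counts) - 1
      counts[which.min(counts)] <- min(counts) + 1
    }
    out[idx] <- rep(split_names, counts)
  }
  data.frame(patient_id = as.character(patient_ids),
             split = factor(out, levels = split_names))
}
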