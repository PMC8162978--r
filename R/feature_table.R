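#' Labelled radiomic feature tables
#'
#' A feature table is a `data.frame` holding one row per sample with the
#' metadata columns `sample_id`, `patient_id`, `label` and (optionally)
#' `synthetic`, followed by numeric feature columns. The label is a factor
#' with levels `c("wildtype", "mutant")`; `"mutant"` is always the positive
#' (minority) class, mirroring mutation-status prediction where mutant
#' tumors are rare.
#'
#' @param features numeric matrix or data.frame of features (samples x
#'   features). Column names are kept; unnamed columns are named
#'   `f_0001`, `f_0002`, ...
#' @param labels character or factor vector of `"mutant"` / `"wildtype"`
#'   labels, one per row of `features`.
#' @param sample_id,patient_id optional identifier vectors; defaults are
#'   `s_0001`... with one patient per sample.
#' @param synthetic logical vector flagging rows created by oversampling;
#'   defaults to `FALSE`.
#' @return A `data.frame` of class `feature_table`.
#' @export
feature_table <- function(features, labels, sample_id = NULL,
                          patient_id = NULL, synthetic = FALSE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  n <- nrow(features)
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    names(features) <- sprintf("f_%04d", seq_len(ncol(features)))
  }
  labels <- as_mutation_label(labels)
  if (length(labels) != n) {
    stop("'labels' must have one entry per sample")
  }
  if (is.null(sample_id)) sample_id <- sprintf("s_%04d", seq_len(n))
  if (is.null(patient_id)) patient_id <- sample_id
  if (anyNA(patient_id)) stop("patient ids must be non-missing")
  synthetic <- rep_len(as.logical(synthetic), n)
  out <- data.frame(
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    label = labels,
    synthetic = synthetic,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, features)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  p <- length(feature_names(x))
  cnt <- table(x$label)
  cat(sprintf(
    "feature_table: %d samples x %d features (%d mutant / %d wildtype%s)\n",
    nrow(x), p, cnt[["mutant"]], cnt[["wildtype"]],
    if (any(x$synthetic)) sprintf(", %d synthetic", sum(x$synthetic)) else ""
  ))
  invisible(x)
}

# canonical label factor; accepts factors, characters, or 0/1 (1 = mutant)
as_mutation_label <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    labels <- ifelse(as.numeric(labels) != 0, "mutant", "wildtype")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("mutant", "wildtype"))
  if (length(bad) > 0) {
    stop("labels must be 'mutant' or 'wildtype', got: ",
         paste(bad, collapse = ", "))
  }
  factor(labels, levels = c("wildtype", "mutant"))
}

#' Feature column names of a feature table
#'
#' @param table a `feature_table` (or any data.frame using its column layout).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("sample_id", "patient_id", "label", "synthetic"))
}

#' Numeric feature matrix of a feature table
#'
#' @inheritParams feature_names
#' @return Numeric matrix (samples x features) with sample ids as rownames.
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(table[, feature_names(table), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

is_minority <- function(table) table$label == "mutant"

#' Read / write feature tables as CSV
#'
#' The CSV layout is `sample_id, patient_id, label, synthetic, <features...>`
#' with `label` in `{mutant, wildtype}`.
#'
#' @param path file path.
#' @return `read_feature_table` returns a `feature_table`;
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "label")
  if (!all(req %in% names(df))) {
    stop("feature table CSV must contain columns: ", paste(req, collapse = ", "))
  }
  synth <- if ("synthetic" %in% names(df)) as.logical(df$synthetic) else FALSE
  feats <- df[, setdiff(names(df), c(req, "synthetic")), drop = FALSE]
  feature_table(feats, df$label, sample_id = df$sample_id,
                patient_id = df$patient_id, synthetic = synth)
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
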