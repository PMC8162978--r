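#' Classifier adapters
#'
#' The cross-validation pipeline treats classifiers as pluggable adapters:
#' a list with a `name`, a `fit(x, y, seed)` function returning a fitted
#' object (`x` numeric matrix, `y` logical, `TRUE` = mutant), and a
#' `score(model, x)` function returning mutant pseudo-probabilities in
#' \[0, 1\]. Adapters must be deterministic given `seed` and must only ever
#' see training rows in `fit`.
#'
#' Provided adapters:
#' * `adapter_centroid()` — nearest-centroid projection with a logistic
#'   squash; dependency-free and fully deterministic, the default for
#'   tests and simulations.
#' * `adapter_logistic()` — logistic regression via [stats::glm()].
#' * `adapter_rf()`, `adapter_svm()`, `adapter_nnet()` — random forest,
#'   SVM (RBF, probability outputs) and a single-hidden-layer neural net
#'   via the \pkg{randomForest}, \pkg{e1071} and \pkg{nnet} packages
#'   (Suggests; the adapter errors if the package is absent).
#'
#' @return A classifier adapter (list with `name`, `fit`, `score`).
#' @name adapters
NULL

#' @rdname adapters
#' @export
adapter_centroid <- function() {
  list(
    name = "centroid",
    fit = function(x, y, seed = 1) {
      mu1 <- colMeans(x[y, , drop = FALSE])
      mu0 <- colMeans(x[!y, , drop = FALSE])
      w <- mu1 - mu0
      z <- drop(x %*% w)
      s <- stats::sd(z)
      list(w = w, mid = (mean(z[y]) + mean(z[!y])) / 2,
           scale = if (is.na(s) || s == 0) 1 else s)
    },
    score = function(model, x) {
      stats::plogis((drop(x %*% model$w) - model$mid) / model$scale)
    }
  )
}

#' @rdname adapters
#' @export
adapter_logistic <- function() {
  list(
    name = "logistic",
    fit = function(x, y, seed = 1) {
      df <- as.data.frame(x)
      df$.y <- as.numeric(y)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    score = function(model, x) {
      p <- suppressWarnings(
        stats::predict(model, newdata = as.data.frame(x), type = "response"))
      pmin(pmax(unname(p), 0), 1)
    }
  )
}

#' @rdname adapters
#' @export
adapter_rf <- function() {
  list(
    name = "rf",
    fit = function(x, y, seed = 1) {
      need_pkg("randomForest")
      rng <- local_rng(seed)
      randomForest::randomForest(x, factor(y, levels = c(FALSE, TRUE)))
    },
    score = function(model, x) {
      unname(stats::predict(model, x, type = "prob")[, "TRUE"])
    }
  )
}

#' @rdname adapters
#' @export
adapter_svm <- function() {
  list(
    name = "svm",
    fit = function(x, y, seed = 1) {
      need_pkg("e1071")
      rng <- local_rng(seed)
      e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), probability = TRUE)
    },
    score = function(model, x) {
      p <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
      unname(p[, "TRUE"])
    }
  )
}

#' @rdname adapters
#' @export
#' @param size,decay hidden-layer size and weight decay for the neural net.
adapter_nnet <- function(size = 3, decay = 0.01) {
  list(
    name = "nnet",
    fit = function(x, y, seed = 1) {
      need_pkg("nnet")
      rng <- local_rng(seed)
      nnet::nnet(x, as.numeric(y), size = size, decay = decay,
                 maxit = 200, trace = FALSE)
    },
    score = function(model, x) {
      pmin(pmax(drop(stats::predict(model, x)), 0), 1)
    }
  )
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this adapter", call. = FALSE)
  }
}

#' Base-model configurations
#'
#' A base-model configuration names one point of the study grid: a feature
#' selector, a feature-set size, a classifier adapter, and whether SMOTE
#' balancing is applied to the training rows. The full study grid
#' (2 selectors x 4 feature-set sizes x 4 classifiers) yields a 32-model
#' bank.
#'
#' @param selector `"mann_whitney"` or `"relieff"`.
#' @param k number of selected features (typically 5, 10, 15 or 20).
#' @param adapter a classifier adapter (see [adapters]).
#' @param smote apply SMOTE to the training rows after selection?
#' @return A list of class `base_model_config`.
#' @export
base_model_config <- function(selector = c("mann_whitney", "relieff"),
                              k = 5, adapter = adapter_centroid(),
                              smote = TRUE) {
  selector <- match.arg(selector)
  structure(list(
    selector = selector, k = as.integer(k), adapter = adapter,
    smote = isTRUE(smote),
    name = sprintf("%s_k%02d_%s%s", selector, k, adapter$name,
                   if (smote) "_smote" else "")
  ), class = "base_model_config")
}

#' Default configuration grid
#'
#' Builds the cross of selectors, feature-set sizes and adapters used for a
#' base-model bank. The defaults give a small deterministic grid; pass four
#' adapters and `k_set = c(5, 10, 15, 20)` for the full 32-model design.
#'
#' @param selectors feature selectors to cross.
#' @param k_set feature-set sizes to cross.
#' @param adapters list of classifier adapters to cross.
#' @param smote apply SMOTE in every configuration?
#' @return List of [base_model_config()] objects.
#' @export
config_grid <- function(selectors = c("mann_whitney", "relieff"),
                        k_set = c(5, 10, 15, 20),
                        adapters = list(adapter_centroid()),
                        smote = TRUE) {
  out <- list()
  for (ad in adapters) {
    for (sel in selectors) {
      for (k in k_set) {
        out[[length(out) + 1]] <- base_model_config(sel, k, ad, smote)
      }
    }
  }
  out
}
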