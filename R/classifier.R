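#' Assemble a reference set for classifier training
#'
#' Pairs frame features with their ground-truth activity labels. A training
#' set must represent all seven classes; `pool_reference_sets()`
#' concatenates several children's sets into the basis of the general
#' model.
#'
#' @param features A [compute_features()] table (or plain data.frame
#'   containing the 12 feature columns).
#' @param labels Activity labels, one per frame.
#' @param child_id Identifier, or `"pooled"` for a combined set.
#' @return A `reference_set` object.
#' @export
reference_set <- function(features, labels, child_id) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  bad <- setdiff(unique(labels), activity_kinds())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  structure(list(child_id = child_id,
                 features = as.data.frame(features)[, feature_names()],
                 labels = factor(labels, levels = activity_kinds())),
            class = "reference_set")
}

#' @rdname reference_set
#' @param sets List of `reference_set` objects.
#' @export
pool_reference_sets <- function(sets) {
  reference_set(do.call(rbind, lapply(sets, `[[`, "features")),
                unlist(lapply(sets, function(s) as.character(s$labels))),
                child_id = "pooled")
}

#' Train an activity-classification model
#'
#' Fits a radial-basis-kernel support vector machine (one-vs-one multiclass
#' voting, via \pkg{e1071}) on the 12 frame features of a labelled
#' reference set. Features are standardized to the training set's mean and
#' standard deviation (a zero-spread feature gets unit scale); the
#' standardization is frozen into the model and re-applied at prediction
#' time. Defaults follow the common recommendation for this
#' implementation: `cost = 1` and kernel width `gamma = 1/12` (one over the
#' number of features).
#'
#' @param refset A [reference_set()]; must contain all seven classes with
#'   at least `min_per_class` frames each.
#' @param cost Regularization weight of the margin violations.
#' @param gamma RBF kernel width.
#' @param scope `"individual"` or `"general"` (metadata only).
#' @param min_per_class Minimum training frames per class.
#' @return An `activity_model` with elements `svm`, `center`, `scale`,
#'   `scope`, `child_id`, `hyperparameters`, `training_accuracy`.
#' @export
train_model <- function(refset, cost = 1, gamma = 1 / 12,
                        scope = c("individual", "general"),
                        min_per_class = 5L) {
  scope <- match.arg(scope)
  stopifnot(inherits(refset, "reference_set"))
  counts <- table(refset$labels)
  missing_cls <- names(counts)[counts == 0]
  if (length(missing_cls)) {
    stop("missing class in training data: ",
         paste(missing_cls, collapse = ", "))
  }
  if (any(counts < min_per_class)) {
    stop("each class needs at least ", min_per_class, " training frames")
  }
  x <- as.matrix(refset$features)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- e1071::svm(xs, refset$labels, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  acc <- mean(stats::predict(fit, xs) == refset$labels)
  message(sprintf("trained %s model (%s): training accuracy %.1f%% on %d frames",
                  scope, refset$child_id, 100 * acc, nrow(x)))
  structure(list(svm = fit, center = center, scale = scale, scope = scope,
                 child_id = refset$child_id,
                 hyperparameters = list(kernel = "radial", cost = cost,
                                        gamma = gamma),
                 training_accuracy = acc),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> %s (%s): RBF SVM, cost %g, gamma %g, %d SVs, training accuracy %.1f%%\n",
              x$scope, x$child_id, x$hyperparameters$cost,
              x$hyperparameters$gamma, nrow(x$svm$SV),
              100 * x$training_accuracy))
  invisible(x)
}

#' Select the model used to classify a child's free-living data
#'
#' Children who took part in the reference measurement are classified with
#' their own individual model; children who were absent are classified with
#' the general model trained on the pooled reference data of those who took
#' part.
#'
#' @param child_id Child to classify.
#' @param individual_models Named list of individual [train_model()] fits
#'   (names are child ids); may be empty.
#' @param general_model The pooled model; must exist.
#' @return An `activity_model`.
#' @export
select_model <- function(child_id, individual_models, general_model) {
  if (is.null(general_model)) stop("general model is required")
  if (!is.null(individual_models) && child_id %in% names(individual_models)) {
    individual_models[[child_id]]
  } else {
    general_model
  }
}

#' Classify frames into activity epochs
#'
#' Applies a trained model to a frame-feature table: the training
#' standardization is applied, each 12-vector gets exactly one of the seven
#' labels, and the result is returned on the feature table's epoch grid.
#'
#' @param model An [train_model()] fit.
#' @param features A [compute_features()] table (12 feature columns).
#' @param child_id Child id recorded on the output; defaults to the feature
#'   table's id.
#' @return A [labeled_epochs()] object, one label per frame, in input
#'   order.
#' @export
predict_epochs <- function(model, features, child_id = NULL) {
  stopifnot(inherits(model, "activity_model"))
  if (is.null(child_id)) child_id <- attr(features, "child_id")
  if (is.null(child_id)) child_id <- "unknown"
  fl <- attr(features, "frame_length")
  if (is.null(fl)) fl <- 2.5
  if (!all(feature_names() %in% names(features))) {
    stop("features must contain the 12 columns of feature_names()")
  }
  if (!nrow(features)) {
    return(labeled_epochs(character(0), as.POSIXct(character(0), tz = "UTC"),
                          character(0), epoch_seconds = fl))
  }
  x <- as.matrix(as.data.frame(features)[, feature_names()])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  labels <- as.character(stats::predict(model$svm, xs))
  start <- if ("start_time" %in% names(features)) features$start_time else
    as.POSIXct("1970-01-01", tz = "UTC") + (seq_len(nrow(features)) - 1) * fl
  labeled_epochs(child_id, start, labels, epoch_seconds = fl)
}

#' Nearest-centroid reference classifier
#'
#' A deliberately simple alternative classifier: standardize features to
#' the training set, average each class's training frames into a centroid,
#' and label new frames by the nearest centroid (Euclidean distance, ties
#' to the first class in canonical order). Useful as an independent
#' cross-check of the kernel classifier in clearly separable regimes.
#'
#' @inheritParams train_model
#' @return A function `(features) -> factor` of predicted labels.
#' @export
centroid_classifier <- function(refset) {
  x <- as.matrix(refset$features)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  cents <- sapply(activity_kinds(), function(k) {
    colMeans(xs[refset$labels == k, , drop = FALSE])
  })
  function(features) {
    z <- as.matrix(as.data.frame(features)[, feature_names()])
    zs <- sweep(sweep(z, 2, center), 2, scale, "/")
    d2 <- sapply(seq_len(ncol(cents)), function(j) {
      rowSums(sweep(zs, 2, cents[, j])^2)
    })
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    factor(activity_kinds()[apply(d2, 1, which.min)],
           levels = activity_kinds())
  }
}
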