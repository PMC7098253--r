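# Movement-intent classification: per-movement RBF-SVM decoders trained on
# block 1 features and evaluated on block 2, with per-bin accuracy,
# sensitivity and specificity metrics.

#' Label feature bins from a cue schedule
#'
#' A bin is labeled with a movement iff its start time lies within
#' `[onset + lag, onset + lag + duration)`; all other bins are `"rest"`.
#'
#' @param schedule A [cue_schedule()].
#' @param n_bins Number of bins to label.
#' @param bin_width Bin width, s (default 0.1).
#' @param lag Non-negative labeling lag, s (default 0).
#' @return Factor of length `n_bins` with levels `movements, "rest"`.
#' @export
label_bins <- function(schedule, n_bins, bin_width = 0.1, lag = 0) {
  stopifnot(inherits(schedule, "cue_schedule"))
  if (lag < 0) stop("lag must be non-negative")
  movements <- .task_movements[[schedule$task_id]]
  labels <- rep("rest", n_bins)
  starts <- (seq_len(n_bins) - 1) * bin_width
  for (i in seq_len(nrow(schedule$events))) {
    on <- schedule$events$onset_s[i] + lag
    off <- on + schedule$events$duration_s[i]
    hit <- starts >= on - 1e-9 & starts < off - 1e-9
    labels[hit] <- schedule$events$movement[i]
  }
  factor(labels, levels = c(movements, "rest"))
}

#' Train per-movement RBF-SVM decoders
#'
#' Fits one binary RBF-kernel support vector machine per movement
#' (movement versus everything else, rest and other movements pooled as
#' negatives) on training-block features. Decision values are oriented so
#' positive means "movement", and scaled by the maximum absolute
#' training-set decision value so scores lie in `[-1, 1]`.
#'
#' @param features Standardized [feature_series()] (or `feature_extract`,
#'   or plain bins x features matrix).
#' @param labels Factor from [label_bins()], aligned with the bins.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width (default `1 / n_features`).
#' @return An object of class `decoder_bundle`.
#' @export
train_decoders <- function(features, labels, cost = 1, gamma = NULL) {
  x <- .decode_matrix(features)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels))
    stop("features and labels must have the same number of bins")
  movements <- setdiff(levels(labels), "rest")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  models <- list()
  for (m in movements) {
    pos <- labels == m
    if (!any(pos)) stop("movement '", m, "' has no positive bins")
    if (all(pos)) stop("movement '", m, "' has no negative bins")
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    dv <- attr(predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    orient <- if (mean(dv[pos]) >= mean(dv[!pos])) 1 else -1
    models[[m]] <- list(fit = fit, orient = orient,
                        scale = max(abs(dv), 1e-12))
  }
  structure(list(movements = movements, models = models,
                 cost = cost, gamma = gamma, n_features = ncol(x)),
            class = "decoder_bundle")
}

#' @export
print.decoder_bundle <- function(x, ...) {
  cat(sprintf("<decoder_bundle> %d movement decoders (RBF SVM, C = %g, gamma = %.4g), %d features\n",
              length(x$movements), x$cost, x$gamma, x$n_features))
  invisible(x)
}

.decode_matrix <- function(features) {
  if (inherits(features, "feature_extract")) features <- features$series
  if (inherits(features, "feature_series")) {
    if (length(dim(features$values)) != 2)
      stop("decoder input must be a bins x features matrix")
    features$values
  } else as.matrix(features)
}

#' Predict movements from features
#'
#' Scores every bin with each movement's decoder (scaled to `[-1, 1]`); the
#' predicted label is the highest-scoring movement if its score exceeds
#' zero, otherwise rest.
#'
#' @param object A [train_decoders()] bundle.
#' @param features Test-block features (standardized with the training
#'   block's statistics).
#' @param ... Unused.
#' @return An object of class `decode_result`: factor `predicted` and a
#'   bins x movements `scores` matrix.
#' @export
predict.decoder_bundle <- function(object, features, ...) {
  x <- .decode_matrix(features)
  if (ncol(x) != object$n_features)
    stop("feature dimensionality (", ncol(x),
         ") does not match training (", object$n_features, ")")
  scores <- sapply(object$movements, function(m) {
    mod <- object$models[[m]]
    dv <- attr(predict(mod$fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    pmin(pmax(mod$orient * dv / mod$scale, -1), 1)
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(x))
  colnames(scores) <- object$movements
  best <- max.col(scores, ties.method = "first")
  pred <- ifelse(scores[cbind(seq_len(nrow(scores)), best)] > 0,
                 object$movements[best], "rest")
  structure(list(predicted = factor(pred,
                                    levels = c(object$movements, "rest")),
                 scores = scores, movements = object$movements),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d bins\n", length(x$predicted)))
  print(table(predicted = x$predicted))
  invisible(x)
}

#' Decoding performance metrics
#'
#' Per-bin metrics in percent. Overall accuracy is the fraction of bins
#' whose predicted label equals the true label. Per movement:
#' \describe{
#'   \item{accuracy}{agreement of the movement's binary decision
#'     (predicted-m versus not) with the truth, over all bins (default), or
#'     with `per_movement = "precision"` the fraction of bins predicted as
#'     the movement that are correct.}
#'   \item{sensitivity}{fraction of the movement's cued bins predicted as
#'     the movement.}
#'   \item{specificity}{fraction of bins where the movement is not cued
#'     that are not predicted as the movement (the true-negative rate of
#'     the movement's binary decision).}
#' }
#' Movements absent from the labels get `NA` sensitivity.
#'
#' @param result A [predict.decoder_bundle()] result (or a factor of
#'   predicted labels).
#' @param labels True labels from [label_bins()].
#' @param per_movement Per-movement accuracy definition: `"binary"`
#'   (default) or `"precision"`.
#' @return An object of class `decode_metrics`: `overall_accuracy` (percent)
#'   and data frame `per_movement`.
#' @export
compute_metrics <- function(result, labels,
                            per_movement = c("binary", "precision")) {
  per_movement <- match.arg(per_movement)
  pred <- if (inherits(result, "decode_result")) result$predicted
          else as.factor(result)
  labels <- as.factor(labels)
  if (length(pred) != length(labels))
    stop("predictions and labels are not aligned")
  movements <- setdiff(levels(labels), "rest")
  overall <- 100 * mean(as.character(pred) == as.character(labels))
  rows <- lapply(movements, function(m) {
    p <- pred == m; t <- labels == m
    acc <- if (per_movement == "binary") 100 * mean(p == t)
           else if (any(p)) 100 * sum(p & t) / sum(p) else NA_real_
    sens <- if (any(t)) 100 * sum(p & t) / sum(t) else NA_real_
    spec <- 100 * sum(!p & !t) / sum(!t)
    data.frame(movement = m, accuracy = acc, sensitivity = sens,
               specificity = spec)
  })
  structure(list(overall_accuracy = overall,
                 per_movement = do.call(rbind, rows),
                 n_bins = length(labels)),
            class = "decode_metrics")
}

#' @export
print.decode_metrics <- function(x, ...) {
  cat(sprintf("<decode_metrics> overall accuracy %.2f%% over %d bins\n",
              x$overall_accuracy, x$n_bins))
  print(x$per_movement, row.names = FALSE, digits = 4)
  invisible(x)
}
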