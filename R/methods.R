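# S3 methods for fitted encoder models.

#' @export
print.ecg_encoder_fit <- function(x, ...) {
  cat(sprintf("<ecg_encoder_fit: %s, %d classes (%s)>\n", x$method,
              length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  epochs run: %d; best validation accuracy %.3f at epoch %d\n",
              nrow(x$history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
summary.ecg_encoder_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("Encoder fit (%s objective)\n", object$method))
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  records: %d train / %d validation / %d test\n",
              length(object$splits$train), length(object$splits$validation),
              length(object$splits$test)))
  cat(sprintf("  epochs: %d (best at %d, patience %d)\n", nrow(h),
              object$best_epoch, object$config$patience))
  cat(sprintf("  final train loss %.4f; best validation accuracy %.3f\n",
              h$train_loss[nrow(h)], object$best_val_accuracy))
  invisible(object)
}

#' @export
coef.ecg_encoder_fit <- function(object, ...) object$weights

#' Predict from a fitted encoder
#'
#' @param object an `ecg_encoder_fit`.
#' @param newdata a `qrs_set` or a list of them.
#' @param type `"class"` (default), `"embedding"` (20 x n matrix), or
#'   `"scores"` (n x C matrix: negated center distances for few-shot fits,
#'   class probabilities for softmax fits).
#' @param ... unused.
#' @return per `type`.
#' @export
predict.ecg_encoder_fit <- function(object, newdata,
                                    type = c("class", "embedding", "scores"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(newdata, "qrs_set")) newdata <- list(newdata)
  emb <- embed_many(newdata, object$weights)
  if (type == "embedding") return(emb)
  if (object$method == "fsl") {
    res <- apply(emb, 2L, nearest_center_classify, centers = object$centers)
    if (type == "class")
      return(vapply(res, `[[`, character(1), "label"))
    t(vapply(res, `[[`, numeric(length(object$classes)), "scores"))
  } else {
    probs <- t(apply(emb, 2L, softmax_head, weights = object$weights))
    colnames(probs) <- object$classes
    if (type == "class")
      return(object$classes[max.col(probs, ties.method = "first")])
    probs
  }
}

#' Plot training history
#'
#' Training loss and validation accuracy per epoch, with the checkpointed
#' best epoch marked.
#'
#' @param x an `ecg_encoder_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecg_encoder_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = x$method, ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Residual-style diagnostics: margin violations on a dataset
#'
#' For a few-shot fit, returns for each record the difference between its
#' distance to its own class center and the distance to the nearest other
#' center (negative = correctly inside its class neighborhood).
#'
#' @param object an `ecg_encoder_fit` with method `"fsl"`.
#' @param newdata list of labeled `qrs_set`; default the fit's test split.
#' @param ... unused.
#' @return numeric vector of margins.
#' @export
residuals.ecg_encoder_fit <- function(object, newdata = NULL, ...) {
  if (object$method != "fsl")
    stop("residual margins are defined for few-shot fits")
  if (is.null(newdata)) newdata <- object$splits$test
  labs <- labels_of(newdata, object$config$label_field)
  emb <- embed_many(newdata, object$weights)
  vapply(seq_along(newdata), function(i) {
    d <- apply(object$centers$centers, 2L, euclidean_distance, y = emb[, i])
    own <- d[match(labs[i], object$centers$classes)]
    own - min(d[-match(labs[i], object$centers$classes)])
  }, numeric(1))
}
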