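#' @export
print.ednet_config <- function(x, ...) {
  cat(sprintf(
    "ednet configuration: width %.3g, %d classes, input %dx%d\n",
    x$width, x$num_classes, x$input_size, x$input_size))
  cat(sprintf(
    "  xception: %s%s | resnet kernel %dx%d, %s skip | norm: %s\n",
    if (x$separable_xception) "separable" else "dense",
    if (x$xception_projection_skip) " + projection skip" else "",
    x$resnet_kernel, x$resnet_kernel, x$resnet_skip,
    if (x$norm) "batch norm" else "none"))
  cat("  blocks:", paste(vapply(x$blocks, function(b) b$name, ""),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ednet <- function(x, ...) {
  r <- count_macs(x$config, input_size = x$config$input_size)
  cat(sprintf(
    "ednet network (seed %d): %d blocks, %s parameters, %.3f G MACs at %d\n",
    x$weight_init_seed, length(x$blocks),
    format(r$total_params, big.mark = ","), r$macs_g,
    x$config$input_size))
  invisible(x)
}

#' @export
summary.ednet <- function(object, ...) {
  print(object)
  summarize_network(object$config)
}

#' @export
coef.ednet <- function(object, ...) {
  p <- collect_params(object)
  names(p) <- vapply(object$blocks, function(b) b$spec$name, "")
  p
}

#' Predict method for networks and fits
#'
#' \code{newdata} may be a batch array (N, 3, H, W), a manifest data.frame
#' (its images are decoded at the network's input size) or a vector of image
#' paths. For a fit, the best-test-accuracy checkpoint is used.
#'
#' @param object an \code{"ednet"} or \code{"ednet_fit"}.
#' @param newdata batch array, manifest data.frame or character paths.
#' @param type \code{"prob"} (default) for class probabilities,
#'   \code{"class"} for predicted label names, \code{"logits"} for raw
#'   scores.
#' @param ... unused.
#' @return matrix of probabilities/logits, or character vector of classes.
#' @export
predict.ednet <- function(object, newdata, type = c("prob", "class", "logits"),
                          ...) {
  type <- match.arg(type)
  size <- object$config$input_size
  batch <- if (is.character(newdata)) {
    man <- data.frame(path = newdata, label = 0L)
    load_image_tensor(man, size = size)$x
  } else if (is.data.frame(newdata)) {
    load_image_tensor(newdata, size = size)$x
  } else newdata
  logits <- ednet_forward(object, batch)
  switch(type,
         logits = logits,
         prob = {
           p <- softmax_rows(logits)
           if (ncol(p) == 7L) colnames(p) <- eye_disease_classes()
           p
         },
         class = {
           cls <- if (object$config$num_classes == 7L) eye_disease_classes()
                  else as.character(seq_len(object$config$num_classes) - 1L)
           cls[max.col(logits, ties.method = "first")]
         })
}

#' @rdname predict.ednet
#' @export
predict.ednet_fit <- function(object, newdata,
                              type = c("prob", "class", "logits"), ...) {
  predict(object$best_net, newdata, type = type, ...)
}

#' @export
print.ednet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "ednet fit: %d epochs | final train acc %.3f, loss %.4f | best test acc %.3f (epoch %s)\n",
    nrow(h), h$train_acc[nrow(h)], h$train_loss[nrow(h)],
    max(h$test_acc, na.rm = TRUE),
    ifelse(is.na(x$best_epoch), "-", x$best_epoch)))
  invisible(x)
}

#' @export
summary.ednet_fit <- function(object, ...) {
  print(object)
  cat("\nHistory (first/last epochs):\n")
  h <- object$history
  print(utils::head(h, 3L), row.names = FALSE)
  if (nrow(h) > 3L) print(utils::tail(h, 3L), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.ednet_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot_history(x$history)
  invisible(x)
}

#' @export
coef.ednet_fit <- function(object, ...) coef(object$best_net, ...)
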