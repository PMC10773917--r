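#' Training hyperparameters
#'
#' The training recipe: SGD with classical momentum and coupled L2 weight
#' decay, cross-entropy loss, batch size 64, 100 epochs, initial learning
#' rate 0.01 decayed to 95% of its value after every epoch.
#'
#' @param batch_size images per SGD step (default 64).
#' @param epochs number of passes over the training split (default 100).
#' @param lr0 initial learning rate (default 0.01).
#' @param lr_decay multiplicative per-epoch decay factor in (0, 1]
#'   (default 0.95).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param weight_decay coupled L2 coefficient (default 4e-4).
#' @param seed integer seed controlling shuffling.
#' @return an object of class \code{"train_config"}.
#' @export
train_config <- function(batch_size = 64L, epochs = 100L, lr0 = 0.01,
                         lr_decay = 0.95, momentum = 0.9,
                         weight_decay = 4e-4, seed = 0L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr0 > 0,
            lr_decay > 0, lr_decay <= 1, momentum >= 0, momentum < 1,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay = lr_decay, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean cross-entropy loss
#'
#' Mean over samples of the negative log-probability the softmax assigns to
#' the true class, computed with the log-sum-exp trick so large logits
#' cannot overflow. With all-zero logits over C classes the loss is log(C).
#'
#' @param logits numeric matrix (N x C).
#' @param labels integer vector of 0-based class indices in [0, C).
#' @return non-negative scalar.
#' @examples
#' cross_entropy(matrix(0, 2, 7), c(0L, 3L))   # log(7)
#' @export
cross_entropy <- function(logits, labels) {
  stopifnot(is.matrix(logits), nrow(logits) == length(labels))
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= ncol(logits)))
    stop("cross_entropy: labels must lie in [0, ", ncol(logits), ")")
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels + 1L)])
}

# gradient of mean cross-entropy w.r.t. logits
cross_entropy_grad <- function(logits, labels) {
  p <- softmax_rows(logits)
  p[cbind(seq_len(nrow(logits)), as.integer(labels) + 1L)] <-
    p[cbind(seq_len(nrow(logits)), as.integer(labels) + 1L)] - 1
  p / nrow(logits)
}

#' Exponential learning-rate schedule
#'
#' Learning rate in force at a given 0-based epoch:
#' \code{lr0 * lr_decay^epoch}. The decay is applied once per epoch (a
#' per-batch reading of the 95% rule would collapse the rate to zero over
#' a full run).
#'
#' @param config a \code{\link{train_config}}.
#' @param epoch 0-based epoch index.
#' @return positive learning rate.
#' @examples
#' lr_schedule(train_config(), 0)   # 0.01
#' lr_schedule(train_config(), 1)   # 0.0095
#' @export
lr_schedule <- function(config, epoch) {
  stopifnot(all(epoch >= 0))
  config$lr0 * config$lr_decay^epoch
}

#' One SGD step with momentum and coupled weight decay
#'
#' Updates \code{v <- momentum * v + g + weight_decay * w} then
#' \code{w <- w - lr * v}, elementwise, recursively over (nested) lists of
#' numeric arrays. Classical (non-Nesterov) momentum; the decay term is
#' coupled into the gradient (L2 regularization), not decoupled.
#'
#' @param weights numeric array or (nested) list of arrays.
#' @param gradients matching structure of gradients.
#' @param velocity matching structure of velocities (use zeros initially).
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 coefficient.
#' @return list with updated \code{weights} and \code{velocity}.
#' @export
sgd_update <- function(weights, gradients, velocity, lr, momentum = 0.9,
                       weight_decay = 0) {
  if (is.list(weights)) {
    stopifnot(is.list(gradients), is.list(velocity),
              length(weights) == length(gradients),
              length(weights) == length(velocity))
    for (i in seq_along(weights)) {
      r <- sgd_update(weights[[i]], gradients[[i]], velocity[[i]], lr,
                      momentum, weight_decay)
      weights[[i]] <- r$weights
      velocity[[i]] <- r$velocity
    }
    return(list(weights = weights, velocity = velocity))
  }
  if (length(weights) != length(gradients) ||
      length(weights) != length(velocity))
    stop("sgd_update: shape mismatch between weights, gradients and velocity")
  v <- momentum * velocity + gradients + weight_decay * weights
  list(weights = weights - lr * v, velocity = v)
}

PARAM_FIELDS <- c("w", "b", "gamma", "beta")

layer_params <- function(layer) layer[intersect(PARAM_FIELDS, names(layer))]

collect_params <- function(net) {
  lapply(net$blocks, function(blk) {
    list(layers = lapply(blk$layers, layer_params),
         proj = if (!is.null(blk$skip_proj)) layer_params(blk$skip_proj))
  })
}

assign_params <- function(net, params) {
  for (bi in seq_along(net$blocks)) {
    for (li in seq_along(net$blocks[[bi]]$layers)) {
      p <- params[[bi]]$layers[[li]]
      for (f in names(p)) net$blocks[[bi]]$layers[[li]][[f]] <- p[[f]]
    }
    if (!is.null(net$blocks[[bi]]$skip_proj)) {
      p <- params[[bi]]$proj
      for (f in names(p)) net$blocks[[bi]]$skip_proj[[f]] <- p[[f]]
    }
  }
  net
}

zero_like <- function(x) {
  if (is.list(x)) return(lapply(x, zero_like))
  x * 0
}

# backward through one fused layer (conv/norm/act); returns dx and gradients
layer_backward <- function(layer, dy, cache) {
  s <- layer$spec
  g <- list()
  if (s$has_swish6) dy <- dy * swish6_grad(cache$act_in)
  if (s$norm) {
    r <- bn_backward(dy, cache$bn)
    dy <- r$dx; g$gamma <- r$dgamma; g$beta <- r$dbeta
  }
  if (s$kind == "conv") {
    r <- conv2d_backward(dy, layer$w, cache$conv)
    dy <- r$dx; g$w <- r$dw; if (s$bias) g$b <- r$db
  } else if (s$kind == "depthwise_conv") {
    r <- depthwise_backward(dy, layer$w, cache$conv)
    dy <- r$dx; g$w <- r$dw; if (s$bias) g$b <- r$db
  } else if (s$kind == "linear") {
    r <- linear_backward(dy, layer$w, cache$linear)
    dy <- r$dx; g$w <- r$dw; g$b <- r$db
  } else if (s$kind == "global_pool") {
    dy <- gap_backward(dy, cache$gap)
  }
  # order gradients like layer_params for structural alignment
  list(dx = dy, grads = g[intersect(PARAM_FIELDS, names(g))])
}

backward_pass <- function(net, caches, dlogits) {
  dy <- dlogits
  grads <- vector("list", length(net$blocks))
  for (bi in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[bi]]
    bc <- caches[[bi]]
    proj_grads <- NULL
    dskip <- NULL
    if (blk$spec$skip == "additive") {
      if (is.null(blk$skip_proj)) {
        dskip <- dy
      } else {
        r <- layer_backward(blk$skip_proj, dy, bc$proj)
        dskip <- r$dx; proj_grads <- r$grads
      }
    } else if (blk$spec$skip == "concat") {
      r <- layer_backward(blk$skip_proj, dy, bc$proj)
      proj_grads <- r$grads
      ch <- dim(r$dx)[4L] %/% 2L
      dy <- r$dx[, , , seq_len(ch), drop = FALSE]
      dskip <- r$dx[, , , ch + seq_len(ch), drop = FALSE]
    }
    lgrads <- vector("list", length(blk$layers))
    for (li in rev(seq_along(blk$layers))) {
      r <- layer_backward(blk$layers[[li]], dy, bc$layers[[li]])
      dy <- r$dx
      lgrads[[li]] <- r$grads
    }
    if (!is.null(dskip)) dy <- dy + dskip
    grads[[bi]] <- list(layers = lgrads, proj = proj_grads)
  }
  list(dx = dy, grads = grads)
}

update_running_stats <- function(net, caches) {
  for (bi in seq_along(net$blocks)) {
    for (li in seq_along(net$blocks[[bi]]$layers)) {
      rs <- caches[[bi]]$layers[[li]]$running
      if (!is.null(rs)) {
        net$blocks[[bi]]$layers[[li]]$running_mean <- rs$mean
        net$blocks[[bi]]$layers[[li]]$running_var <- rs$var
      }
    }
    rs <- caches[[bi]]$proj$running
    if (!is.null(rs)) {
      net$blocks[[bi]]$skip_proj$running_mean <- rs$mean
      net$blocks[[bi]]$skip_proj$running_var <- rs$var
    }
  }
  net
}

#' Train a network with SGD
#'
#' Runs the full training recipe on the train split of a manifest:
#' mini-batch SGD with momentum and L2 weight decay on the cross-entropy
#' loss, exponential per-epoch learning-rate decay, per-epoch train and test
#' accuracy tracking, and best-test-accuracy checkpointing. Fully
#' deterministic given the config seed and the network's init seed.
#'
#' All images are decoded once up front at the network's input size; the
#' loop itself touches only in-memory arrays.
#'
#' @param net an assembled \code{"ednet"}.
#' @param manifest dataset manifest with train and test splits.
#' @param config a \code{\link{train_config}}.
#' @param verbose print one line per epoch.
#' @return an object of class \code{"ednet_fit"}: \code{net} (final
#'   weights), \code{best_net} (highest test accuracy), \code{history}
#'   (data.frame: epoch, lr, train_loss, train_acc, test_acc),
#'   \code{config}, \code{best_epoch}.
#' @export
train_ednet <- function(net, manifest, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(net, "ednet"), inherits(config, "train_config"))
  if (!any(manifest$split == "train"))
    stop("train_ednet: manifest has no train split")
  size <- net$config$input_size
  tr <- load_image_tensor(manifest, size = size, split = "train")
  te <- if (any(manifest$split == "test"))
    load_image_tensor(manifest, size = size, split = "test")
  velocity <- zero_like(collect_params(net))
  history <- vector("list", config$epochs)
  best_acc <- -Inf; best_net <- net; best_epoch <- NA_integer_
  n <- dim(tr$x)[1L]
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(config, epoch)
    idx <- batch_indices(n, config$batch_size, config$seed, epoch)
    tot_loss <- 0; tot_correct <- 0L
    for (b in idx) {
      x <- nchw_to_hwcn(tr$x[b, , , , drop = FALSE])
      y <- tr$y[b]
      fwd <- forward_pass(net, x, training = TRUE, keep_cache = TRUE)
      net <- update_running_stats(net, fwd$caches)
      loss <- cross_entropy(fwd$out, y)
      if (!is.finite(loss))
        stop("train_ednet: non-finite loss at epoch ", epoch,
             " (learning rate ", lr, "); training diverged")
      tot_loss <- tot_loss + loss * length(b)
      tot_correct <- tot_correct +
        sum(max.col(fwd$out, ties.method = "first") - 1L == y)
      bwd <- backward_pass(net, fwd$caches, cross_entropy_grad(fwd$out, y))
      upd <- sgd_update(collect_params(net), bwd$grads, velocity, lr,
                        config$momentum, config$weight_decay)
      net <- assign_params(net, upd$weights)
      velocity <- upd$velocity
    }
    test_acc <- if (!is.null(te))
      evaluate_tensor(net, te$x, te$y)$accuracy else NA_real_
    history[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = tot_loss / n,
      train_acc = tot_correct / n, test_acc = test_acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  train %.3f  test %.3f",
                      epoch, lr, tot_loss / n, tot_correct / n, test_acc))
    if (!is.na(test_acc) && test_acc > best_acc) {
      best_acc <- test_acc; best_net <- net; best_epoch <- epoch
    }
  }
  structure(list(net = net, best_net = best_net, best_epoch = best_epoch,
                 history = do.call(rbind, history), config = config,
                 manifest_source = attr(manifest, "source")),
            class = "ednet_fit")
}

evaluate_tensor <- function(net, x, y, batch_size = 64L) {
  n <- dim(x)[1L]
  classes <- net$config$num_classes
  pred <- integer(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    logits <- forward_pass(net, nchw_to_hwcn(x[b, , , , drop = FALSE]),
                           training = FALSE)$out
    pred[b] <- max.col(logits, ties.method = "first") - 1L
  }
  confusion <- matrix(0L, classes, classes,
                      dimnames = if (classes == 7L)
                        list(true = eye_disease_classes(),
                             pred = eye_disease_classes()))
  for (i in seq_len(n))
    confusion[y[i] + 1L, pred[i] + 1L] <- confusion[y[i] + 1L, pred[i] + 1L] + 1L
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  list(accuracy = mean(pred == y), confusion = confusion,
       per_class_recall = recall, predictions = pred)
}

#' Evaluate a network on a manifest split
#'
#' Accuracy (correct / total), the C x C confusion matrix (rows = true
#' class, columns = prediction; row sums equal per-class counts) and
#' per-class recall.
#'
#' @param net an \code{"ednet"} or \code{"ednet_fit"} (its best checkpoint
#'   is used).
#' @param manifest dataset manifest.
#' @param split which split to evaluate (default \code{"test"}).
#' @param batch_size evaluation batch size.
#' @return list with \code{accuracy}, \code{confusion},
#'   \code{per_class_recall}, \code{predictions} (0-based).
#' @export
evaluate_ednet <- function(net, manifest, split = "test", batch_size = 64L) {
  if (inherits(net, "ednet_fit")) net <- net$best_net
  man <- manifest[manifest$split == split, ]
  if (nrow(man) == 0L) stop("evaluate_ednet: empty split '", split, "'")
  te <- load_image_tensor(man, size = net$config$input_size)
  evaluate_tensor(net, te$x, te$y, batch_size)
}

#' Export a training history
#'
#' Writes the per-epoch history (epoch, lr, train_loss, train_acc,
#' test_acc) as CSV and, optionally, accuracy/loss curve plots as a PNG.
#'
#' @param history history data.frame from \code{\link{train_ednet}} (or an
#'   \code{ednet_fit}).
#' @param csv_path output CSV path.
#' @param plot_path optional output PNG path for the curves.
#' @return invisibly, the CSV path.
#' @export
export_history <- function(history, csv_path, plot_path = NULL) {
  if (inherits(history, "ednet_fit")) history <- history$history
  utils::write.csv(history, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2))
    plot_history(history)
  }
  invisible(csv_path)
}

plot_history <- function(history) {
  graphics::plot(history$epoch, history$train_acc, type = "l", col = "blue",
                 ylim = c(0, 1), xlab = "epoch", ylab = "accuracy",
                 main = "Accuracy")
  if (!all(is.na(history$test_acc)))
    graphics::lines(history$epoch, history$test_acc, col = "red")
  graphics::legend("bottomright", c("train", "test"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  graphics::plot(history$epoch, history$train_loss, type = "l",
                 col = "blue", xlab = "epoch", ylab = "loss", main = "Loss")
}

#' Save / load a network checkpoint
#'
#' Serializes a network or fit, including its configuration and seeds, for
#' later reuse.
#'
#' @param object an \code{"ednet"} or \code{"ednet_fit"}.
#' @param path checkpoint file path.
#' @return \code{load_ednet} returns the deserialized object.
#' @export
save_ednet <- function(object, path) {
  stopifnot(inherits(object, "ednet") || inherits(object, "ednet_fit"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ednet
#' @export
load_ednet <- function(path) readRDS(path)
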