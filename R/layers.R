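LAYER_KINDS <- c("conv", "depthwise_conv", "norm", "activation",
                 "pool", "global_pool", "linear")

#' Declarative layer specification
#'
#' A \code{layer_spec} describes one weighted or structural layer of a
#' convolutional network: its kind, channel counts, kernel geometry and
#' whether a batch-normalization and/or a swish6 activation are fused after
#' it. Blocks and whole networks are ordered sequences of these records; the
#' complexity counter and the executable network builder both consume them.
#'
#' Fused \code{norm} counts 2 parameters per output channel (scale and
#' shift). Convolution bias is disabled whenever a normalization immediately
#' follows (it would be absorbed by the shift) and enabled otherwise;
#' \code{bias} can override this.
#'
#' @param kind one of \code{"conv"}, \code{"depthwise_conv"}, \code{"norm"},
#'   \code{"activation"}, \code{"pool"}, \code{"global_pool"},
#'   \code{"linear"}.
#' @param in_channels,out_channels positive integer channel counts;
#'   \code{depthwise_conv} requires them equal.
#' @param kernel odd positive kernel size (square); one of 1, 3, 5, 7 for the
#'   network rows used here. Ignored for non-convolution kinds except
#'   \code{"pool"} (fixed 2).
#' @param stride positive integer stride.
#' @param padding non-negative integer zero-padding on each border.
#' @param norm logical; a per-channel batch normalization follows this layer.
#' @param has_swish6 logical; a swish6 activation follows this layer.
#' @param bias logical or NA; NA (default) resolves to \code{!norm} for
#'   convolutions and \code{TRUE} for linear layers.
#' @param pool_type \code{"max"} or \code{"avg"}, for \code{kind = "pool"}.
#' @return an object of class \code{"ednet_layer_spec"}.
#' @examples
#' layer_spec("conv", 3, 64, kernel = 7, stride = 2, padding = 3,
#'            norm = TRUE, has_swish6 = TRUE)
#' @export
layer_spec <- function(kind, in_channels, out_channels,
                       kernel = 1L, stride = 1L, padding = 0L,
                       norm = FALSE, has_swish6 = FALSE, bias = NA,
                       pool_type = "max") {
  kind <- match.arg(kind, LAYER_KINDS)
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  padding <- as.integer(padding)
  stopifnot(in_channels >= 1L, out_channels >= 1L,
            stride >= 1L, padding >= 0L)
  if (kind %in% c("conv", "depthwise_conv")) {
    if (kernel < 1L || kernel %% 2L == 0L)
      stop("layer_spec: kernel must be odd and positive, got ", kernel)
  }
  if (kind == "depthwise_conv" && in_channels != out_channels)
    stop("layer_spec: depthwise_conv requires in_channels == out_channels")
  if (kind %in% c("norm", "activation", "global_pool") &&
      in_channels != out_channels)
    stop("layer_spec: ", kind, " cannot change the channel count")
  if (is.na(bias))
    bias <- if (kind == "linear") TRUE else if (kind %in% c("conv", "depthwise_conv")) !norm else FALSE
  structure(list(kind = kind, in_channels = in_channels,
                 out_channels = out_channels, kernel = kernel,
                 stride = stride, padding = padding, norm = isTRUE(norm),
                 has_swish6 = isTRUE(has_swish6), bias = isTRUE(bias),
                 pool_type = match.arg(pool_type, c("max", "avg"))),
            class = "ednet_layer_spec")
}

#' @export
print.ednet_layer_spec <- function(x, ...) {
  act <- if (x$has_swish6) "/swish6" else ""
  nrm <- if (x$norm) "/BN" else ""
  cat(sprintf("%-14s %4d -> %-4d  k=%d s=%d p=%d%s%s\n",
              x$kind, x$in_channels, x$out_channels, x$kernel, x$stride,
              x$padding, nrm, act))
  invisible(x)
}

#' Block specification
#'
#' Groups an ordered sequence of \code{\link{layer_spec}} records under a
#' named block with an optional skip connection. \code{skip = "additive"}
#' adds the block input to the block output elementwise and requires matching
#' input/output shapes unless a 1x1 projection (\code{skip_proj}) reconciles
#' the channel counts; \code{skip = "concat"} concatenates input and output
#' along channels and applies the mandatory \code{skip_proj} to restore the
#' block's nominal output width.
#'
#' @param name block name, one of \code{"ED_Conv"}, \code{"ED_Resnet"},
#'   \code{"ED_Xception"}, \code{"ED_Linear"} (other names allowed for
#'   fixtures).
#' @param layers list of \code{layer_spec} objects.
#' @param skip \code{"none"}, \code{"additive"} or \code{"concat"}.
#' @param skip_proj optional \code{layer_spec} for a 1x1 projection on the
#'   skip path.
#' @return an object of class \code{"ednet_block_spec"}.
#' @export
block_spec <- function(name, layers, skip = "none", skip_proj = NULL) {
  skip <- match.arg(skip, c("none", "additive", "concat"))
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "ednet_layer_spec")))
  cin <- layers[[1L]]$in_channels
  cout <- layers[[length(layers)]]$out_channels
  for (i in seq_len(length(layers) - 1L)) {
    if (layers[[i]]$out_channels != layers[[i + 1L]]$in_channels)
      stop("block_spec '", name, "': channel mismatch between rows ", i,
           " (out ", layers[[i]]$out_channels, ") and ", i + 1L,
           " (in ", layers[[i + 1L]]$in_channels, ")")
  }
  if (skip == "additive" && is.null(skip_proj) && cin != cout)
    stop("block_spec '", name, "': additive skip requires equal input and ",
         "output channels (", cin, " vs ", cout, ") or a projection")
  if (skip == "concat" && is.null(skip_proj))
    stop("block_spec '", name, "': concat skip requires a projection layer")
  structure(list(name = name, layers = layers, skip = skip,
                 skip_proj = skip_proj,
                 in_channels = cin, out_channels = cout),
            class = "ednet_block_spec")
}

#' @export
print.ednet_block_spec <- function(x, ...) {
  cat(sprintf("[%s]  %d -> %d  (skip: %s)\n", x$name, x$in_channels,
              x$out_channels, x$skip))
  for (l in x$layers) print(l)
  if (!is.null(x$skip_proj)) {
    cat("  skip projection: "); print(x$skip_proj)
  }
  invisible(x)
}

# flatten a config / block list / single block into a plain list of
# layer_spec rows (skip projections included) — the counter's input
flatten_layers <- function(x) {
  if (inherits(x, "ednet_layer_spec")) return(list(x))
  if (inherits(x, "ednet_block_spec")) {
    out <- x$layers
    if (!is.null(x$skip_proj)) out <- c(out, list(x$skip_proj))
    return(out)
  }
  if (inherits(x, "ednet_config")) x <- x$blocks
  if (inherits(x, "ednet")) x <- x$config$blocks
  if (is.list(x)) return(do.call(c, lapply(x, flatten_layers)))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as layer specifications")
}
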