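#' Stem block: 7x7 strided convolution
#'
#' Builds the ED_Conv stem: a single 7x7 convolution from \code{in_channels}
#' to \code{out_channels} with stride 2 and padding 3 (halving the spatial
#' size), followed by batch normalization and swish6.
#'
#' @param in_channels,out_channels channel counts (defaults 3 and 64).
#' @param norm include batch normalization (disable only for identity tests).
#' @return an \code{\link{block_spec}}.
#' @export
build_ed_conv <- function(in_channels = 3L, out_channels = 64L, norm = TRUE) {
  block_spec("ED_Conv", list(
    layer_spec("conv", in_channels, out_channels, kernel = 7L, stride = 2L,
               padding = 3L, norm = norm, has_swish6 = TRUE)))
}

#' Residual bottleneck block
#'
#' Builds an ED_Resnet block: a 1x1 convolution halving the channel count, a
#' depthwise convolution at the same width, and a 1x1 convolution restoring
#' the input width, each followed by batch normalization, with swish6 after
#' the final convolution and a skip connection from block input to block
#' output. The default skip is elementwise addition (the channel arithmetic
#' of the network structure table balances only under addition); a
#' channel-concatenation variant with a reconciling 1x1 projection is
#' available via \code{skip = "concat"}.
#'
#' @param cin even, positive input channel count; the block preserves it.
#' @param kernel depthwise kernel size, 3 (default) or 5.
#' @param skip \code{"additive"} (default) or \code{"concat"}.
#' @param norm include batch normalizations.
#' @return a \code{\link{block_spec}} with input width == output width.
#' @export
build_ed_resnet_block <- function(cin, kernel = 3L,
                                  skip = c("additive", "concat"),
                                  norm = TRUE) {
  skip <- match.arg(skip)
  cin <- as.integer(cin)
  if (cin %% 2L != 0L)
    stop("build_ed_resnet_block: cin must be even, got ", cin)
  kernel <- as.integer(kernel)
  mid <- cin %/% 2L
  layers <- list(
    layer_spec("conv", cin, mid, kernel = 1L, norm = norm),
    layer_spec("depthwise_conv", mid, mid, kernel = kernel,
               padding = (kernel - 1L) %/% 2L, norm = norm),
    layer_spec("conv", mid, cin, kernel = 1L, norm = norm,
               has_swish6 = TRUE))
  proj <- if (skip == "concat")
    layer_spec("conv", 2L * cin, cin, kernel = 1L, norm = norm)
  block_spec("ED_Resnet", layers, skip = skip, skip_proj = proj)
}

#' Multi-kernel channel-doubling block
#'
#' Builds an ED_Xception block: sequential 3x3, 5x5 and 7x7 same-width
#' convolutions (paddings 1/2/3, preserving the spatial size), then a 1x1
#' convolution doubling the channel count, with batch normalization after
#' every convolution and swish6 after the final one. The three spatial
#' convolutions are depthwise-separable (depthwise + 1x1 pointwise) when
#' \code{separable = TRUE}, dense otherwise; an optional 1x1 projection skip
#' from input to output is available.
#'
#' @param cin positive input channel count; output has \code{2 * cin}.
#' @param separable use depthwise-separable spatial convolutions (default
#'   TRUE, the configuration frozen by \code{\link{sweep_architecture_variants}}).
#' @param projection_skip add a 1x1 projection skip path input -> output.
#' @param norm include batch normalizations.
#' @return a \code{\link{block_spec}} doubling the channel count.
#' @export
build_ed_xception_block <- function(cin, separable = TRUE,
                                    projection_skip = FALSE, norm = TRUE) {
  cin <- as.integer(cin)
  stopifnot(cin >= 1L)
  spatial <- function(k) {
    pad <- (k - 1L) %/% 2L
    if (separable)
      list(layer_spec("depthwise_conv", cin, cin, kernel = k, padding = pad),
           layer_spec("conv", cin, cin, kernel = 1L, norm = norm))
    else
      list(layer_spec("conv", cin, cin, kernel = k, padding = pad,
                      norm = norm))
  }
  layers <- c(spatial(3L), spatial(5L), spatial(7L),
              list(layer_spec("conv", cin, 2L * cin, kernel = 1L,
                              norm = norm, has_swish6 = TRUE)))
  proj <- if (projection_skip)
    layer_spec("conv", cin, 2L * cin, kernel = 1L, norm = norm)
  block_spec("ED_Xception", layers,
             skip = if (projection_skip) "additive" else "none",
             skip_proj = proj)
}

build_ed_linear <- function(cin, num_classes) {
  block_spec("ED_Linear", list(
    layer_spec("global_pool", cin, cin),
    layer_spec("linear", cin, num_classes)))
}

#' Full network configuration
#'
#' Declares the complete network: one ED_Conv stem, two ED_Resnet blocks and
#' three ED_Xception blocks interleaved (stem, resnet, xception, xception,
#' resnet, xception), and a global-pool + linear head. Channel widths follow
#' 64-128-256-512 scaled by \code{width}; only the stem downsamples
#' (stride 2), so a 224x224 input reaches the head at 112x112 before global
#' pooling.
#'
#' The structural interpretation flags default to the configuration frozen by
#' the complexity sweep (\code{\link{sweep_architecture_variants}}):
#' depthwise-separable ED_Xception convolutions, no projection skips, 3x3
#' residual depthwise kernel, additive residual skips.
#'
#' @param width channel-width multiplier (1 = full network; 0.25 gives the
#'   desk-scale variant used in the training examples).
#' @param num_classes number of output classes (default 7).
#' @param input_size expected square input size in pixels (default 224).
#' @param separable_xception depthwise-separable vs dense ED_Xception
#'   convolutions.
#' @param xception_projection_skip add 1x1 projection skips to ED_Xception.
#' @param resnet_kernel depthwise kernel of ED_Resnet blocks (3 or 5).
#' @param resnet_skip \code{"additive"} or \code{"concat"}.
#' @param norm include batch normalizations throughout.
#' @return an object of class \code{"ednet_config"}.
#' @examples
#' cfg <- ednet_config(width = 0.25)
#' count_params(cfg)$total_params
#' @export
ednet_config <- function(width = 1, num_classes = 7L, input_size = 224L,
                         separable_xception = TRUE,
                         xception_projection_skip = FALSE,
                         resnet_kernel = 3L,
                         resnet_skip = c("additive", "concat"),
                         norm = TRUE) {
  resnet_skip <- match.arg(resnet_skip)
  stopifnot(width > 0, num_classes >= 1L, input_size >= 7L)
  ch <- as.integer(round(64L * width * c(1L, 2L, 4L, 8L)))
  ch <- pmax(2L, ch + ch %% 2L)    # even widths so bottlenecks halve cleanly
  blocks <- list(
    build_ed_conv(3L, ch[1L], norm = norm),
    build_ed_resnet_block(ch[1L], kernel = resnet_kernel, skip = resnet_skip,
                          norm = norm),
    build_ed_xception_block(ch[1L], separable = separable_xception,
                            projection_skip = xception_projection_skip,
                            norm = norm),
    build_ed_xception_block(ch[2L], separable = separable_xception,
                            projection_skip = xception_projection_skip,
                            norm = norm),
    build_ed_resnet_block(ch[3L], kernel = resnet_kernel, skip = resnet_skip,
                          norm = norm),
    build_ed_xception_block(ch[3L], separable = separable_xception,
                            projection_skip = xception_projection_skip,
                            norm = norm))
  blocks <- c(blocks, list(build_ed_linear(ch[4L], as.integer(num_classes))))
  cfg <- structure(list(
    blocks = blocks, width = width, num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    separable_xception = isTRUE(separable_xception),
    xception_projection_skip = isTRUE(xception_projection_skip),
    resnet_kernel = as.integer(resnet_kernel), resnet_skip = resnet_skip,
    norm = isTRUE(norm)), class = "ednet_config")
  validate_channel_chain(cfg)
  cfg
}

validate_channel_chain <- function(cfg) {
  b <- cfg$blocks
  for (i in seq_len(length(b) - 1L)) {
    if (b[[i]]$out_channels != b[[i + 1L]]$in_channels)
      stop("channel chain mismatch: block ", i, " (", b[[i]]$name,
           ") emits ", b[[i]]$out_channels, " channels but block ", i + 1L,
           " (", b[[i + 1L]]$name, ") expects ", b[[i + 1L]]$in_channels)
  }
  invisible(TRUE)
}

init_layer <- function(spec) {
  l <- list(spec = spec)
  k <- spec$kernel
  if (spec$kind == "conv") {
    sd <- sqrt(2 / (k * k * spec$in_channels))
    l$w <- array(stats::rnorm(k * k * spec$in_channels * spec$out_channels,
                              sd = sd),
                 dim = c(k, k, spec$in_channels, spec$out_channels))
  } else if (spec$kind == "depthwise_conv") {
    sd <- sqrt(2 / (k * k))
    l$w <- array(stats::rnorm(k * k * spec$out_channels, sd = sd),
                 dim = c(k, k, spec$out_channels))
  } else if (spec$kind == "linear") {
    sd <- sqrt(2 / spec$in_channels)
    l$w <- matrix(stats::rnorm(spec$out_channels * spec$in_channels,
                               sd = sd),
                  nrow = spec$out_channels)
  }
  if (spec$bias) l$b <- numeric(spec$out_channels)
  if (spec$norm) {
    l$gamma <- rep(1, spec$out_channels)
    l$beta <- numeric(spec$out_channels)
    l$running_mean <- numeric(spec$out_channels)
    l$running_var <- rep(1, spec$out_channels)
  }
  l
}

#' Assemble an executable network
#'
#' Instantiates learnable weights for every layer of a configuration,
#' Kaiming-initialized (zero-mean normal, variance 2/fan-in) from a fixed
#' seed so two assemblies with the same seed are bitwise identical.
#'
#' @param config an \code{\link{ednet_config}} (default configuration if
#'   omitted).
#' @param weight_init_seed integer seed for the weight draw.
#' @return an object of class \code{"ednet"}: the configuration plus
#'   weighted, executable blocks.
#' @examples
#' net <- assemble_ednet(ednet_config(width = 0.125, input_size = 32))
#' x <- array(stats::runif(2 * 3 * 32 * 32), dim = c(2, 3, 32, 32))
#' dim(ednet_forward(net, x))   # 2 x 7
#' @export
assemble_ednet <- function(config = ednet_config(), weight_init_seed = 42L) {
  stopifnot(inherits(config, "ednet_config"))
  validate_channel_chain(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(weight_init_seed))
  blocks <- lapply(config$blocks, function(bs) {
    list(spec = bs,
         layers = lapply(bs$layers, init_layer),
         skip_proj = if (!is.null(bs$skip_proj)) init_layer(bs$skip_proj))
  })
  structure(list(config = config, blocks = blocks,
                 weight_init_seed = as.integer(weight_init_seed)),
            class = "ednet")
}

#' Shorthand constructor
#'
#' \code{ednet(...)} builds and assembles a network in one call; arguments
#' are passed to \code{\link{ednet_config}}.
#'
#' @param ... arguments for \code{\link{ednet_config}}.
#' @param weight_init_seed integer seed for the weight draw.
#' @return an object of class \code{"ednet"}.
#' @export
ednet <- function(..., weight_init_seed = 42L) {
  assemble_ednet(ednet_config(...), weight_init_seed = weight_init_seed)
}

run_layer <- function(layer, x, training, keep_cache) {
  s <- layer$spec
  caches <- list()
  if (s$kind == "conv") {
    r <- conv2d_forward(x, layer$w, layer$b, s$stride, s$padding)
    x <- r$out; if (keep_cache) caches$conv <- r$cache
  } else if (s$kind == "depthwise_conv") {
    r <- depthwise_forward(x, layer$w, layer$b, s$stride, s$padding)
    x <- r$out; if (keep_cache) caches$conv <- r$cache
  } else if (s$kind == "global_pool") {
    r <- gap_forward(x)
    x <- r$out; if (keep_cache) caches$gap <- r$cache
  } else if (s$kind == "linear") {
    r <- linear_forward(x, layer$w, layer$b)
    x <- r$out; if (keep_cache) caches$linear <- r$cache
  } else if (s$kind != "norm" && s$kind != "activation") {
    stop("forward: unsupported layer kind ", s$kind)
  }
  if (s$norm) {
    r <- bn_forward(x, layer$gamma, layer$beta, layer$running_mean,
                    layer$running_var, training = training)
    x <- r$out
    if (keep_cache) caches$bn <- r$cache
    caches$running <- list(mean = r$running_mean, var = r$running_var)
  }
  if (s$has_swish6) {
    if (keep_cache) caches$act_in <- x
    x <- swish6(x)
  }
  list(out = x, caches = caches)
}

forward_pass <- function(net, x, training = FALSE, keep_cache = FALSE) {
  block_caches <- vector("list", length(net$blocks))
  for (bi in seq_along(net$blocks)) {
    blk <- net$blocks[[bi]]
    bin <- x
    lcaches <- vector("list", length(blk$layers))
    for (li in seq_along(blk$layers)) {
      r <- run_layer(blk$layers[[li]], x, training, keep_cache)
      x <- r$out
      lcaches[[li]] <- r$caches
    }
    pcache <- NULL
    if (blk$spec$skip == "additive") {
      if (is.null(blk$skip_proj)) {
        x <- x + bin
      } else {
        r <- run_layer(blk$skip_proj, bin, training, keep_cache)
        x <- x + r$out
        pcache <- r$caches
      }
    } else if (blk$spec$skip == "concat") {
      d <- dim(x)
      cc <- array(0, dim = c(d[1L], d[2L], d[3L], 2L * d[4L]))
      cc[, , , seq_len(d[4L])] <- x
      cc[, , , d[4L] + seq_len(d[4L])] <- bin
      r <- run_layer(blk$skip_proj, cc, training, keep_cache)
      x <- r$out
      pcache <- r$caches
    }
    block_caches[[bi]] <- list(layers = lcaches, proj = pcache)
  }
  list(out = x, caches = block_caches)
}

#' Forward pass
#'
#' Runs a batch through the network and returns the raw class logits.
#' Deterministic given weights and input; batch normalization uses running
#' statistics (inference mode).
#'
#' @param net an assembled \code{"ednet"} object.
#' @param batch numeric array of dimension (N, 3, H, W) with H == W ==
#'   \code{input_size}, values typically in [0, 1].
#' @return numeric matrix (N x num_classes) of finite logits.
#' @export
ednet_forward <- function(net, batch) {
  stopifnot(inherits(net, "ednet"))
  d <- dim(batch)
  sz <- net$config$input_size
  if (is.null(d) || length(d) != 4L)
    stop("batch must be a rank-4 array (N, C, H, W)")
  if (d[2L] != net$blocks[[1L]]$spec$in_channels)
    stop("batch has ", d[2L], " channels; network expects ",
         net$blocks[[1L]]$spec$in_channels)
  if (d[3L] != sz || d[4L] != sz)
    stop("batch spatial size ", d[3L], "x", d[4L],
         " does not match the configured input size ", sz, "x", sz)
  forward_pass(net, nchw_to_hwcn(batch), training = FALSE)$out
}

#' Class probabilities
#'
#' Softmax of \code{\link{ednet_forward}}: one probability row per image,
#' each row non-negative and summing to 1 across the seven classes.
#'
#' @inheritParams ednet_forward
#' @return numeric matrix (N x num_classes); rows sum to 1. Columns are named
#'   by class.
#' @export
predict_proba <- function(net, batch) {
  p <- softmax_rows(ednet_forward(net, batch))
  if (ncol(p) == length(eye_disease_classes()))
    colnames(p) <- eye_disease_classes()
  p
}

#' Layer-by-layer structure listing
#'
#' Returns (and prints) the network structure in the style of a structure
#' table: one row per layer with block name, layer description, channel
#' counts, kernel size and stride/padding.
#'
#' @param x an \code{ednet}, \code{ednet_config}, \code{ednet_block_spec} or
#'   list of blocks.
#' @param quiet suppress printing.
#' @return invisibly, a data.frame of the rows.
#' @export
summarize_network <- function(x, quiet = FALSE) {
  if (inherits(x, "ednet")) x <- x$config
  blocks <- if (inherits(x, "ednet_config")) x$blocks
            else if (inherits(x, "ednet_block_spec")) list(x)
            else x
  rows <- list()
  for (b in blocks) {
    specs <- b$layers
    if (!is.null(b$skip_proj)) specs <- c(specs, list(b$skip_proj))
    first <- TRUE
    for (s in specs) {
      lab <- switch(s$kind,
        conv = "Conv", depthwise_conv = "Dep-Conv", linear = "Linear",
        global_pool = "Global_pool", pool = paste0(s$pool_type, "-pool"),
        norm = "BN", activation = "swish6")
      if (s$norm) lab <- paste0(lab, "/BN")
      if (s$has_swish6) lab <- paste0(lab, "/swish6")
      rows[[length(rows) + 1L]] <- data.frame(
        model = if (first) b$name else "", layer = lab,
        in_ch = s$in_channels, out_ch = s$out_channels,
        kernel = if (s$kind %in% c("conv", "depthwise_conv"))
                   sprintf("%d x %d", s$kernel, s$kernel) else "",
        stride_padding = if (s$kind %in% c("conv", "depthwise_conv"))
                           sprintf("%d/%d", s$stride, s$padding) else "",
        stringsAsFactors = FALSE)
      first <- FALSE
    }
  }
  tab <- do.call(rbind, rows)
  if (!quiet) print(tab, row.names = FALSE)
  invisible(tab)
}
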