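run_block <- function(bspec, x_hwcn, seed = 1L, zero_weights = FALSE) {
  set.seed(seed)
  blk <- list(spec = bspec,
              layers = lapply(bspec$layers, ednet:::init_layer),
              skip_proj = if (!is.null(bspec$skip_proj))
                ednet:::init_layer(bspec$skip_proj))
  if (zero_weights) {
    for (i in seq_along(blk$layers)) {
      if (!is.null(blk$layers[[i]]$w)) blk$layers[[i]]$w[] <- 0
      if (!is.null(blk$layers[[i]]$b)) blk$layers[[i]]$b[] <- 0
    }
  }
  net <- list(config = list(), blocks = list(blk))
  ednet:::forward_pass(net, x_hwcn, training = TRUE)$out
}

test_that("the stem halves the spatial size and emits 64 channels", {
  b <- build_ed_conv()
  s <- b$layers[[1L]]
  expect_equal(c(s$kernel, s$stride, s$padding), c(7L, 2L, 3L))
  expect_equal(c(s$in_channels, s$out_channels), c(3L, 64L))
  expect_true(s$has_swish6 && s$norm && !s$bias)
  # ((224 + 2*3 - 7) %/% 2) + 1 = 112 ; same formula at 7 -> 4
  out <- run_block(b, array(stats::runif(7 * 7 * 1 * 3), c(7, 7, 1, 3)))
  expect_equal(dim(out), c(4L, 4L, 1L, 64L))
  out16 <- run_block(b, array(stats::runif(16 * 16 * 2 * 3), c(16, 16, 2, 3)))
  expect_equal(dim(out16), c(8L, 8L, 2L, 64L))
})

test_that("the residual bottleneck halves and restores the channel width", {
  for (cin in c(64L, 256L)) {
    b <- build_ed_resnet_block(cin)
    widths <- vapply(b$layers, function(l) l$out_channels, 0L)
    expect_equal(widths, c(cin %/% 2L, cin %/% 2L, cin))
    expect_equal(b$layers[[2L]]$kind, "depthwise_conv")
    expect_equal(b$layers[[2L]]$kernel, 3L)
    expect_equal(b$skip, "additive")
  }
  expect_equal(build_ed_resnet_block(64L, kernel = 5L)$layers[[2L]]$kernel, 5L)
  expect_error(build_ed_resnet_block(63L), "even")
  # block output preserves the input shape
  x <- array(stats::runif(6 * 6 * 2 * 8), c(6, 6, 2, 8))
  expect_equal(dim(run_block(build_ed_resnet_block(8L), x)), dim(x))
})

test_that("a zero-weight residual block with norm bypassed is the identity", {
  b <- build_ed_resnet_block(8L, norm = FALSE)
  x <- array(stats::runif(5 * 5 * 3 * 8), c(5, 5, 3, 8))
  expect_equal(run_block(b, x, zero_weights = TRUE), x)
})

test_that("the multi-kernel block doubles channels and keeps spatial size", {
  for (cin in c(64L, 256L)) {
    b <- build_ed_xception_block(cin)
    expect_equal(b$out_channels, 2L * cin)
  }
  dense <- build_ed_xception_block(8L, separable = FALSE)
  expect_equal(vapply(dense$layers, function(l) l$kernel, 0L),
               c(3L, 5L, 7L, 1L))
  sep <- build_ed_xception_block(8L, separable = TRUE)
  expect_equal(vapply(sep$layers, function(l) l$kind, ""),
               c("depthwise_conv", "conv", "depthwise_conv", "conv",
                 "depthwise_conv", "conv", "conv"))
  for (variant in list(dense, sep)) {
    x <- array(stats::runif(8 * 8 * 1 * 8), c(8, 8, 1, 8))
    expect_equal(dim(run_block(variant, x)), c(8L, 8L, 1L, 16L))
  }
  proj <- build_ed_xception_block(8L, projection_skip = TRUE)
  expect_equal(proj$skip, "additive")
  expect_equal(proj$skip_proj$out_channels, 16L)
})

test_that("the assembled network follows the declared channel chain", {
  cfg <- ednet_config()
  expect_length(cfg$blocks, 7L)
  expect_equal(vapply(cfg$blocks, function(b) b$name, ""),
               c("ED_Conv", "ED_Resnet", "ED_Xception", "ED_Xception",
                 "ED_Resnet", "ED_Xception", "ED_Linear"))
  for (i in seq_len(length(cfg$blocks) - 1L))
    expect_equal(cfg$blocks[[i]]$out_channels,
                 cfg$blocks[[i + 1L]]$in_channels)
  expect_equal(cfg$blocks[[7L]]$layers[[2L]]$in_channels, 512L)
  expect_equal(cfg$blocks[[7L]]$layers[[2L]]$out_channels, 7L)
  # a broken chain is reported with the offending blocks named
  bad <- cfg
  bad$blocks[[3L]] <- build_ed_xception_block(32L)
  expect_error(ednet:::validate_channel_chain(bad), "block 2")
})

test_that("assembly is deterministic and the forward pass well-shaped", {
  n1 <- ednet(width = 0.125, input_size = 16L, weight_init_seed = 9L)
  n2 <- ednet(width = 0.125, input_size = 16L, weight_init_seed = 9L)
  expect_identical(coef(n1), coef(n2))
  n3 <- ednet(width = 0.125, input_size = 16L, weight_init_seed = 10L)
  expect_false(identical(coef(n1), coef(n3)))

  x <- array(stats::runif(4 * 3 * 16 * 16), c(4, 3, 16, 16))
  lg <- ednet_forward(n1, x)
  expect_equal(dim(lg), c(4L, 7L))
  expect_true(all(is.finite(lg)))
  # identical images give identical logit rows; batch order is respected
  x2 <- x; x2[2, , , ] <- x[1, , , ]
  lg2 <- ednet_forward(n1, x2)
  expect_equal(lg2[1, ], lg2[2, ], tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(ednet_forward(n1, x[perm, , , , drop = FALSE]), lg[perm, ],
               tolerance = 1e-10)
  # any single perturbed weight changes the output
  n4 <- n1
  n4$blocks[[2]]$layers[[1]]$w[1] <- n4$blocks[[2]]$layers[[1]]$w[1] + 0.1
  expect_false(isTRUE(all.equal(ednet_forward(n4, x), lg)))

  expect_error(ednet_forward(n1, array(0, c(2, 1, 16, 16))), "channels")
  expect_error(ednet_forward(n1, array(0, c(2, 3, 8, 8))), "spatial size")

  k3 <- ednet(width = 0.125, input_size = 16L, num_classes = 3L)
  expect_equal(dim(ednet_forward(k3, x)), c(4L, 3L))
})

test_that("predicted probabilities are a valid softmax of the logits", {
  net <- ednet(width = 0.125, input_size = 16L)
  x <- array(stats::runif(3 * 3 * 16 * 16), c(3, 3, 16, 16))
  p <- predict_proba(net, x)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p >= 0))
  lg <- ednet_forward(net, x)
  expect_equal(apply(p, 1, which.max), apply(lg, 1, which.max))
  expect_equal(colnames(p), eye_disease_classes())
})

test_that("analytic gradients agree with finite differences everywhere", {
  net <- ednet(width = 2 / 64, input_size = 8L, weight_init_seed = 3L)
  set.seed(7)
  x <- array(stats::runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  expect_lt(max_grad_error(net, x, c(0L, 4L, 6L)), 1e-3)
  # concat-skip and projection-skip variants backpropagate correctly too
  cfgv <- ednet_config(width = 2 / 64, input_size = 8L,
                       resnet_skip = "concat",
                       xception_projection_skip = TRUE)
  netv <- assemble_ednet(cfgv, weight_init_seed = 4L)
  expect_lt(max_grad_error(netv, x, c(1L, 2L, 5L)), 1e-3)
})

test_that("the structure listing covers every block and round-trips config", {
  tab <- summarize_network(ednet_config(), quiet = TRUE)
  expect_equal(sum(tab$model != ""), 7L)
  expect_equal(tab$layer[1L], "Conv/BN/swish6")
  expect_equal(utils::tail(tab$layer, 1L), "Linear")

  rc <- run_config(architecture = list(width = 0.5, input_size = 64L),
                   training = list(epochs = 3L, lr0 = 0.02),
                   data = list(image_size = 24L, seed = 8L),
                   weight_init_seed = 17L)
  path <- tempfile(fileext = ".yaml")
  write_run_config(rc, path)
  rc2 <- read_run_config(path)
  expect_equal(rc2$architecture$width, 0.5)
  expect_equal(rc2$training$lr0, 0.02)
  expect_equal(rc2$data$image_size, 24L)
  expect_equal(rc2$weight_init_seed, 17L)
  inst <- ednet:::instantiate_run(rc2)
  expect_s3_class(inst$architecture, "ednet_config")
  expect_equal(inst$training$epochs, 3L)
  expect_equal(inst$data$image_size, 24L)
})
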