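test_that("cross-entropy has its closed-form values and monotonicity", {
  expect_equal(cross_entropy(matrix(0, 2, 7), c(0L, 3L)), log(7),
               tolerance = 1e-12)
  confident <- matrix(0, 1, 7); confident[1, 3] <- 100
  expect_lt(cross_entropy(confident, 2L), 1e-10)
  # raising the true-class logit with others fixed always lowers the loss
  z <- matrix(stats::rnorm(7), 1, 7)
  losses <- vapply(seq(0, 3, by = 0.5), function(d) {
    z2 <- z; z2[1, 5] <- z[1, 5] + d
    cross_entropy(z2, 4L)
  }, 0)
  expect_true(all(diff(losses) < 0))
  # stability under huge logits
  expect_equal(cross_entropy(matrix(c(1e4, 1e4), 1, 2), 0L), log(2),
               tolerance = 1e-9)
  expect_error(cross_entropy(matrix(0, 1, 7), 7L), "labels")
  expect_error(cross_entropy(matrix(0, 1, 7), -1L), "labels")
})

test_that("the learning-rate schedule decays 5% per epoch", {
  cfg <- train_config()
  expect_equal(lr_schedule(cfg, 0), 0.01)
  expect_equal(lr_schedule(cfg, 1), 0.0095)
  lrs <- lr_schedule(cfg, 0:99)
  expect_length(lrs, 100L)
  expect_true(all(diff(lrs) < 0))
  expect_equal(lrs[100], 0.01 * 0.95^99)
})

test_that("SGD with momentum follows the hand-computed recurrence", {
  # plain gradient step when momentum and decay are off
  r <- sgd_update(weights = 2, gradients = 0.5, velocity = 0, lr = 0.1,
                  momentum = 0, weight_decay = 0)
  expect_equal(r$weights, 2 - 0.1 * 0.5)
  # zero gradient, zero velocity: nothing moves
  r0 <- sgd_update(1.5, 0, 0, lr = 0.1, momentum = 0.9)
  expect_equal(r0$weights, 1.5)
  # two steps on the 1-D quadratic f(w) = w^2/2 (gradient = w), computed by
  # an independent scalar recurrence
  w <- 1; v <- 0
  for (i in 1:2) {
    v <- 0.9 * v + w          # g = w, wd = 0
    w <- w - 0.1 * v
  }
  s <- sgd_update(1, 1, 0, lr = 0.1, momentum = 0.9)
  s <- sgd_update(s$weights, s$weights, s$velocity, lr = 0.1, momentum = 0.9)
  expect_equal(s$weights, w, tolerance = 1e-12)
  expect_equal(s$velocity, v, tolerance = 1e-12)
  # weight decay couples into the gradient
  rd <- sgd_update(2, 0, 0, lr = 1, momentum = 0, weight_decay = 0.1)
  expect_equal(rd$weights, 2 - 0.2)
  # nested structures update elementwise; mismatches are rejected
  nest <- sgd_update(list(a = c(1, 2), b = list(c = 3)),
                     list(a = c(1, 1), b = list(c = 1)),
                     list(a = c(0, 0), b = list(c = 0)), lr = 1,
                     momentum = 0)
  expect_equal(nest$weights$a, c(0, 1))
  expect_equal(nest$weights$b$c, 2)
  expect_error(sgd_update(c(1, 2), 1, c(0, 0), lr = 1), "mismatch")
})

test_that("evaluation reports accuracy, confusion and per-class recall", {
  # a constant predictor on the published test composition scores the modal
  # class share
  cc <- default_class_counts()
  labels <- rep(seq_len(7L) - 1L, cc$test)
  const_pred <- rep(3L, length(labels))   # Diabetic_retinopathy
  expect_equal(mean(const_pred == labels), 275 / 1149)

  man <- easy_dataset(n_train = 12L, n_test = 6L)
  net <- ednet(width = 0.125, input_size = 32L, weight_init_seed = 2L)
  ev <- evaluate_ednet(net, man, split = "test")
  expect_equal(sum(ev$confusion), 42L)
  expect_equal(unname(rowSums(ev$confusion)), rep(6L, 7L))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 42)
  expect_equal(unname(ev$per_class_recall),
               unname(diag(ev$confusion) / 6))
  # an untrained network cannot be far from chance on balanced data
  expect_lt(ev$accuracy, 0.5)
  expect_error(evaluate_ednet(net, man[man$split == "train", ]), "empty")
})

test_that("a short run records history, follows the schedule, reproduces", {
  man <- easy_dataset(n_train = 12L, n_test = 6L)
  net <- ednet(width = 0.125, input_size = 32L, weight_init_seed = 1L)
  cfg <- train_config(batch_size = 8L, epochs = 3L, seed = 4L)
  fit1 <- train_ednet(net, man, cfg)
  expect_s3_class(fit1, "ednet_fit")
  expect_equal(nrow(fit1$history), 3L)
  expect_equal(fit1$history$lr, lr_schedule(cfg, 0:2))
  expect_true(all(fit1$history$train_loss >= 0))
  expect_true(all(fit1$history$train_acc >= 0 & fit1$history$train_acc <= 1))
  # bitwise reproducibility of the whole trajectory
  fit2 <- train_ednet(net, man, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(coef(fit1$net), coef(fit2$net))
  expect_error(train_ednet(net, man[man$split == "test", ], cfg),
               "no train split")
})

test_that("training loss trends downward on the easy synthetic set", {
  # window-3 smoothed epoch losses must be non-increasing for several seeds
  man <- easy_dataset(n_train = 24L, n_test = 8L)
  for (seed in c(1L, 2L)) {
    net <- ednet(width = 0.125, input_size = 32L, weight_init_seed = seed)
    fit <- train_ednet(net, man, train_config(batch_size = 8L, epochs = 5L,
                                              seed = seed))
    sm <- stats::filter(fit$history$train_loss, rep(1 / 3, 3), sides = 2)
    sm <- sm[!is.na(sm)]
    expect_true(all(diff(sm) <= 1e-8),
                info = paste("seed", seed, "losses:",
                             paste(round(fit$history$train_loss, 4),
                                   collapse = " ")))
  }
})

test_that("history export round-trips and renders plots", {
  h <- data.frame(epoch = 0:4, lr = lr_schedule(train_config(), 0:4),
                  train_loss = c(2, 1.5, 1.1, 0.9, 0.8),
                  train_acc = c(0.2, 0.4, 0.6, 0.7, 0.8),
                  test_acc = c(0.2, 0.3, 0.5, 0.6, 0.7))
  csv <- tempfile(fileext = ".csv"); png_f <- tempfile(fileext = ".png")
  export_history(h, csv, png_f)
  expect_equal(utils::read.csv(csv), h)
  expect_true(file.exists(png_f) && file.size(png_f) > 0)
})

test_that("fits expose the standard modelling methods", {
  man <- easy_dataset(n_train = 12L, n_test = 6L)
  net <- ednet(width = 0.125, input_size = 32L)
  fit <- train_ednet(net, man, train_config(batch_size = 8L, epochs = 2L,
                                            seed = 0L))
  expect_output(print(fit), "ednet fit")
  p <- predict(fit, man[man$split == "test", ][1:3, ])
  expect_equal(dim(p), c(3L, 7L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  cls <- predict(fit, man[man$split == "test", ][1:3, ], type = "class")
  expect_true(all(cls %in% eye_disease_classes()))
  cp <- tempfile(fileext = ".rds")
  save_ednet(fit, cp)
  fit2 <- load_ednet(cp)
  expect_identical(fit2$history, fit$history)
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.size(pf) > 0)
})
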