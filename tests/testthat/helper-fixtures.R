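# Shared fixtures and independent oracles for the suite.

# brute-force pooling oracle: explicit scan over non-overlapping 2x2 windows
pool_oracle <- function(grid, fun) {
  h <- nrow(grid) %/% 2L
  w <- ncol(grid) %/% 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- grid[(2L * i - 1L):(2L * i), (2L * j - 1L):(2L * j)]
      out[i, j] <- fun(as.vector(win))
    }
  }
  out
}

# balanced synthetic counts
balanced_counts <- function(n_train, n_test) {
  data.frame(class = eye_disease_classes(),
             train = rep(as.integer(n_train), 7L),
             test = rep(as.integer(n_test), 7L),
             stringsAsFactors = FALSE)
}

# trivial pixel-statistic classifier: nearest class centroid over simple
# image moments (channel means/sds, darkness-weighted horizontal centroid,
# central-patch brightness, bright-pixel fraction)
pixel_features <- function(path) {
  x <- preprocess(path, size = 32L)          # (3, 32, 32)
  lum <- (x[1L, , ] + x[2L, , ] + x[3L, , ]) / 3
  dark <- pmax(0.6 - lum, 0)
  xs <- matrix(seq(-1, 1, length.out = 32L), 32L, 32L, byrow = TRUE)
  mid <- 13:20
  c(apply(x, 1L, mean), apply(x, 1L, stats::sd),
    sum(dark * xs) / max(sum(dark), 1e-8),
    mean(lum[mid, mid]), mean(lum > 0.9), mean(dark > 0))
}

centroid_classifier_accuracy <- function(manifest) {
  tr <- manifest[manifest$split == "train", ]
  te <- manifest[manifest$split == "test", ]
  ftr <- t(vapply(tr$path, pixel_features, numeric(10L)))
  fte <- t(vapply(te$path, pixel_features, numeric(10L)))
  cents <- lapply(sort(unique(tr$label)), function(l)
    colMeans(ftr[tr$label == l, , drop = FALSE]))
  pred <- apply(fte, 1L, function(f)
    which.min(vapply(cents, function(ct) sum((f - ct)^2), 0)) - 1L)
  mean(pred == te$label)
}

# central finite-difference gradient check on sampled coordinates
max_grad_error <- function(net, x_hwcn, labels, per_field = 2L,
                           eps = 1e-5) {
  fwd <- ednet:::forward_pass(net, x_hwcn, training = TRUE,
                              keep_cache = TRUE)
  bwd <- ednet:::backward_pass(net, fwd$caches,
                               ednet:::cross_entropy_grad(fwd$out, labels))
  loss_at <- function(n)
    cross_entropy(ednet:::forward_pass(n, x_hwcn, TRUE, FALSE)$out, labels)
  worst <- 0
  for (bi in seq_along(net$blocks)) {
    for (li in seq_along(net$blocks[[bi]]$layers)) {
      lay <- net$blocks[[bi]]$layers[[li]]
      for (f in intersect(c("w", "b", "gamma", "beta"), names(lay))) {
        g <- bwd$grads[[bi]]$layers[[li]][[f]]
        for (k in sample(length(lay[[f]]), min(per_field, length(lay[[f]])))) {
          np <- net
          np$blocks[[bi]]$layers[[li]][[f]][k] <-
            np$blocks[[bi]]$layers[[li]][[f]][k] + eps
          nm <- net
          nm$blocks[[bi]]$layers[[li]][[f]][k] <-
            nm$blocks[[bi]]$layers[[li]][[f]][k] - eps
          num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
          worst <- max(worst, abs(num - g[k]) /
                         max(1e-6, abs(num) + abs(g[k])))
        }
      }
    }
  }
  worst
}

# one shared small synthetic dataset per test run (32 px, fully separable)
easy_dataset <- local({
  man <- NULL
  function(n_train = 24L, n_test = 8L, noise = 0, separability = 1,
           seed = 5L, image_size = 32L) {
    key <- paste(n_train, n_test, noise, separability, seed, image_size)
    if (!is.null(man) && attr(man, "key") == key) return(man)
    dir <- file.path(tempdir(), paste0("ednet_ds_", gsub("[ .]", "_", key)))
    spec <- synthetic_spec(counts = balanced_counts(n_train, n_test),
                           image_size = image_size, noise = noise,
                           separability = separability, seed = seed)
    m <- generate_synthetic_dataset(spec, dir)
    attr(m, "key") <- key
    man <<- m
    man
  }
})
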