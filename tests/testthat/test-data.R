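test_that("the default class composition matches the published dataset", {
  cc <- default_class_counts()
  expect_equal(cc$class, eye_disease_classes())
  expect_equal(sum(cc$train), 3451L)
  expect_equal(sum(cc$test), 1149L)
  expect_equal(cc$train[cc$class == "Uveitis"], 40L)
  expect_equal(cc$test[cc$class == "Uveitis"], 10L)
  expect_equal(cc$train[cc$class == "Cataracts"], 813L)
  expect_equal(cc$test[cc$class == "Cataracts"], 272L)
  expect_equal(max(cc$test), 275L)   # Diabetic_retinopathy, the modal class
})

test_that("generation writes the requested counts deterministically", {
  spec <- synthetic_spec(counts = balanced_counts(3L, 2L), image_size = 16L,
                         seed = 42L)
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  m1 <- generate_synthetic_dataset(spec, d1)
  m2 <- generate_synthetic_dataset(spec, d2)
  expect_equal(nrow(m1), 7L * 5L)
  expect_equal(sum(m1$split == "train"), 21L)
  expect_equal(sum(m1$split == "test"), 14L)
  expect_true(all(file.exists(m1$path)))
  expect_identical(unname(tools::md5sum(m1$path)),
                   unname(tools::md5sum(m2$path)))
  # a different seed must change the pixels
  m3 <- generate_synthetic_dataset(
    synthetic_spec(counts = balanced_counts(3L, 2L), image_size = 16L,
                   seed = 43L),
    file.path(tempdir(), "gen_c"))
  expect_false(identical(unname(tools::md5sum(m1$path)),
                         unname(tools::md5sum(m3$path))))
  expect_equal(attr(m1, "source"), "synthetic")
})

test_that("the folder loader mirrors the on-disk layout and rejects junk", {
  spec <- synthetic_spec(counts = balanced_counts(2L, 1L), image_size = 16L,
                         seed = 7L)
  root <- file.path(tempdir(), "folder_ds")
  man <- generate_synthetic_dataset(spec, root)
  writeLines("not an image", file.path(root, "train", "Cataracts", "x.txt"))
  got <- load_image_folder(root)
  expect_equal(nrow(got), nrow(man))
  expect_setequal(got$path, man$path)          # the .txt file is ignored
  expect_equal(attr(got, "source"), "folder")

  dir.create(file.path(root, "train", "Pinkeye"))
  expect_error(load_image_folder(root), "Pinkeye")
  unlink(file.path(root, "train", "Pinkeye"), recursive = TRUE)
  dir.create(file.path(root, "test", "Uveitis"), showWarnings = FALSE)
  # Uveitis test dir exists and has images; empty a different one
  empty <- file.path(root, "test", "Normal")
  unlink(list.files(empty, full.names = TRUE))
  expect_warning(load_image_folder(root), "empty class directory")
  expect_error(load_image_folder(tempdir()), "train/")
})

test_that("manifests round-trip through CSV", {
  man <- easy_dataset()
  p <- tempfile(fileext = ".csv")
  write_manifest(man, p)
  man2 <- read_manifest(p)
  expect_equal(man2$path, man$path)
  expect_equal(man2$label, man$label)
  expect_equal(man2$split, man$split)
})

test_that("preprocessing scales, resizes and preserves means", {
  w <- tempfile(fileext = ".png")
  png::writePNG(array(1, dim = c(32, 32, 3)), w)
  expect_equal(preprocess(w, size = 16L), array(1, dim = c(3, 16, 16)))
  b <- tempfile(fileext = ".png")
  png::writePNG(array(0, dim = c(32, 32, 3)), b)
  expect_equal(preprocess(b, size = 16L), array(0, dim = c(3, 16, 16)))
  # factor-2 bilinear downsampling of a checkerboard is an exact block
  # average, so the image mean is preserved
  cb <- array(0, dim = c(448, 448, 3))
  cb[, , 1] <- outer(1:448, 1:448, function(i, j) (i + j) %% 2)
  cb[, , 2] <- cb[, , 1]; cb[, , 3] <- cb[, , 1]
  f <- tempfile(fileext = ".png")
  png::writePNG(cb, f)
  out <- preprocess(f, size = 224L)
  expect_equal(dim(out), c(3L, 224L, 224L))
  expect_lt(abs(mean(out) - mean(cb)), 1e-6)
  # grayscale images are expanded to three identical channels
  g <- tempfile(fileext = ".png")
  png::writePNG(matrix(stats::runif(64), 8, 8), g)
  pg <- preprocess(g, size = 8L)
  expect_equal(pg[1, , ], pg[3, , ])
  expect_error(preprocess(tempfile(fileext = ".bmp")), "decode")
})

test_that("epoch batching is a deterministic partition", {
  b <- batch_indices(10L, 4L, shuffle_seed = 1L)
  expect_equal(lengths(b, use.names = FALSE), c(4L, 4L, 2L))
  expect_setequal(unlist(b), 1:10)
  expect_identical(batch_indices(10L, 4L, 1L, epoch = 3L),
                   batch_indices(10L, 4L, 1L, epoch = 3L))
  expect_false(identical(unlist(batch_indices(100L, 10L, 1L, epoch = 0L)),
                         unlist(batch_indices(100L, 10L, 1L, epoch = 1L))))
  expect_error(batch_indices(0L, 4L, 1L), "empty")
})

test_that("motif contrast controls class separability", {
  # fully separable conditions: a trivial pixel-statistic classifier works
  man <- easy_dataset(n_train = 12L, n_test = 6L)
  expect_gt(centroid_classifier_accuracy(man), 0.95)
  # with separability zero the classes are identical up to noise: accuracy
  # must be statistically indistinguishable from chance (1/7)
  spec0 <- synthetic_spec(counts = balanced_counts(12L, 6L),
                          image_size = 32L, noise = 0.05,
                          separability = 0, seed = 9L)
  man0 <- generate_synthetic_dataset(spec0, file.path(tempdir(), "s0"))
  acc0 <- centroid_classifier_accuracy(man0)
  n_test <- sum(man0$split == "test")
  pval <- stats::binom.test(round(acc0 * n_test), n_test, 1 / 7)$p.value
  expect_gt(pval, 0.001)
})
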