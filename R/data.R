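#' Class labels
#'
#' The seven eye-disease categories in their fixed project-wide order.
#' Integer class indices are 0-based throughout the package (0 =
#' Bulging_Eyes ... 6 = Normal).
#'
#' @return character vector of length 7.
#' @export
eye_disease_classes <- function() {
  c("Bulging_Eyes", "Cataracts", "Crossed_Eyes", "Diabetic_retinopathy",
    "Glaucoma", "Uveitis", "Normal")
}

#' Default per-class train/test counts
#'
#' The published dataset composition: 3,451 training and 1,149 test images
#' over seven classes with strong imbalance (24 Bulging_Eyes vs 823
#' Diabetic_retinopathy training images). These are the default counts of
#' \code{\link{synthetic_spec}}.
#'
#' @return data.frame with columns \code{class}, \code{train}, \code{test}.
#' @export
default_class_counts <- function() {
  data.frame(class = eye_disease_classes(),
             train = c(24L, 813L, 131L, 823L, 815L, 40L, 805L),
             test = c(6L, 272L, 43L, 275L, 274L, 10L, 269L),
             stringsAsFactors = FALSE)
}

#' Synthetic dataset specification
#'
#' Describes a synthetic seven-class eye-image dataset: per-class train/test
#' counts (default: the published composition), square image size, pixel
#' noise level, class separability and the generation seed.
#'
#' \code{separability} scales the contrast of each class's procedural motif
#' against the shared eye template: at 1 the motifs are at full strength, at
#' 0 every class renders the identical plain eye and no classifier can beat
#' chance. \code{noise} is the standard deviation of i.i.d. Gaussian pixel
#' noise added after rendering (values clipped back to [0, 1]).
#'
#' @param counts data.frame like \code{\link{default_class_counts}}.
#' @param image_size square image edge in pixels (default 224).
#' @param noise pixel noise sigma in [0, 1] (default 0.02).
#' @param separability motif contrast s in [0, 1] (default 0.9).
#' @param seed integer generation seed.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(counts = default_class_counts(),
                           image_size = 224L, noise = 0.02,
                           separability = 0.9, seed = 1L) {
  stopifnot(is.data.frame(counts),
            all(c("class", "train", "test") %in% names(counts)),
            all(counts$train >= 0L), all(counts$test >= 0L),
            setequal(counts$class, eye_disease_classes()),
            image_size >= 8L, noise >= 0, noise <= 1,
            separability >= 0, separability <= 1)
  counts <- counts[match(eye_disease_classes(), counts$class), ]
  structure(list(counts = counts, image_size = as.integer(image_size),
                 noise = noise, separability = separability,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic per-image seed, independent of generation order
image_seed <- function(base, class_idx, split, i) {
  s <- (as.double(base %% 1000003L) * 2654L +
          class_idx * 97003L + (if (split == "test") 31L else 0L) +
          i * 13L)
  as.integer(s %% 2147483629)
}

# render one synthetic eye image: array (S, S, 3) in [0, 1]
render_eye <- function(class_idx, size, s, sigma, seed) {
  set.seed(seed)
  S <- size
  xv <- seq(-1, 1, length.out = S)
  X <- matrix(xv, S, S, byrow = TRUE)    # x varies along columns
  Y <- matrix(xv, S, S)                  # y varies along rows
  img <- array(0, dim = c(S, S, 3L))
  # skin background with mild vertical shading
  base <- c(0.80, 0.68, 0.58)
  for (c3 in 1:3) img[, , c3] <- base[c3] - 0.05 * Y
  # class geometry deviations
  ax <- 0.78; ay <- 0.45            # sclera semi-axes
  cx <- 0; pupil_r <- 0.10; iris_r <- 0.24
  lens_opacity <- 0; ring <- 0; lesions <- 0L
  if (class_idx == 0L) { ax <- ax * (1 + 0.25 * s); ay <- ay * (1 + 0.55 * s) }
  if (class_idx == 1L) lens_opacity <- s
  if (class_idx == 2L) cx <- 0.38 * s
  if (class_idx == 4L) pupil_r <- pupil_r + 0.16 * s
  if (class_idx == 5L) ring <- s
  if (class_idx == 3L) lesions <- 14L
  inside <- (X / ax)^2 + (Y / ay)^2 <= 1
  sclera <- c(0.97, 0.96, 0.94)
  for (c3 in 1:3) img[, , c3][inside] <- sclera[c3]
  r2 <- (X - cx)^2 + Y^2
  iris_px <- inside & r2 <= iris_r^2
  iris_col <- c(0.42, 0.30, 0.16)
  for (c3 in 1:3) img[, , c3][iris_px] <- iris_col[c3]
  if (ring > 0) {  # uveitis: inflamed red annulus around the iris
    ann <- inside & r2 > iris_r^2 & r2 <= (iris_r + 0.10)^2
    red <- c(0.85, 0.15, 0.15)
    for (c3 in 1:3)
      img[, , c3][ann] <- (1 - ring) * img[, , c3][ann] + ring * red[c3]
  }
  pupil_px <- r2 <= pupil_r^2
  for (c3 in 1:3) img[, , c3][pupil_px] <- 0.05
  if (lens_opacity > 0) {  # cataract: bright opacity over the lens
    lens <- r2 <= (pupil_r + 0.06)^2
    opal <- c(0.88, 0.88, 0.82)
    for (c3 in 1:3)
      img[, , c3][lens] <- (1 - lens_opacity) * img[, , c3][lens] +
        lens_opacity * opal[c3]
  }
  if (lesions > 0L) {  # diabetic retinopathy: scattered small red lesions
    for (l in seq_len(lesions)) {
      lx <- stats::runif(1, -0.6, 0.6); ly <- stats::runif(1, -0.35, 0.35)
      lr <- stats::runif(1, 0.02, 0.05)
      px <- inside & ((X - lx)^2 + (Y - ly)^2 <= lr^2)
      les <- c(0.75, 0.10, 0.05)
      for (c3 in 1:3)
        img[, , c3][px] <- (1 - s) * img[, , c3][px] + s * les[c3]
    }
  }
  if (sigma > 0)
    img <- img + array(stats::rnorm(length(img), sd = sigma), dim = dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic eye-image dataset
#'
#' Writes PNG images into \code{out_dir/{train,test}/<ClassName>/}, one
#' procedural motif per class (enlarged sclera for bulging eyes, bright lens
#' opacity for cataracts, off-center pupil for crossed eyes, scattered red
#' lesions for diabetic retinopathy, enlarged pupil for glaucoma, inflamed
#' iris ring for uveitis, plain eye for normal). Motif contrast scales with
#' the spec's \code{separability}; i.i.d. Gaussian pixel noise with the
#' spec's \code{noise} sigma is added. Generation is fully deterministic
#' given the spec seed: every image has its own derived seed, so outputs are
#' byte-identical across runs and independent of generation order.
#'
#' The synthetic motifs are a desk-scale stand-in for the real (Kaggle and
#' hospital) photographs, which are not redistributable; no clinical realism
#' is claimed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param out_dir writable output directory (created if missing).
#' @return the dataset manifest: data.frame with columns \code{path},
#'   \code{class}, \code{label} (0-based), \code{split}; attribute
#'   \code{source = "synthetic"}.
#' @export
generate_synthetic_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("generate_synthetic_dataset: cannot write to ", out_dir)
  classes <- eye_disease_classes()
  rows <- list()
  for (split in c("train", "test")) {
    for (ci in seq_along(classes)) {
      n <- spec$counts[[split]][ci]
      if (n == 0L) next
      cdir <- file.path(out_dir, split, classes[ci])
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n)) {
        img <- render_eye(ci - 1L, spec$image_size, spec$separability,
                          spec$noise,
                          image_seed(spec$seed, ci - 1L, split, i))
        p <- file.path(cdir, sprintf("%s_%04d.png", tolower(classes[ci]), i))
        png::writePNG(img, p)
        rows[[length(rows) + 1L]] <- data.frame(
          path = p, class = classes[ci], label = ci - 1L, split = split,
          stringsAsFactors = FALSE)
      }
    }
  }
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  attr(man, "source") <- "synthetic"
  man
}

#' Load a class-subdirectory image dataset
#'
#' Reads a \code{root/{train,test}/<ClassName>/*.png|jpg|jpeg} layout into a
#' manifest. Directory names must be known class labels; unknown names raise
#' an error listing them, empty class directories raise a warning, and files
#' with other extensions are ignored.
#'
#' @param root dataset root containing \code{train/} and \code{test/}.
#' @return manifest data.frame (path, class, label, split), attribute
#'   \code{source = "folder"}.
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(file.path(root, "train")) ||
      !dir.exists(file.path(root, "test")))
    stop("load_image_folder: ", root, " must contain train/ and test/")
  classes <- eye_disease_classes()
  rows <- list()
  for (split in c("train", "test")) {
    dirs <- list.dirs(file.path(root, split), recursive = FALSE,
                      full.names = FALSE)
    unknown <- setdiff(dirs, classes)
    if (length(unknown))
      stop("load_image_folder: unknown class directories in ", split, "/: ",
           paste(unknown, collapse = ", "))
    for (cl in dirs) {
      files <- list.files(file.path(root, split, cl),
                          pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                          full.names = TRUE)
      if (length(files) == 0L) {
        warning("load_image_folder: empty class directory ",
                file.path(split, cl))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = files, class = cl, label = match(cl, classes) - 1L,
        split = split, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("load_image_folder: no images found in ", root)
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  if (anyDuplicated(man$path)) stop("load_image_folder: duplicate paths")
  attr(man, "source") <- "folder"
  man
}

#' Write / read a dataset manifest as CSV
#'
#' @param manifest manifest data.frame.
#' @param path CSV file path.
#' @return \code{read_manifest} returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[c("path", "class", "label", "split")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "class", "label", "split") %in% names(man)))
  man
}

# bilinear interpolation weight matrix mapping n_in samples to n_out
bilinear_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5   # 1-based continuous source coordinate
    lo <- floor(src); frac <- src - lo
    lo <- min(max(lo, 1L), n_in); hi <- min(lo + 1L, n_in)
    w[i, lo] <- w[i, lo] + (1 - frac)
    w[i, hi] <- w[i, hi] + frac
  }
  w
}

bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1L] == out_h && d[2L] == out_w) return(img)
  A <- bilinear_weights(d[1L], out_h)
  B <- t(bilinear_weights(d[2L], out_w))
  out <- array(0, dim = c(out_h, out_w, d[3L]))
  for (c3 in seq_len(d[3L])) out[, , c3] <- A %*% img[, , c3] %*% B
  out
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package: ", path)
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- aperm(img, c(2L, 1L, 3L))
    else img <- t(img)
  } else {
    stop("preprocess: cannot decode ", path, " (extension .", ext, ")")
  }
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Decode and preprocess one image
#'
#' Reads a PNG (or JPEG, via EBImage) file, converts grayscale to 3 channels,
#' drops any alpha channel, bilinearly resizes to \code{size x size} and
#' returns a (3, size, size) array of RGB values in [0, 1]. No mean/std
#' normalization is applied: the network is trained from scratch, not from
#' pretrained weights.
#'
#' @param path image file path.
#' @param size output edge length (default 224).
#' @return numeric array (3, size, size).
#' @export
preprocess <- function(path, size = 224L) {
  img <- bilinear_resize(read_image(path), size, size)
  aperm(img, c(3L, 1L, 2L))
}

#' Load a manifest into a batch tensor
#'
#' Decodes every image of (a split of) a manifest into one (N, 3, size,
#' size) array plus its 0-based label vector. Convenient for desk-scale
#' datasets that fit in memory; the training loop uses it to avoid repeated
#' decoding.
#'
#' @param manifest manifest data.frame.
#' @param size image edge length.
#' @param split optional \code{"train"} or \code{"test"} filter.
#' @return list with \code{x} (N, 3, size, size) and \code{y} (length-N
#'   integer labels, 0-based).
#' @export
load_image_tensor <- function(manifest, size = 224L, split = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  n <- nrow(manifest)
  if (n == 0L) stop("load_image_tensor: empty manifest")
  x <- array(0, dim = c(n, 3L, size, size))
  for (i in seq_len(n)) x[i, , , ] <- preprocess(manifest$path[i], size)
  list(x = x, y = as.integer(manifest$label))
}

#' Deterministic epoch batching
#'
#' Splits manifest row indices into shuffled batches for one epoch. The
#' shuffle is deterministic per \code{(shuffle_seed, epoch)}; every record
#' appears exactly once and the final short batch is kept.
#'
#' @param n number of records (or a manifest data.frame).
#' @param batch_size batch size >= 1.
#' @param shuffle_seed integer seed.
#' @param epoch 0-based epoch index.
#' @return list of integer index vectors.
#' @export
batch_indices <- function(n, batch_size, shuffle_seed, epoch = 0L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 1L) stop("batch_indices: empty manifest")
  stopifnot(batch_size >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((as.integer(shuffle_seed) + 7919L * as.integer(epoch)) %%
             2147483629L)
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
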