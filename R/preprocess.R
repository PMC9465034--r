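#' Crop the region of interest around the insect body
#'
#' Cuts a square window (140 x 140 by default) centred on the centroid of the
#' foreground mask. When the window overruns the frame, the image border is
#' expanded by edge replication before cropping, so the output always has the
#' requested size.
#'
#' @param image `H x W x 3` array.
#' @param mask logical foreground mask (>= 1 pixel set).
#' @param size ROI side length, px.
#' @return A `size x size x 3` array.
#' @export
crop_roi <- function(image, mask, size = 140L) {
  if (!any(mask)) stop("empty mask: route this capture through QC instead")
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  size <- as.integer(size)
  cy <- round(mean(row(mask)[mask]))
  cx <- round(mean(col(mask)[mask]))
  half <- size %/% 2L
  rows <- (cy - half + 1L):(cy - half + size)
  cols <- (cx - half + 1L):(cx - half + size)
  rows <- pmin(pmax(rows, 1L), nrow(mask))  # edge replication
  cols <- pmin(pmax(cols, 1L), ncol(mask))
  image[rows, cols, , drop = FALSE]
}

rotate90 <- function(img, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(img)
  rot_one <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  for (i in seq_len(k))
    img <- {
      out <- array(0, dim = c(dim(img)[2], dim(img)[1], dim(img)[3]))
      for (ch in seq_len(dim(img)[3])) out[, , ch] <- rot_one(img[, , ch])
      out
    }
  img
}

shear_image <- function(img, factor) {
  if (factor == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  centre <- (h + 1) / 2
  out <- img
  for (i in seq_len(h)) {
    src <- round(seq_len(w) + factor * (i - centre))
    src <- pmin(pmax(src, 1L), w)  # edge replication fill
    out[i, , ] <- img[i, src, ]
  }
  out
}

#' Online training augmentation
#'
#' The real-time augmentation applied to training images only: rotation by a
#' random multiple of 90 degrees, horizontal shear with a factor drawn
#' uniformly from \[0, 0.5\] (the image is resampled with edge-replication
#' fill), and independent horizontal/vertical flips. Output size equals input
#' size; the input must be square.
#'
#' @param image square `H x H x 3` array.
#' @param seed integer seed; ignored when `transforms` is supplied.
#' @param transforms optional list `list(rot = k, shear = s, flip_h =, flip_v =)`
#'   fixing the transform deterministically (all-off gives the identity).
#' @return The augmented array.
#' @export
augment <- function(image, seed = 1L, transforms = NULL) {
  stopifnot(dim(image)[1] == dim(image)[2])
  if (is.null(transforms)) {
    transforms <- withr::with_seed(as.integer(seed), list(
      rot = sample(0:3, 1), shear = stats::runif(1, 0, 0.5),
      flip_h = stats::runif(1) < 0.5, flip_v = stats::runif(1) < 0.5))
  }
  img <- rotate90(image, transforms$rot)
  img <- shear_image(img, transforms$shear)
  if (isTRUE(transforms$flip_h)) img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (isTRUE(transforms$flip_v)) img <- img[dim(img)[1]:1, , , drop = FALSE]
  img
}

# Largest-remainder apportionment of n into parts proportional to p,
# ties resolved in part order (train first).
apportion <- function(n, p) {
  p <- p / sum(p)
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    extra <- order(frac, seq_along(p), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits per class in the given proportions using largest-remainder
#' rounding with ties resolved toward train, then val, then test; this
#' reproduces, e.g., 6300/1350/1350 for 9000 images at 7:1.5:1.5 and
#' 852/284/284 for 1420 at 6:2:2.
#'
#' @param ds an [insect_dataset].
#' @param ratios positive length-3 weights for train/val/test (normalized
#'   internally).
#' @param seed integer seed for the within-class shuffle.
#' @return The dataset with its `split` field assigned.
#' @export
split_dataset <- function(ds, ratios = c(7, 1.5, 1.5), seed = 1L) {
  stopifnot(inherits(ds, "insect_dataset"), length(ratios) == 3, all(ratios >= 0),
            sum(ratios) > 0)
  split <- rep(NA_character_, length(ds$images))
  withr::with_seed(as.integer(seed), {
    for (c in sort(unique(ds$labels))) {
      idx <- which(ds$labels == c)
      if (length(idx) < 3) stop(sprintf("class %d has fewer than 3 images", c))
      counts <- apportion(length(idx), ratios)
      idx <- sample(idx)
      split[idx] <- rep(c("train", "val", "test"), counts)
    }
  })
  ds$split <- split
  ds
}

#' Extract one split of a dataset
#' @param ds an [insect_dataset]; @param which `"train"`, `"val"` or `"test"`.
#' @return The subsetted [insect_dataset].
#' @export
dataset_split <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  dataset_subset(ds, which(ds$split == which))
}

class_sizes <- function(ds) {
  vapply(seq_along(ds$class_names) - 1L,
         function(c) sum(ds$labels == c), integer(1))
}

#' Rebalance the field dataset's oversized fourth category
#'
#' The field dataset has three small target-insect classes and a large
#' non-target/noise fourth class; this keeps classes 0--2 whole and randomly
#' downsamples class 3 to `n_fourth` images (70 by default).
#'
#' @param ds2 a 4-class [insect_dataset].
#' @param n_fourth images to keep in class 3.
#' @param seed integer seed.
#' @return An [insect_dataset] with provenance `"dataset2_1"`.
#' @export
build_dataset2_1 <- function(ds2, n_fourth = 70L, seed = 1L) {
  stopifnot(inherits(ds2, "insect_dataset"))
  if (length(ds2$class_names) != 4L) stop("dataset must have exactly 4 classes")
  fourth <- which(ds2$labels == 3L)
  if (length(fourth) < n_fourth)
    stop(sprintf("class 3 has %d images, fewer than n_fourth = %d",
                 length(fourth), n_fourth))
  keep4 <- withr::with_seed(as.integer(seed),
                            sort(sample(fourth, n_fourth)))
  out <- dataset_subset(ds2, sort(c(which(ds2$labels < 3L), keep4)))
  out$provenance <- "dataset2_1"
  out
}

#' Filling mix of lab and field training sets
#'
#' Pads each of the field training set's three target classes with lab
#' (Dataset 1) images until every target class matches the size of the field
#' set's fourth (non-target) class; the fourth class is left unchanged.
#'
#' @param ds1_train lab training set with classes 0--2 (extra classes allowed
#'   are ignored beyond 0--2).
#' @param ds2_train field training set with classes 0--3.
#' @param seed integer seed for sampling the padding images.
#' @return An [insect_dataset] with provenance `"filled_mix"`, every image
#'   marked `train`.
#' @export
filling_mix <- function(ds1_train, ds2_train, seed = 1L) {
  stopifnot(inherits(ds1_train, "insect_dataset"),
            inherits(ds2_train, "insect_dataset"))
  if (length(ds2_train$class_names) != 4L) stop("field set must have 4 classes")
  target <- sum(ds2_train$labels == 3L)
  if (target == 0L) stop("degenerate input: field fourth class is empty")
  pieces <- list()
  withr::with_seed(as.integer(seed), {
    for (c in 0:2) {
      have <- which(ds2_train$labels == c)
      need <- target - length(have)
      if (need < 0) stop("field class already larger than the fourth class")
      pool <- which(ds1_train$labels == c)
      if (length(pool) < need)
        stop(sprintf("lab set lacks %d images to fill class %d", need, c))
      pad <- if (need > 0) sort(sample(pool, need)) else integer(0)
      piece1 <- dataset_subset(ds2_train, have)
      piece2 <- dataset_subset(ds1_train, pad)
      piece2$labels <- rep(c, length(piece2$labels))  # same class by construction
      piece2$class_names <- ds2_train$class_names
      pieces[[length(pieces) + 1L]] <- piece1
      pieces[[length(pieces) + 1L]] <- piece2
    }
  })
  pieces[[length(pieces) + 1L]] <- dataset_subset(ds2_train,
                                                  which(ds2_train$labels == 3L))
  out <- Reduce(function(a, b) dataset_bind(a, b), pieces)
  out$provenance <- "filled_mix"
  out$split <- rep("train", length(out$images))
  if (anyDuplicated(out$ids)) stop("duplicate image identities in mixed set")
  out
}

#' Symmetric mix of lab and rebalanced field training sets
#'
#' Doubles every class: for each target class, all images of the rebalanced
#' field training set plus the same number sampled from the lab set; for the
#' fourth class, all its field images plus the same number from an external
#' pool of fourth-category images disjoint from the field set.
#'
#' @param ds1_train lab training set with classes 0--2.
#' @param ds2_1_train rebalanced field training set with classes 0--3.
#' @param extra_fourth_pool [insect_dataset] of additional class-3 images,
#'   disjoint (by id) from `ds2_1_train`.
#' @param seed integer seed.
#' @return An [insect_dataset] with provenance `"symmetric_mix"`, every image
#'   marked `train`.
#' @export
symmetric_mix <- function(ds1_train, ds2_1_train, extra_fourth_pool, seed = 1L) {
  stopifnot(inherits(ds1_train, "insect_dataset"),
            inherits(ds2_1_train, "insect_dataset"),
            inherits(extra_fourth_pool, "insect_dataset"))
  if (length(ds2_1_train$class_names) != 4L) stop("field set must have 4 classes")
  if (any(extra_fourth_pool$ids %in% ds2_1_train$ids))
    stop("extra fourth-category pool overlaps the field set")
  pieces <- list()
  withr::with_seed(as.integer(seed), {
    for (c in 0:2) {
      have <- which(ds2_1_train$labels == c)
      n_c <- length(have)
      if (n_c == 0L) stop(sprintf("empty class %d in the field set", c))
      pool <- which(ds1_train$labels == c)
      if (length(pool) < n_c)
        stop(sprintf("lab set lacks %d class-%d images", n_c, c))
      piece1 <- dataset_subset(ds2_1_train, have)
      piece2 <- dataset_subset(ds1_train, sort(sample(pool, n_c)))
      piece2$labels <- rep(c, length(piece2$labels))
      piece2$class_names <- ds2_1_train$class_names
      pieces[[length(pieces) + 1L]] <- piece1
      pieces[[length(pieces) + 1L]] <- piece2
    }
    have4 <- which(ds2_1_train$labels == 3L)
    n4 <- length(have4)
    if (n4 == 0L) stop("empty fourth class in the field set")
    pool4 <- which(extra_fourth_pool$labels == 3L)
    if (length(pool4) < n4)
      stop(sprintf("fourth-category pool has %d images, need %d",
                   length(pool4), n4))
    pieces[[length(pieces) + 1L]] <- dataset_subset(ds2_1_train, have4)
    pieces[[length(pieces) + 1L]] <- dataset_subset(extra_fourth_pool,
                                                    sort(sample(pool4, n4)))
  })
  out <- Reduce(function(a, b) dataset_bind(a, b), pieces)
  out$provenance <- "symmetric_mix"
  out$split <- rep("train", length(out$images))
  if (anyDuplicated(out$ids)) stop("duplicate image identities in mixed set")
  out
}
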