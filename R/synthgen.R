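#' Scene specification for synthetic falling-insect sequences
#'
#' Describes a static, noisy camera background plus a single dark insect body
#' that moves along a supplied per-frame trajectory (the capture channel of a
#' light-trap imaging device photographs insects falling in a parabola in
#' front of a fixed background). Intensities are on the 8-bit scale 0--255.
#'
#' @param frame_size integer vector `c(height, width)` in pixels.
#' @param background_mean mean background intensity (0--255).
#' @param background_noise_sigma per-pixel Gaussian noise standard deviation,
#'   in intensity units.
#' @param object_axes ellipse semi-axes `c(a, b)` of the insect body, pixels.
#' @param object_orientation ellipse orientation, radians.
#' @param object_intensity mean body intensity (0--255); the body is rendered
#'   with this value on all three channels unless `object_color` is given.
#' @param object_color optional RGB triplet overriding `object_intensity`.
#' @param trajectory matrix with one row per frame and columns `(y, x)` giving
#'   the body centroid per frame, or `NULL` for a background-only scene.
#' @param blur_sigma Gaussian blur applied to the rendered body (pixels);
#'   emulates soft focus on a moving target. Ground-truth masks are taken
#'   before blurring.
#' @param clutter_rate probability per frame that a small transient blob
#'   (3--10 px, lasting 1--2 frames) appears, emulating debris and small
#'   non-target insects.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(frame_size = c(200L, 200L),
                       background_mean = 160,
                       background_noise_sigma = 8,
                       object_axes = c(12, 7),
                       object_orientation = 0.4,
                       object_intensity = 60,
                       object_color = NULL,
                       trajectory = NULL,
                       blur_sigma = 1,
                       clutter_rate = 0.05) {
  stopifnot(length(frame_size) == 2L, all(frame_size >= 8))
  if (background_mean < 0 || background_mean > 255)
    stop("background_mean must lie in [0, 255]")
  if (object_intensity < 0 || object_intensity > 255)
    stop("object_intensity must lie in [0, 255]")
  if (any(object_axes <= 0)) stop("object axes must be positive")
  if (background_noise_sigma < 0) stop("background_noise_sigma must be >= 0")
  if (clutter_rate < 0 || clutter_rate > 1) stop("clutter_rate must be in [0, 1]")
  if (!is.null(trajectory)) {
    trajectory <- as.matrix(trajectory)
    if (ncol(trajectory) != 2L) stop("trajectory must have columns (y, x)")
  }
  if (!is.null(object_color)) {
    stopifnot(length(object_color) == 3L)
    if (any(object_color < 0 | object_color > 255))
      stop("object_color must lie in [0, 255]")
  }
  structure(list(frame_size = as.integer(frame_size),
                 background_mean = background_mean,
                 background_noise_sigma = background_noise_sigma,
                 object_axes = object_axes,
                 object_orientation = object_orientation,
                 object_intensity = object_intensity,
                 object_color = object_color,
                 trajectory = trajectory,
                 blur_sigma = blur_sigma,
                 clutter_rate = clutter_rate),
            class = "scene_spec")
}

#' Parabolic fall trajectory across the camera view
#'
#' Convenience constructor for the centroid path of a body entering the frame
#' near the top with a small horizontal velocity and accelerating downwards.
#'
#' @param n_frames number of frames.
#' @param frame_size `c(height, width)` in pixels.
#' @param x0,y0 entry position; the default starts just above the frame, so
#'   the body enters the view while falling (and the background model sees
#'   object-free frames first).
#' @param vx horizontal velocity, px/frame.
#' @param g vertical acceleration, px/frame^2.
#' @return An `n_frames` x 2 matrix of `(y, x)` positions.
#' @export
parabolic_trajectory <- function(n_frames, frame_size = c(200L, 200L),
                                 x0 = frame_size[2] * 0.3,
                                 y0 = -frame_size[1] * 0.15,
                                 vx = frame_size[2] * 0.4 / n_frames,
                                 g = 2 * frame_size[1] * 1.3 / n_frames^2) {
  t <- seq_len(n_frames) - 1
  cbind(y = y0 + 0.5 * g * t^2, x = x0 + vx * t)
}

# Filled-ellipse mask on an h x w grid; (cy, cx) centre, (a, b) semi-axes,
# theta orientation of the major axis.
ellipse_mask <- function(h, w, cy, cx, a, b, theta = 0) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Replicate a matrix into an H x W x 3 array.
gray_to_rgb <- function(m) array(m, dim = c(dim(m), 3L))

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # gblur's kernel cannot exceed the image; pad small windows by replication
  brush <- 2 * ceiling(3 * sigma) + 1
  pad <- max(0L, ceiling((brush + 1 - min(dim(m))) / 2))
  if (pad > 0L) {
    ri <- pmin(pmax(seq_len(nrow(m) + 2 * pad) - pad, 1L), nrow(m))
    ci <- pmin(pmax(seq_len(ncol(m) + 2 * pad) - pad, 1L), ncol(m))
    out <- EBImage::gblur(m[ri, ci, drop = FALSE], sigma = sigma)
    return(out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m)), drop = FALSE])
  }
  EBImage::gblur(m, sigma = sigma)
}

#' Render a synthetic frame sequence with ground-truth masks
#'
#' Composites, frame by frame, a noisy grayscale background, an optional
#' moving insect body (blurred by `blur_sigma` after the ground-truth mask is
#' taken), and transient clutter blobs. Identical `(spec, seed)` give
#' bitwise-identical output.
#'
#' @param spec a [scene_spec()].
#' @param n_frames number of frames to render (>= 1).
#' @param seed integer seed controlling noise and clutter.
#' @return A list of class `frame_sequence` with elements `frames` (list of
#'   `H x W x 3` arrays, 0--255), `truth_masks` (list of logical `H x W`
#'   matrices marking the un-blurred body pixels), and `spec`.
#' @export
render_sequence <- function(spec, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1)
  if (!is.null(spec$trajectory) && nrow(spec$trajectory) < n_frames)
    stop("trajectory has fewer rows than n_frames")
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  col <- if (is.null(spec$object_color)) rep(spec$object_intensity, 3) else spec$object_color
  withr::with_seed(as.integer(seed), {
    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    clutter <- list()  # each: list(mask, ttl, intensity)
    for (t in seq_len(n_frames)) {
      bg <- spec$background_mean +
        if (spec$background_noise_sigma > 0)
          matrix(stats::rnorm(h * w, 0, spec$background_noise_sigma), h, w)
        else 0
      bg <- matrix(clamp255(bg), h, w)
      frame <- gray_to_rgb(bg)

      # transient clutter: spawn, draw, age out
      if (spec$clutter_rate > 0 && stats::runif(1) < spec$clutter_rate) {
        r <- sqrt(stats::runif(1, 3, 10) / pi)
        cm <- ellipse_mask(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w), r, r)
        clutter[[length(clutter) + 1L]] <-
          list(mask = cm, ttl = sample(1:2, 1), intensity = stats::runif(1, 20, 90))
      }
      keep <- logical(length(clutter))
      for (i in seq_along(clutter)) {
        cl <- clutter[[i]]
        for (ch in 1:3) {
          plane <- frame[, , ch]
          plane[cl$mask] <- cl$intensity
          frame[, , ch] <- plane
        }
        clutter[[i]]$ttl <- cl$ttl - 1L
        keep[i] <- clutter[[i]]$ttl > 0L
      }
      clutter <- clutter[keep]

      # insect body, rendered inside a local window for speed
      mask <- matrix(FALSE, h, w)
      if (!is.null(spec$trajectory)) {
        pos <- spec$trajectory[t, ]
        half <- ceiling(max(spec$object_axes) + 3 * spec$blur_sigma + 2)
        r0 <- max(1, floor(pos[1]) - half); r1 <- min(h, ceiling(pos[1]) + half)
        c0 <- max(1, floor(pos[2]) - half); c1 <- min(w, ceiling(pos[2]) + half)
        if (r0 < r1 && c0 < c1) {
          rr <- r0:r1
          cc <- c0:c1
          sub <- ellipse_mask(length(rr), length(cc),
                              pos[1] - rr[1] + 1, pos[2] - cc[1] + 1,
                              spec$object_axes[1], spec$object_axes[2],
                              spec$object_orientation)
          if (any(sub)) {
            mask[rr, cc] <- sub
            alpha <- gaussian_blur(sub * 1, spec$blur_sigma)
            for (ch in 1:3)
              frame[rr, cc, ch] <- frame[rr, cc, ch] * (1 - alpha) +
                col[ch] * alpha
          }
        }
      }
      frames[[t]] <- clamp255(frame)
      masks[[t]] <- mask
    }
    structure(list(frames = frames, truth_masks = masks, spec = spec),
              class = "frame_sequence")
  })
}

#' Insect class specification for synthetic labelled image sets
#'
#' Parameterises a visually distinguishable insect class by body colour,
#' stripe texture, elongation and size. `size_px` is the mean body area in
#' pixels at the 140 px reference frame; it is scaled with the squared ratio
#' of the rendered image size to 140 so the body occupies a comparable
#' fraction of the frame at any resolution.
#'
#' @param class_name label.
#' @param body_color_mean,body_color_sigma RGB mean and between-image sd.
#' @param texture_period stripe period along the body axis, px (reference scale).
#' @param shape_elongation major/minor axis ratio (>= 1).
#' @param size_px mean body area, px at the 140 px reference scale.
#' @param type `"insect"` or `"noise"`; a noise class renders cluttered,
#'   distorted non-target frames instead of a single body.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(class_name, body_color_mean, body_color_sigma = c(10, 10, 10),
                       texture_period = 6, shape_elongation = 2, size_px = 3000,
                       type = c("insect", "noise")) {
  type <- match.arg(type)
  stopifnot(length(body_color_mean) == 3L, shape_elongation >= 1, size_px > 0,
            texture_period > 0)
  structure(list(class_name = class_name, body_color_mean = body_color_mean,
                 body_color_sigma = body_color_sigma,
                 texture_period = texture_period,
                 shape_elongation = shape_elongation, size_px = size_px,
                 type = type),
            class = "class_spec")
}

#' Default class specifications
#'
#' Three separable moth-like classes standing in for the cotton bollworm moth
#' (tan, striped), the corn borer moth (pale yellow, slender) and *Spodoptera
#' litura* (dark brown, broad), plus an optional fourth non-target/noise
#' class. Colours, sizes and textures are chosen so that the classes are
#' distinguishable by more than one cue and a nearest-centroid classifier on
#' mean RGB alone already separates them well.
#'
#' @param include_noise add the fourth non-target/noise class.
#' @return A list of [class_spec()] objects.
#' @export
default_class_specs <- function(include_noise = FALSE) {
  specs <- list(
    class_spec("bollworm_moth", c(168, 138, 92), c(12, 12, 12),
               texture_period = 7, shape_elongation = 1.9, size_px = 4000),
    class_spec("borer_moth", c(208, 192, 130), c(10, 10, 10),
               texture_period = 4, shape_elongation = 2.6, size_px = 2600),
    class_spec("spodoptera_litura", c(96, 76, 60), c(10, 10, 10),
               texture_period = 9, shape_elongation = 1.5, size_px = 5200))
  if (include_noise)
    specs <- c(specs, list(
      class_spec("non_target", c(130, 130, 130), c(40, 40, 40),
                 texture_period = 5, shape_elongation = 1.2, size_px = 1500,
                 type = "noise")))
  specs
}

render_class_image <- function(cs, image_size, background_mean = 160) {
  s <- image_size
  scale2 <- (s / 140)^2
  bg <- clamp255(background_mean + matrix(stats::rnorm(s * s, 0, 3), s, s))
  img <- gray_to_rgb(bg)
  if (cs$type == "noise") {
    # non-target capture: several irregular blobs, heavy noise, smears
    nblob <- sample(2:6, 1)
    for (i in seq_len(nblob)) {
      r <- sqrt(stats::runif(1, 20, 400) * scale2 / pi)
      el <- stats::runif(1, 1, 3)
      m <- ellipse_mask(s, s, stats::runif(1, 1, s), stats::runif(1, 1, s),
                        r * sqrt(el), r / sqrt(el), stats::runif(1, 0, pi))
      colb <- clamp255(stats::rnorm(3, cs$body_color_mean, cs$body_color_sigma))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- colb[ch]
        img[, , ch] <- plane
      }
    }
    img <- img + array(stats::rnorm(s * s * 3, 0, 15), dim = c(s, s, 3))
    return(clamp255(img))
  }
  area <- max(9, stats::rnorm(1, cs$size_px * scale2, 0.08 * cs$size_px * scale2))
  b <- sqrt(area / (pi * cs$shape_elongation))
  a <- b * cs$shape_elongation
  theta <- stats::runif(1, 0, pi)
  cy <- s / 2 + stats::runif(1, -0.06 * s, 0.06 * s)
  cx <- s / 2 + stats::runif(1, -0.06 * s, 0.06 * s)
  m <- ellipse_mask(s, s, cy, cx, a, b, theta)
  colb <- clamp255(stats::rnorm(3, cs$body_color_mean, cs$body_color_sigma))
  # stripe texture along the major axis
  yy <- matrix(seq_len(s), s, s) - cy
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  period <- max(1.5, cs$texture_period * s / 140)
  stripes <- 1 + 0.25 * sin(2 * pi * u / period)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- clamp255(colb[ch] * stripes[m])
    img[, , ch] <- plane
  }
  img <- gaussian_blur_rgb(img, 0.5)
  img <- img + array(stats::rnorm(s * s * 3, 0, 2), dim = c(s, s, 3))
  clamp255(img)
}

gaussian_blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  for (ch in 1:3) img[, , ch] <- gaussian_blur(img[, , ch], sigma)
  img
}

#' Generate a labelled insect image dataset
#'
#' Renders `n_per_class` single-insect images per class on a plain grayscale
#' background, in the style of a small CIFAR-like benchmark. Labels are
#' 0-based class indices in the order of `classes`.
#'
#' @param classes list of [class_spec()] objects (>= 2, unique names).
#' @param n_per_class images per class; a scalar, or a vector with one count
#'   per class for unbalanced sets such as a field collection.
#' @param image_size side length in px (>= 32).
#' @param seed integer seed.
#' @param provenance tag recorded on the dataset; also prefixes image ids, so
#'   give independently generated datasets distinct tags before mixing them.
#' @param color_shift RGB offset added to every class's body colour,
#'   emulating the domain shift between lab and field imagery.
#' @param background_mean background intensity (0--255).
#' @return An [insect_dataset] object.
#' @export
make_insect_dataset <- function(classes, n_per_class, image_size = 32L, seed = 1L,
                                provenance = "synthetic",
                                color_shift = c(0, 0, 0),
                                background_mean = 160) {
  stopifnot(length(classes) >= 2, all(n_per_class >= 1), image_size >= 32)
  nm <- vapply(classes, function(c) c$class_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate class names")
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  if (any(color_shift != 0))
    classes <- lapply(classes, function(cs) {
      cs$body_color_mean <- clamp255(cs$body_color_mean + color_shift)
      cs
    })
  withr::with_seed(as.integer(seed), {
    images <- vector("list", sum(n_per_class))
    labels <- integer(length(images))
    k <- 0L
    for (ci in seq_along(classes)) {
      for (i in seq_len(n_per_class[ci])) {
        k <- k + 1L
        images[[k]] <- render_class_image(classes[[ci]], as.integer(image_size),
                                          background_mean = background_mean)
        labels[k] <- ci - 1L
      }
    }
    insect_dataset(images, labels, class_names = nm, provenance = provenance)
  })
}

#' Labelled insect image set
#'
#' The container shared by the dataset-construction and training stages:
#' a list of `H x W x 3` arrays (0--255), 0-based integer labels, class
#' names, an optional train/val/test split assignment, stable per-image
#' identifiers (used to guarantee mixing strategies never duplicate an image
#' within a split), and a provenance tag.
#'
#' @param images list of `H x W x 3` arrays.
#' @param labels integer vector of 0-based class indices.
#' @param class_names character vector naming classes `0..K-1`.
#' @param split optional character vector (`"train"`, `"val"`, `"test"`) or NA.
#' @param ids optional character identifiers; generated when missing.
#' @param provenance free-form tag (`"dataset1"`, `"dataset2"`, `"dataset2_1"`,
#'   `"filled_mix"`, `"symmetric_mix"`, ...).
#' @return An object of class `insect_dataset`.
#' @export
insect_dataset <- function(images, labels, class_names,
                           split = NULL, ids = NULL, provenance = "unknown") {
  labels <- as.integer(labels)
  stopifnot(length(images) == length(labels))
  if (length(labels) && (min(labels) < 0 || max(labels) >= length(class_names)))
    stop("labels must index class_names (0-based)")
  if (is.null(ids))
    ids <- sprintf("%s_%06d", provenance, seq_along(images))
  if (is.null(split)) split <- rep(NA_character_, length(images))
  stopifnot(length(ids) == length(images), length(split) == length(images))
  structure(list(images = images, labels = labels, class_names = class_names,
                 split = split, ids = ids, provenance = provenance),
            class = "insect_dataset")
}

#' @export
length.insect_dataset <- function(x) length(x$images)

#' @export
print.insect_dataset <- function(x, ...) {
  cat(sprintf("<insect_dataset> %d images, %d classes [%s], provenance: %s\n",
              length(x$images), length(x$class_names),
              paste(x$class_names, collapse = ", "), x$provenance))
  print(dataset_counts(x))
  invisible(x)
}

#' Per-class (and per-split) image counts
#' @param ds an [insect_dataset].
#' @return A table of counts by class (rows) and split (columns, when any
#'   split assignment exists).
#' @export
dataset_counts <- function(ds) {
  cls <- factor(ds$class_names[ds$labels + 1L], levels = ds$class_names)
  if (all(is.na(ds$split))) return(table(class = cls))
  table(class = cls, split = factor(ds$split, levels = c("train", "val", "test")))
}

#' Subset an insect dataset by index
#' @param ds an [insect_dataset]; @param idx integer indices.
#' @return The subsetted [insect_dataset].
#' @export
dataset_subset <- function(ds, idx) {
  insect_dataset(ds$images[idx], ds$labels[idx], ds$class_names,
                 split = ds$split[idx], ids = ds$ids[idx],
                 provenance = ds$provenance)
}

#' Bind two datasets with the same class set
#' @keywords internal
dataset_bind <- function(a, b, provenance = a$provenance) {
  stopifnot(identical(a$class_names, b$class_names))
  insect_dataset(c(a$images, b$images), c(a$labels, b$labels), a$class_names,
                 split = c(a$split, b$split), ids = c(a$ids, b$ids),
                 provenance = provenance)
}

#' Daily count series specification
#'
#' Deterministic geometric growth `count(d) = round(base * growth^d)` for day
#' index `d = 0, 1, ...`, with optional Poisson sampling around that mean
#' (`noise > 0`), the natural noise model for trap counts.
#'
#' @param n_days length of the series (>= 1).
#' @param base_count expected count on day 0 (>= 0).
#' @param daily_growth multiplicative day-on-day rate.
#' @param noise 0 for the exact deterministic series; any positive value
#'   switches on Poisson sampling with the deterministic series as the mean.
#' @param seed integer seed (used only when `noise > 0`).
#' @return An object of class `count_series_spec`.
#' @export
count_series_spec <- function(n_days, base_count = 10, daily_growth = 1.0,
                              noise = 0, seed = 1L) {
  stopifnot(n_days >= 1)
  if (base_count < 0) stop("base_count must be >= 0")
  if (daily_growth < 0) stop("daily_growth must be >= 0")
  structure(list(n_days = as.integer(n_days), base_count = base_count,
                 daily_growth = daily_growth, noise = noise,
                 seed = as.integer(seed)),
            class = "count_series_spec")
}

#' Generate a daily moth-count series
#'
#' @param spec a [count_series_spec()].
#' @param start_date first day (class `Date`).
#' @return A data.frame with columns `date` and `count` (non-negative
#'   integers), one row per day.
#' @export
make_count_series <- function(spec, start_date = as.Date("2019-08-03")) {
  stopifnot(inherits(spec, "count_series_spec"))
  d <- seq_len(spec$n_days) - 1
  lambda <- spec$base_count * spec$daily_growth^d
  counts <- if (spec$noise > 0)
    withr::with_seed(spec$seed, stats::rpois(spec$n_days, lambda))
  else
    as.integer(round(lambda))
  data.frame(date = start_date + d, count = as.integer(counts))
}

#' Write a rendered sequence to disk
#'
#' Frames and ground-truth masks as PNG plus a JSON manifest holding the
#' capture metadata record (device name, location, timestamp) in the schema
#' used by the acquisition software.
#'
#' @param seq a `frame_sequence` from [render_sequence()].
#' @param dir output directory (created if needed).
#' @param metadata capture metadata list; defaults to a synthetic record.
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir, metadata = list(
                             device_name = "synthetic-trap-01",
                             location = list(lat = 44.316, lon = 86.061),
                             timestamp = "2019-08-03T22:00:00Z")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[t]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", t)))
    png::writePNG(seq$truth_masks[[t]] * 1,
                  file.path(dir, sprintf("mask_%04d.png", t)))
  }
  manifest <- list(n_frames = length(seq$frames),
                   frame_size = seq$spec$frame_size, metadata = metadata)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a count series as CSV (date, count)
#' @param series data.frame from [make_count_series()]; @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read a count series CSV (date, count)
#' @param path file path.
#' @return data.frame with `date` (Date) and `count` (integer).
#' @export
read_count_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(df)))
    stop("counts CSV must have columns date, count")
  df$date <- as.Date(df$date)
  df$count <- as.integer(df$count)
  df
}
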