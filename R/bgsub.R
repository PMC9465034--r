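#' Background-model configuration
#'
#' Parameters of the per-pixel adaptive Gaussian-mixture background model and
#' of the morphological cleanup applied to raw foreground masks. Defaults
#' follow the usual adaptive-mixture conventions: 5 components, learning rate
#' 0.01, a 2.5-standard-deviation match gate and a 0.7 cumulative-weight
#' background fraction, with a 30-frame burn-in before masks are trusted.
#'
#' @param K components per pixel-channel.
#' @param alpha learning rate in (0, 1); 0 freezes the model (no updates).
#' @param match_threshold match gate in standard deviations.
#' @param background_fraction cumulative-weight cutoff T selecting the most
#'   likely components as background.
#' @param init_sigma standard deviation assigned to newly created components.
#' @param var_floor lower bound on component variance.
#' @param low_weight prior weight of a replacement component.
#' @param burn_in frames used to settle the model before masks are emitted.
#' @param morph_size side of the square structuring element for the opening
#'   and closing cleanup; 0 disables cleanup.
#' @return A list of class `bg_config`.
#' @export
bg_config <- function(K = 5L, alpha = 0.01, match_threshold = 2.5,
                      background_fraction = 0.7, init_sigma = 30,
                      var_floor = 4, low_weight = 0.05,
                      burn_in = 30L, morph_size = 3L) {
  stopifnot(K >= 1, alpha >= 0, alpha < 1, match_threshold > 0,
            background_fraction > 0, background_fraction <= 1,
            init_sigma > 0, var_floor > 0, burn_in >= 0)
  structure(list(K = as.integer(K), alpha = alpha,
                 match_threshold = match_threshold,
                 background_fraction = background_fraction,
                 init_sigma = init_sigma, var_floor = var_floor,
                 low_weight = low_weight, burn_in = as.integer(burn_in),
                 morph_size = as.integer(morph_size)),
            class = "bg_config")
}

#' Initialize a single-pixel Gaussian mixture
#'
#' One pixel-channel's mixture state, seeded from the first observed value
#' (component 1 centred on it with full weight).
#'
#' @param first_value the first observed intensity.
#' @param config a [bg_config()].
#' @return A list of class `pixel_mixture` with `weights`, `means`, `vars`
#'   (all length `K`, kept sorted by weight/sd descending) and the config.
#' @export
pixel_mixture <- function(first_value, config = bg_config()) {
  K <- config$K
  structure(list(weights = c(1, rep(0, K - 1L)),
                 means = c(first_value, rep(0, K - 1L)),
                 vars = rep(config$init_sigma^2, K),
                 config = config),
            class = "pixel_mixture")
}

#' One observation update of a pixel mixture
#'
#' If the value matches a component (within `match_threshold` standard
#' deviations, scanning components in decreasing weight/sd order), that
#' component's weight, mean and variance move toward the observation by the
#' learning rate; otherwise the least likely component is replaced by a new
#' one centred on the value. Weights are renormalized after every update and
#' component order restored. A zero learning rate leaves the mixture
#' unchanged.
#'
#' @param mix a [pixel_mixture()].
#' @param value observed intensity.
#' @return The updated `pixel_mixture`.
#' @export
update_pixel <- function(mix, value) {
  stopifnot(inherits(mix, "pixel_mixture"))
  cfg <- mix$config
  if (cfg$alpha == 0) return(mix)
  sds <- sqrt(mix$vars)
  ord <- order(mix$weights / sds, decreasing = TRUE)
  match <- NA_integer_
  for (k in ord) {
    if (mix$weights[k] <= 0) next
    if (abs(value - mix$means[k]) <= cfg$match_threshold * sds[k]) {
      match <- k
      break
    }
  }
  a <- cfg$alpha
  if (!is.na(match)) {
    mix$weights <- (1 - a) * mix$weights
    mix$weights[match] <- mix$weights[match] + a
    d <- value - mix$means[match]
    mix$means[match] <- mix$means[match] + a * d
    mix$vars[match] <- max(mix$vars[match] + a * (d^2 - mix$vars[match]),
                           cfg$var_floor)
  } else {
    worst <- ord[length(ord)]
    mix$means[worst] <- value
    mix$vars[worst] <- cfg$init_sigma^2
    mix$weights[worst] <- cfg$low_weight
  }
  mix$weights <- mix$weights / sum(mix$weights)
  ord2 <- order(mix$weights / sqrt(mix$vars), decreasing = TRUE)
  mix$weights <- mix$weights[ord2]
  mix$means <- mix$means[ord2]
  mix$vars <- mix$vars[ord2]
  mix
}

#' Background components of a pixel mixture
#'
#' The smallest prefix of components (in weight/sd order) whose cumulative
#' weight reaches the background fraction T.
#'
#' @param mix a [pixel_mixture()].
#' @return Integer indices of the background components.
#' @export
background_components <- function(mix) {
  cum <- cumsum(mix$weights)
  seq_len(min(which(cum >= mix$config$background_fraction)))
}

#' Gaussian-mixture background subtraction over a frame stack
#'
#' Runs the per-pixel mixture model over all frames (RGB channels modelled
#' independently; a pixel is foreground when any channel fails to match a
#' background component), then applies a morphological opening and closing to
#' each mask. Masks produced during the burn-in period are returned but
#' flagged, and downstream capture QC ignores them.
#'
#' @param frames a `frame_sequence` from [render_sequence()], or a list of
#'   `H x W x 3` arrays (0--255).
#' @param config a [bg_config()].
#' @param keep_background_removed also return the background-removed images
#'   (foreground pixels kept, background zeroed); off by default as it
#'   duplicates the frame stack in memory.
#' @return A list of class `subtraction_result`: `masks` (list of logical
#'   matrices), `burn_in` (number of initial frames to ignore), `config`,
#'   and optionally `bg_removed` (list of masked frames).
#' @export
subtract <- function(frames, config = bg_config(),
                     keep_background_removed = FALSE) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (length(frames) < 1) stop("empty frame stack")
  raw <- gmm_subtract_cpp(frames, config$K, config$alpha,
                          config$match_threshold, config$background_fraction,
                          config$init_sigma^2, config$var_floor,
                          config$low_weight)
  masks <- lapply(raw, clean_mask, size = config$morph_size)
  out <- structure(list(masks = masks,
                        burn_in = min(config$burn_in, length(masks)),
                        config = config),
                   class = "subtraction_result")
  if (keep_background_removed)
    out$bg_removed <- Map(apply_mask, frames, masks)
  out
}

# Morphological opening then closing with a size x size box element.
clean_mask <- function(mask, size = 3L) {
  if (size <= 1) return(mask)
  kern <- matrix(1L, size, size)
  m <- EBImage::closing(EBImage::opening(mask * 1, kern), kern)
  m > 0.5
}

#' Apply a foreground mask to a frame
#'
#' Returns the background-removed image: foreground pixels keep their values,
#' background pixels are zeroed.
#'
#' @param frame an `H x W x 3` array; @param mask logical `H x W` matrix.
#' @return The masked `H x W x 3` array.
#' @export
apply_mask <- function(frame, mask) {
  stopifnot(all(dim(frame)[1:2] == dim(mask)))
  frame * array(mask, dim = dim(frame))
}

#' Capture quality-control configuration
#'
#' @param s_min blob size (px) below which a spurious blob counts as
#'   removable noise.
#' @param f_bg fraction of frame pixels of residual (non-main-blob)
#'   foreground above which the background is judged not removed.
#' @param b_min minimum mean gradient magnitude over the main blob's boundary
#'   pixels for the target to count as sharp; below it the capture is
#'   `blurred`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(s_min = 20L, f_bg = 0.01, b_min = 10) {
  structure(list(s_min = as.integer(s_min), f_bg = f_bg, b_min = b_min),
            class = "qc_config")
}

#' The six capture QC categories
#' @export
qc_categories <- c("clean", "removable_noise", "nonremovable_noise",
                   "out_of_view", "background_not_removed", "blurred")

#' Rule-based QC categorization of a capture
#'
#' Assigns exactly one of the six categories used to audit acquisition
#' quality: `out_of_view` (no foreground, or the main blob touches the frame
#' border), `background_not_removed` (residual foreground beyond the main
#' blob exceeds `f_bg` of the frame), `blurred` (main blob boundary gradient
#' below `b_min`), `removable_noise` (all secondary blobs below `s_min` px),
#' `nonremovable_noise` (some secondary blob at or above `s_min`), else
#' `clean`.
#'
#' @param image `H x W x 3` array (0--255).
#' @param mask logical foreground mask of the same height/width.
#' @param config a [qc_config()].
#' @return A single character QC category.
#' @export
classify_capture <- function(image, mask, config = qc_config()) {
  if (!all(dim(image)[1:2] == dim(mask))) stop("image/mask size mismatch")
  if (!any(mask)) return("out_of_view")
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  main_mask <- lab == main
  h <- nrow(mask); w <- ncol(mask)
  if (any(main_mask[1, ]) || any(main_mask[h, ]) ||
      any(main_mask[, 1]) || any(main_mask[, w]))
    return("out_of_view")
  residual <- sum(sizes[-main])
  if (residual > config$f_bg * h * w) return("background_not_removed")
  if (boundary_gradient(image, main_mask) < config$b_min) return("blurred")
  if (length(sizes) > 1L) {
    if (all(sizes[-main] < config$s_min)) return("removable_noise")
    return("nonremovable_noise")
  }
  "clean"
}

# Mean gradient magnitude of the grayscale image over the internal boundary
# pixels of a blob; a sharpness statistic for the blurred-capture rule.
boundary_gradient <- function(image, blob) {
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  h <- nrow(gray); w <- ncol(gray)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  g <- sqrt(gx^2 + gy^2)
  eroded <- EBImage::erode(blob * 1, matrix(1L, 3L, 3L)) > 0.5
  boundary <- blob & !eroded
  if (!any(boundary)) boundary <- blob
  mean(g[boundary])
}

#' QC a whole subtraction result
#'
#' Applies [classify_capture()] to every post-burn-in frame.
#'
#' @param frames `frame_sequence` or list of frames matching `result`.
#' @param result a `subtraction_result` from [subtract()].
#' @param config a [qc_config()].
#' @return A data.frame with columns `frame` and `category`.
#' @export
qc_sequence <- function(frames, result, config = qc_config()) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  idx <- seq_along(frames)
  idx <- idx[idx > result$burn_in]
  cats <- vapply(idx, function(t)
    classify_capture(frames[[t]], result$masks[[t]], config), character(1))
  data.frame(frame = idx, category = cats, stringsAsFactors = FALSE)
}

#' Select clean captures for dataset assembly
#'
#' Deterministic, seeded selection of `keep_n` captures judged `clean`,
#' emulating the threshold-segmentation screening used to keep 300 of each
#' sample's 400 captures. If fewer than `keep_n` clean captures exist, all of
#' them are returned with a warning reporting the shortfall.
#'
#' @param captures list of capture records, each a list with elements
#'   `image`, `mask` and `qc` (a category from [classify_capture()]).
#' @param keep_n number to keep.
#' @param seed integer seed for the selection.
#' @return The selected sublist of `captures`.
#' @export
select_clean <- function(captures, keep_n, seed = 1L) {
  stopifnot(keep_n >= 0)
  qc <- vapply(captures, function(x) x$qc, character(1))
  clean_idx <- which(qc == "clean")
  if (keep_n == 0) return(captures[integer(0)])
  if (length(clean_idx) < keep_n) {
    warning(sprintf("only %d clean captures available (requested %d)",
                    length(clean_idx), keep_n))
    return(captures[clean_idx])
  }
  sel <- withr::with_seed(as.integer(seed),
                          sort(sample(clean_idx, keep_n)))
  captures[sel]
}
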