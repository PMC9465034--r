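#' Canonical names of the 30-feature descriptor
#'
#' Nine colour features (mean, standard deviation, skewness per RGB channel
#' over the body pixels), sixteen texture features (contrast, correlation,
#' energy, homogeneity of the gray co-occurrence matrix at 0, 45, 90 and 135
#' degrees), and five shape features (area, perimeter, circularity,
#' eccentricity, extent of the body mask). The order is fixed; feature tables
#' and selection results always use it.
#'
#' @return Character vector of length 30.
#' @export
feature_names <- function() {
  color <- as.vector(outer(c("mean", "sd", "skew"), c("r", "g", "b"),
                           function(s, ch) paste(ch, s, sep = "_")))
  texture <- as.vector(outer(c("contrast", "correlation", "energy", "homogeneity"),
                             c(0, 45, 90, 135),
                             function(s, a) sprintf("glcm_%s_a%d", s, a)))
  c(color, texture, c("area", "perimeter", "circularity", "eccentricity", "extent"))
}

quantize_gray <- function(gray, levels) {
  q <- floor(gray * levels / 256) + 1L
  pmin(pmax(q, 1L), levels)
}

glcm_offsets <- function(distance) {
  list(`0` = c(0L, distance), `45` = c(-distance, distance),
       `90` = c(-distance, 0L), `135` = c(-distance, -distance))
}

#' Gray-level co-occurrence matrix at one angle
#'
#' Symmetric, normalized co-occurrence matrix of the quantized gray image:
#' each in-mask pixel pair at the given offset is counted in both directions
#' and the matrix is divided by the total pair count, so all entries sum to 1.
#'
#' @param gray matrix of intensities 0--255.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param mask optional logical matrix; only pairs with both pixels in the
#'   mask are counted.
#' @param levels number of gray levels after quantization.
#' @param distance pair offset, px.
#' @return A `levels x levels` matrix summing to 1 (all zeros if no pair
#'   exists).
#' @export
glcm_matrix <- function(gray, angle, mask = NULL, levels = 16L, distance = 1L) {
  stopifnot(angle %in% c(0, 45, 90, 135))
  if (min(dim(gray)) <= distance) stop("ROI smaller than the GLCM distance")
  q <- quantize_gray(gray, levels)
  off <- glcm_offsets(as.integer(distance))[[as.character(angle)]]
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- rep(TRUE, length(a))
  if (!is.null(mask))
    keep <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(0, levels, levels)
  if (any(keep)) {
    tab <- table(factor(a[keep], levels = seq_len(levels)),
                 factor(b[keep], levels = seq_len(levels)))
    counts <- unclass(tab) + t(unclass(tab))  # symmetric
    counts <- counts / sum(counts)
    dimnames(counts) <- NULL
  }
  counts
}

glcm_summaries <- function(P) {
  levels <- nrow(P)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (s_i > 0 && s_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j) else 1
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' GLCM texture statistics at four angles
#'
#' Contrast, correlation, energy and homogeneity of the symmetric normalized
#' co-occurrence matrix at 0, 45, 90 and 135 degrees (16 values). A uniform
#' region has contrast 0 and energy 1 at every angle; correlation of a
#' degenerate (single-level) matrix is defined as 1.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 16, angle-major, in the order of
#'   [feature_names()].
#' @export
glcm_stats <- function(gray, mask = NULL, levels = 16L, distance = 1L) {
  out <- unlist(lapply(c(0, 45, 90, 135), function(a)
    glcm_summaries(glcm_matrix(gray, a, mask, levels, distance))))
  names(out) <- feature_names()[10:25]
  out
}

# Crofton-style perimeter: count foreground/background 4-neighbour edges
# (frame border counts as background), correct the staircase bias by pi/4,
# then subtract pi because the pixel-square boundary circumscribes the
# underlying smooth contour by half a pixel (total turning 2*pi times 1/2).
# Unbiased for smooth convex bodies such as a disk.
mask_perimeter <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  edges <- sum(abs(pad[-1, ] - pad[-nrow(pad), ])) +
    sum(abs(pad[, -1] - pad[, -ncol(pad)]))
  max(edges * pi / 4 - pi, 0)
}

mask_eccentricity <- function(mask) {
  ys <- row(mask)[mask]; xs <- col(mask)[mask]
  if (length(ys) < 2) return(0)
  cv <- stats::cov(cbind(xs, ys))
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

skewness <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Extract the 30-feature descriptor of a masked ROI
#'
#' Colour statistics are computed on the masked pixels, texture on the
#' masked grayscale ROI, and shape on the mask alone, so the descriptor is
#' invariant to where the body sits in the frame.
#'
#' @param roi `H x W x 3` array (0--255).
#' @param mask logical body mask (>= 1 pixel).
#' @param levels,distance GLCM quantization and offset.
#' @return Named numeric vector of length 30 in [feature_names()] order.
#' @export
extract_features <- function(roi, mask, levels = 16L, distance = 1L) {
  if (!any(mask)) stop("empty mask")
  stopifnot(all(dim(roi)[1:2] == dim(mask)))
  color <- unlist(lapply(1:3, function(ch) {
    v <- roi[, , ch][mask]
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0, skewness(v))
  }))
  gray <- (roi[, , 1] + roi[, , 2] + roi[, , 3]) / 3
  texture <- glcm_stats(gray, mask, levels, distance)
  area <- sum(mask)
  perim <- mask_perimeter(mask)
  circ <- if (perim > 0) 4 * pi * area / perim^2 else 0
  ecc <- mask_eccentricity(mask)
  ys <- range(row(mask)[mask]); xs <- range(col(mask)[mask])
  extent <- area / ((diff(ys) + 1) * (diff(xs) + 1))
  out <- c(color, texture, area, perim, circ, ecc, extent)
  names(out) <- feature_names()
  out
}

#' Feature table for a labelled dataset
#'
#' Extracts the 30-feature descriptor for every image; the body mask is
#' recovered by thresholding against the known plain background when no
#' masks are supplied.
#'
#' @param ds an [insect_dataset].
#' @param masks optional list of logical masks; when NULL, a simple
#'   background-difference threshold segments the body.
#' @param threshold absolute difference from the background gray used for
#'   segmentation.
#' @return A data.frame: 30 feature columns plus a `label` column.
#' @export
dataset_features <- function(ds, masks = NULL, threshold = 25) {
  feats <- matrix(NA_real_, length(ds$images), 30L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_along(ds$images)) {
    img <- ds$images[[i]]
    m <- if (!is.null(masks)) masks[[i]] else segment_body(img, threshold)
    if (!any(m)) m <- matrix(TRUE, nrow(img), ncol(img))  # degenerate fallback
    feats[i, ] <- extract_features(img, m)
  }
  out <- as.data.frame(feats)
  out$label <- ds$labels
  out
}

# Threshold segmentation of a body on a near-uniform background: keep pixels
# whose gray value departs from the median background by more than the
# threshold, then take the largest connected component.
segment_body <- function(img, threshold = 25) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  bg <- stats::median(gray)
  m <- abs(gray - bg) > threshold
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' GBDT feature selection by mean-importance thresholding
#'
#' Fits a gradient-boosted CART ensemble (log-loss objective) on the feature
#' matrix, reads gain-based importances, and keeps every feature whose
#' importance reaches the mean importance over all features. Features the
#' ensemble never used have importance 0; if no feature was used at all the
#' selection is empty.
#'
#' @param X numeric matrix (samples x features, named columns).
#' @param y integer class labels (0-based, >= 2 classes).
#' @param n_rounds,max_depth,eta GBDT size, tree depth, learning rate.
#' @param seed integer seed.
#' @return A list of class `selection_result`: `importances` (named, all
#'   features), `threshold` (mean importance), `selected` (indices in
#'   original column order), `selected_names`.
#' @export
select_features <- function(X, y, n_rounds = 200L, max_depth = 3L, eta = 0.1,
                            seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (nrow(X) < 10 * length(classes))
    stop("need at least 10 samples per class overall")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(factor(y, levels = classes)) - 1L
  params <- if (length(classes) == 2)
    list(objective = "binary:logistic", eval_metric = "logloss")
  else
    list(objective = "multi:softprob", num_class = length(classes),
         eval_metric = "mlogloss")
  params$max_depth <- max_depth
  params$eta <- eta
  params$nthread <- 1
  bst <- withr::with_seed(as.integer(seed),
    xgboost::xgb.train(params,
                       xgboost::xgb.DMatrix(X, label = y),
                       nrounds = n_rounds, verbose = 0))
  imp_tab <- xgboost::xgb.importance(model = bst)
  importances <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (nrow(imp_tab) > 0)
    importances[imp_tab$Feature] <- imp_tab$Gain
  threshold <- mean(importances)
  selected <- if (sum(importances) == 0) integer(0)
  else which(importances >= threshold)
  structure(list(importances = importances, threshold = threshold,
                 selected = as.integer(selected),
                 selected_names = colnames(X)[selected]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features at threshold %.4g\n",
              length(x$selected), length(x$importances), x$threshold))
  if (length(x$selected))
    cat(" ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}
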