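# Independent reference implementations used as oracles.

# Brute-force symmetric GLCM by direct enumeration of all pixel pairs.
glcm_bruteforce <- function(gray, angle, mask = NULL, levels = 16L,
                            distance = 1L) {
  q <- floor(gray * levels / 256) + 1L
  q[q < 1L] <- 1L
  q[q > levels] <- levels
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > h || j2 < 1 || j2 > w) next
      if (!is.null(mask) && (!mask[i, j] || !mask[i2, j2])) next
      counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      counts[q[i2, j2], q[i, j]] <- counts[q[i2, j2], q[i, j]] + 1
    }
  if (sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# Brute-force per-pixel re-implementation of the adaptive-mixture
# update/match recursion (per channel; foreground when any channel fails to
# match a background component). Mirrors the published recursion directly.
gmm_bruteforce <- function(frames, K = 5, alpha = 0.01, match_sigma = 2.5,
                           bg_fraction = 0.7, init_var = 900, var_floor = 4,
                           low_weight = 0.05) {
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  masks <- vector("list", length(frames))
  for (t in seq_along(frames)) masks[[t]] <- matrix(FALSE, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w))
      for (ch in 1:3) {
        wv <- c(1, rep(0, K - 1))
        mu <- c(frames[[1]][i, j, ch], rep(0, K - 1))
        va <- rep(init_var, K)
        for (t in seq_along(frames)) {
          v <- frames[[t]][i, j, ch]
          ord <- order(wv / sqrt(va), decreasing = TRUE)
          n_bg <- min(which(cumsum(wv[ord]) >= bg_fraction))
          match_pos <- NA
          for (k in seq_len(K)) {
            kk <- ord[k]
            if (wv[kk] <= 0) next
            if (abs(v - mu[kk]) <= match_sigma * sqrt(va[kk])) {
              match_pos <- k
              break
            }
          }
          if (is.na(match_pos) || match_pos > n_bg)
            masks[[t]][i, j] <- TRUE
          if (alpha > 0) {
            if (!is.na(match_pos)) {
              kk <- ord[match_pos]
              wv <- (1 - alpha) * wv
              wv[kk] <- wv[kk] + alpha
              d <- v - mu[kk]
              mu[kk] <- mu[kk] + alpha * d
              va[kk] <- max(va[kk] + alpha * (d^2 - va[kk]), var_floor)
            } else {
              kk <- ord[K]
              mu[kk] <- v
              va[kk] <- init_var
              wv[kk] <- low_weight
            }
            wv <- wv / sum(wv)
          }
        }
      }
  masks
}

# Hand-written outbreak grading lookup straight from the published table,
# right-closed bands, level-5 rate band read as "above 500%".
grade_lookup <- function(density, rate) {
  d_level <- if (density <= 5) 1 else if (density <= 10) 2 else
    if (density <= 20) 3 else if (density <= 30) 4 else 5
  r_level <- if (rate <= 0) 1 else if (rate <= 100) 2 else
    if (rate <= 300) 3 else if (rate <= 500) 4 else 5
  max(d_level, r_level)
}

# Tiny labelled dataset with given per-class sizes; image content is an
# arbitrary constant since only bookkeeping is exercised.
dummy_dataset <- function(sizes, provenance = "dummy",
                          class_names = paste0("c", seq_along(sizes) - 1)) {
  labels <- rep(seq_along(sizes) - 1L, sizes)
  images <- replicate(sum(sizes), array(1, c(2, 2, 3)), simplify = FALSE)
  insect_dataset(images, labels, class_names, provenance = provenance)
}

# A small, well-separated 3-class image set used by classifier tests.
small_image_set <- function(n_per_class = 30, image_size = 32, seed = 1) {
  ds <- make_insect_dataset(default_class_specs(), n_per_class, image_size,
                            seed = seed, provenance = "small")
  split_dataset(ds, c(7, 1.5, 1.5), seed = seed)
}
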