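test_that("a constant stream drives the dominant component to the value", {
  mix <- pixel_mixture(120, bg_config())
  for (i in 1:500) mix <- update_pixel(mix, 120)
  expect_equal(mix$means[1], 120)
  expect_gt(mix$weights[1], 0.99)
  expect_equal(sum(mix$weights), 1)
})

test_that("a zero learning rate leaves the mixture untouched", {
  mix <- pixel_mixture(50, bg_config(alpha = 0))
  expect_identical(update_pixel(mix, 200), mix)
})

test_that("an alternating stream builds two components bracketing the values", {
  mix <- pixel_mixture(50, bg_config())
  for (i in 1:400) mix <- update_pixel(mix, if (i %% 2) 50 else 200)
  top2 <- sort(mix$means[1:2])
  expect_lt(abs(top2[1] - 50), 10)
  expect_lt(abs(top2[2] - 200), 10)
  expect_equal(sum(mix$weights), 1)
  expect_true(all(mix$vars >= mix$config$var_floor))
})

test_that("fast subtraction equals the brute-force recursion on a toy stack", {
  set.seed(42)
  frames <- lapply(1:20, function(t) {
    base <- array(rep(c(60, 120, 180), each = 3), c(3, 3, 3))
    base + array(rnorm(27, 0, 5), c(3, 3, 3)) +
      (if (t > 10) array(c(rep(0, 4), 150, rep(0, 22)), c(3, 3, 3)) else 0)
  })
  fast <- subtract(frames, bg_config(morph_size = 0L, burn_in = 0L))
  slow <- gmm_bruteforce(frames)
  for (t in 1:20) expect_identical(fast$masks[[t]], slow[[t]], label = paste("frame", t))
})

test_that("a static scene yields all-background masks after burn-in", {
  sp <- scene_spec(frame_size = c(30, 30), background_noise_sigma = 5,
                   clutter_rate = 0, trajectory = NULL)
  sq <- render_sequence(sp, 60, seed = 5)
  res <- subtract(sq, bg_config(burn_in = 30))
  for (t in 31:60) expect_false(any(res$masks[[t]]))
})

test_that("masks recover the moving object with IoU >= 0.7", {
  n <- 80
  traj <- parabolic_trajectory(n, c(100, 100))
  sp <- scene_spec(frame_size = c(100, 100), trajectory = traj)
  sq <- render_sequence(sp, n, seed = 6)
  res <- subtract(sq, bg_config(burn_in = 30))
  iou <- c()
  for (t in 31:n) {
    tm <- sq$truth_masks[[t]]
    if (!any(tm)) next
    if (any(tm[1, ]) || any(tm[100, ]) || any(tm[, 1]) || any(tm[, 100])) next
    pm <- res$masks[[t]]
    iou <- c(iou, sum(tm & pm) / sum(tm | pm))
  }
  expect_gt(length(iou), 10)
  expect_gte(median(iou), 0.7)
})

test_that("capture QC assigns the six categories by rule", {
  img <- array(160, c(100, 100, 3))
  body <- pestwatch:::ellipse_mask(100, 100, 50, 50, 12, 7)
  for (ch in 1:3) img[, , ch][body] <- 60
  # empty mask
  expect_equal(classify_capture(img, matrix(FALSE, 100, 100)), "out_of_view")
  # single compact in-view blob
  expect_equal(classify_capture(img, body), "clean")
  # blob touching the border
  edge <- pestwatch:::ellipse_mask(100, 100, 3, 50, 8, 6)
  img2 <- array(160, c(100, 100, 3))
  for (ch in 1:3) img2[, , ch][edge] <- 60
  expect_equal(classify_capture(img2, edge), "out_of_view")
  # blob plus a 6-px transient speck -> removable
  speck <- body
  speck[80:81, 80:82] <- TRUE
  expect_equal(classify_capture(img, speck), "removable_noise")
  # blob plus a large secondary blob -> nonremovable (below the f_bg residual cut)
  second <- body
  second[75:82, 70:77] <- TRUE  # 64 px
  expect_equal(classify_capture(img, second), "nonremovable_noise")
  # massive residual foreground -> background not removed
  resid <- body
  resid[70:95, 5:60] <- TRUE
  expect_equal(classify_capture(img, resid), "background_not_removed")
  # blurred body edge: low boundary gradient
  blurimg <- array(160, c(100, 100, 3))
  alpha <- pestwatch:::gaussian_blur(body * 1, 6)
  for (ch in 1:3) blurimg[, , ch] <- blurimg[, , ch] * (1 - alpha) + 60 * alpha
  expect_equal(classify_capture(blurimg, body), "blurred")
  expect_error(classify_capture(img, matrix(FALSE, 10, 10)), "mismatch")
})

test_that("QC on a rendered sequence judges object frames clean", {
  n <- 70
  traj <- parabolic_trajectory(n, c(100, 100))
  sp <- scene_spec(frame_size = c(100, 100), trajectory = traj,
                   clutter_rate = 0)
  sq <- render_sequence(sp, n, seed = 9)
  res <- subtract(sq, bg_config(burn_in = 25))
  qc <- qc_sequence(sq, res)
  inview <- vapply(qc$frame, function(t) {
    tm <- sq$truth_masks[[t]]
    any(tm) && !(any(tm[1, ]) || any(tm[100, ]) || any(tm[, 1]) ||
                   any(tm[, 100]))
  }, logical(1))
  expect_true(all(qc$category[inview] %in% c("clean", "removable_noise")))
})

test_that("select_clean keeps the requested count, deterministically", {
  caps <- lapply(1:40, function(i)
    list(image = NULL, mask = NULL,
         qc = if (i %% 4 == 0) "removable_noise" else "clean"))
  sel <- select_clean(caps, 20, seed = 1)
  expect_length(sel, 20)
  expect_true(all(vapply(sel, function(x) x$qc, character(1)) == "clean"))
  expect_identical(select_clean(caps, 20, seed = 1), sel)
  expect_length(select_clean(caps, 0), 0)
  all_clean <- lapply(1:5, function(i) list(qc = "clean"))
  expect_identical(select_clean(all_clean, 5), all_clean)
  expect_warning(short <- select_clean(caps, 35), "30 clean")
  expect_length(short, 30)
})

test_that("more background noise never increases the clean fraction", {
  clean_frac <- function(sigma) {
    n <- 60
    traj <- parabolic_trajectory(n, c(80, 80))
    sp <- scene_spec(frame_size = c(80, 80), trajectory = traj,
                     background_noise_sigma = sigma, clutter_rate = 0)
    sq <- render_sequence(sp, n, seed = 21)
    res <- subtract(sq, bg_config(burn_in = 25))
    qc <- qc_sequence(sq, res)
    mean(qc$category == "clean")
  }
  fr <- vapply(c(4, 12, 30), clean_frac, numeric(1))
  expect_true(all(diff(fr) <= 1e-9))
})
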