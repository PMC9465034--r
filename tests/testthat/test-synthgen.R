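test_that("zero-noise background-only scenes render constant frames", {
  sp <- scene_spec(frame_size = c(20, 24), background_noise_sigma = 0,
                   clutter_rate = 0, trajectory = NULL)
  sq <- render_sequence(sp, 5, seed = 1)
  expect_length(sq$frames, 5)
  for (f in sq$frames) expect_true(all(f == sp$background_mean))
  for (m in sq$truth_masks) expect_false(any(m))
})

test_that("rendering is deterministic under a fixed seed", {
  traj <- parabolic_trajectory(10, c(40, 40))
  sp <- scene_spec(frame_size = c(40, 40), trajectory = traj)
  a <- render_sequence(sp, 10, seed = 7)
  b <- render_sequence(sp, 10, seed = 7)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth_masks, b$truth_masks)
  c <- render_sequence(sp, 10, seed = 8)
  expect_false(identical(a$frames, c$frames))
})

test_that("background noise level matches the requested sigma", {
  sp <- scene_spec(frame_size = c(40, 40), background_noise_sigma = 8,
                   clutter_rate = 0)
  sq <- render_sequence(sp, 200, seed = 2)
  v <- vapply(sq$frames, function(f) as.vector(f[, , 1]),
              numeric(40 * 40))
  sds <- apply(v, 1, sd)
  expect_lt(abs(median(sds) - 8) / 8, 0.1)
})

test_that("the object appears at the trajectory position and masks are exact", {
  traj <- cbind(c(10, 20), c(15, 25))
  sp <- scene_spec(frame_size = c(40, 40), background_noise_sigma = 0,
                   clutter_rate = 0, blur_sigma = 0, trajectory = traj,
                   object_axes = c(4, 3))
  sq <- render_sequence(sp, 2, seed = 1)
  expect_true(sq$truth_masks[[1]][10, 15])
  expect_true(sq$truth_masks[[2]][20, 25])
  expect_false(sq$truth_masks[[1]][20, 25])
  # unblurred body pixels take the object intensity exactly
  expect_true(all(sq$frames[[1]][, , 1][sq$truth_masks[[1]]] ==
                    sp$object_intensity))
})

test_that("a trajectory shorter than the frame count is rejected", {
  sp <- scene_spec(trajectory = cbind(1:3, 1:3))
  expect_error(render_sequence(sp, 5), "fewer rows")
})

test_that("insect dataset bookkeeping: counts, labels, determinism", {
  ds <- make_insect_dataset(default_class_specs(), 5, 32, seed = 3)
  expect_length(ds$images, 15)
  expect_equal(as.vector(table(ds$labels)), c(5, 5, 5))
  ds2 <- make_insect_dataset(default_class_specs(), 5, 32, seed = 3)
  expect_identical(ds$images, ds2$images)
  # per-class counts may differ
  ds3 <- make_insect_dataset(default_class_specs(include_noise = TRUE),
                             c(4, 3, 4, 6), 32, seed = 1)
  expect_equal(as.vector(table(ds3$labels)), c(4, 3, 4, 6))
  expect_error(make_insect_dataset(list(class_spec("a", c(1, 2, 3)),
                                        class_spec("a", c(4, 5, 6))), 3),
               "duplicate")
})

test_that("default classes separate by mean colour alone", {
  ds <- make_insect_dataset(default_class_specs(), 40, 32, seed = 11)
  rgb <- t(vapply(ds$images, function(im)
    c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3])), numeric(3)))
  cent <- vapply(0:2, function(c) colMeans(rgb[ds$labels == c, , drop = FALSE]),
                 numeric(3))
  pred <- apply(rgb, 1, function(v) which.min(colSums((cent - v)^2)) - 1)
  expect_gt(mean(pred == ds$labels), 0.9)
})

test_that("count series: constant, doubling, and rejection of bad specs", {
  cs <- make_count_series(count_series_spec(14, base_count = 10,
                                            daily_growth = 1, noise = 0))
  expect_equal(cs$count, rep(10L, 14))
  cs2 <- make_count_series(count_series_spec(8, 10, 2.0, noise = 0))
  expect_equal(cs2$count[2] / cs2$count[1], 2)
  expect_equal(cs2$count, as.integer(round(10 * 2^(0:7))))
  expect_error(count_series_spec(5, base_count = -1), "base_count")
})

test_that("Poisson count noise is centred on the deterministic series", {
  spec0 <- count_series_spec(6, base_count = 20, daily_growth = 1.2, noise = 0)
  det <- make_count_series(spec0)$count
  sims <- vapply(seq_len(1000), function(r)
    make_count_series(count_series_spec(6, 20, 1.2, noise = 1,
                                        seed = r))$count,
    numeric(6))
  expect_lt(max(abs(rowMeans(sims) - det) / det), 0.05)
})

test_that("sequence and count-series round-trip through disk formats", {
  sp <- scene_spec(frame_size = c(16, 16), clutter_rate = 0,
                   trajectory = cbind(c(8, 9), c(8, 9)))
  sq <- render_sequence(sp, 2, seed = 1)
  d <- tempfile()
  write_sequence(sq, d)
  expect_true(file.exists(file.path(d, "frame_0001.png")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- png::readPNG(file.path(d, "frame_0002.png")) * 255
  expect_equal(dim(back), c(16, 16, 3))
  f <- tempfile(fileext = ".csv")
  cs <- make_count_series(count_series_spec(5, 3, 1.5))
  write_count_series(cs, f)
  expect_equal(read_count_series(f), cs)
})
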