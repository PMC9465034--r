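test_that("ROI cropping centres the window on the mask centroid", {
  img <- array(runif(400 * 400 * 3, 0, 255), c(400, 400, 3))
  mask <- matrix(FALSE, 400, 400)
  mask[180:220, 190:230] <- TRUE
  roi <- crop_roi(img, mask)
  expect_equal(dim(roi), c(140, 140, 3))
  # centroid of the blob lands on pixel (70, 70) of the crop
  expect_equal(roi[70, 70, ], img[200, 210, ])
  # uniform image stays uniform
  u <- crop_roi(array(5, c(400, 400, 3)), mask)
  expect_true(all(u == 5))
  expect_error(crop_roi(img, matrix(FALSE, 400, 400)), "empty mask")
})

test_that("cropping near a border expands by edge replication", {
  img <- array(0, c(200, 200, 3))
  img[1, 1, ] <- 99
  mask <- matrix(FALSE, 200, 200)
  mask[4:7, 4:7] <- TRUE
  roi <- crop_roi(img, mask)
  expect_equal(dim(roi), c(140, 140, 3))
  # rows above the frame are replicated from row 1
  expect_equal(roi[1, 1, ], c(99, 99, 99))
})

test_that("augmentation: identity, involution, determinism", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ident <- list(rot = 0, shear = 0, flip_h = FALSE, flip_v = FALSE)
  expect_identical(augment(img, transforms = ident), img)
  r180 <- list(rot = 2, shear = 0, flip_h = FALSE, flip_v = FALSE)
  expect_equal(augment(augment(img, transforms = r180), transforms = r180), img)
  expect_identical(augment(img, seed = 5), augment(img, seed = 5))
  expect_false(identical(augment(img, seed = 5), augment(img, seed = 6)))
  expect_equal(dim(augment(img, seed = 1)), dim(img))
})

test_that("stratified splits reproduce the published dataset arithmetic", {
  ds1 <- dummy_dataset(c(3000, 3000, 3000))
  sp <- split_dataset(ds1, c(7, 1.5, 1.5), seed = 1)
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(6300, 1350, 1350))
  ds2 <- dummy_dataset(c(80, 60, 80, 1200))
  sp2 <- split_dataset(ds2, c(6, 2, 2), seed = 1)
  expect_equal(as.vector(table(sp2$split)[c("train", "val", "test")]),
               c(852, 284, 284))
  # per-class proportions within one image of exact
  for (c in 0:3) {
    n_c <- sum(sp2$labels == c)
    tr_c <- sum(sp2$labels == c & sp2$split == "train")
    expect_lte(abs(tr_c - 0.6 * n_c), 1)
  }
  all_train <- split_dataset(dummy_dataset(c(5, 5)), c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  expect_error(split_dataset(dummy_dataset(c(2, 5)), c(7, 1.5, 1.5)),
               "fewer than 3")
})

test_that("splits are disjoint, exhaustive and label-preserving", {
  ds <- dummy_dataset(c(40, 25, 33))
  sp <- split_dataset(ds, c(6, 2, 2), seed = 9)
  expect_false(any(is.na(sp$split)))
  expect_identical(sp$labels, ds$labels)
  parts <- lapply(c("train", "val", "test"), function(w) dataset_split(sp, w))
  ids <- unlist(lapply(parts, function(p) p$ids))
  expect_equal(sort(ids), sort(ds$ids))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("the fourth category is downsampled to exactly n_fourth", {
  ds2 <- dummy_dataset(c(80, 60, 80, 1200))
  d21 <- build_dataset2_1(ds2, n_fourth = 70, seed = 2)
  expect_equal(as.vector(table(d21$labels)), c(80, 60, 80, 70))
  expect_length(d21$images, 290)
  expect_equal(d21$provenance, "dataset2_1")
  # identity when n_fourth equals the class size
  small <- dummy_dataset(c(4, 4, 4, 10))
  expect_length(build_dataset2_1(small, 10)$images, 22)
  # same sizes, different membership across seeds
  a <- build_dataset2_1(ds2, 70, seed = 1)
  b <- build_dataset2_1(ds2, 70, seed = 2)
  expect_equal(table(a$labels), table(b$labels))
  expect_false(identical(a$ids, b$ids))
  expect_error(build_dataset2_1(dummy_dataset(c(5, 5, 5, 30)), 70), "fewer")
  expect_error(build_dataset2_1(dummy_dataset(c(5, 5, 5)), 3), "4 classes")
})

test_that("filling mix pads the target classes up to the fourth class size", {
  ds1 <- dummy_dataset(c(800, 800, 800), provenance = "lab")
  ds1$split <- rep("train", length(ds1$images))
  ds2 <- dummy_dataset(c(48, 36, 48, 720), provenance = "field")
  ds2$split <- rep("train", length(ds2$images))
  fm <- filling_mix(ds1, ds2, seed = 1)
  expect_equal(as.vector(table(fm$labels)), rep(720L, 4))
  expect_equal(fm$provenance, "filled_mix")
  expect_false(anyDuplicated(fm$ids) > 0)
  # no-op when classes already match the fourth
  eq <- dummy_dataset(c(10, 10, 10, 10), provenance = "eq")
  expect_equal(as.vector(table(filling_mix(ds1, eq)$labels)), rep(10L, 4))
  # degenerate and under-resourced inputs are rejected
  expect_error(filling_mix(ds1, dummy_dataset(c(5, 5, 5, 0))), "degenerate")
  expect_error(filling_mix(dummy_dataset(c(10, 10, 10)),
                           dummy_dataset(c(2, 2, 2, 500))), "lacks")
})

test_that("symmetric mix doubles every class with disjoint identities", {
  ds1 <- dummy_dataset(c(200, 200, 200), provenance = "lab")
  d21 <- dummy_dataset(c(48, 36, 48, 42), provenance = "field")
  pool <- dummy_dataset(c(0, 0, 0, 100), provenance = "pool")
  sm <- symmetric_mix(ds1, d21, pool, seed = 3)
  expect_equal(as.vector(table(sm$labels)), c(96L, 72L, 96L, 84L))
  expect_equal(sm$provenance, "symmetric_mix")
  expect_false(anyDuplicated(sm$ids) > 0)
  # class balance is exactly doubled
  expect_equal(as.vector(table(sm$labels)),
               2L * as.vector(table(d21$labels)))
  expect_error(symmetric_mix(dummy_dataset(c(0, 10, 10)), d21, pool), "lacks")
  expect_error(symmetric_mix(ds1, d21, dummy_dataset(c(0, 0, 0, 10))),
               "pool has")
  overlap <- d21
  expect_error(symmetric_mix(ds1, d21, overlap), "overlaps")
})
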