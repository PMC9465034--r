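test_that("only depths of the 2Sn+2 family build, with helpful rejection", {
  m <- build_resnet_v2(seed = 1)
  expect_equal(count_weighted_layers(m), 56L)
  expect_equal(length(m$arch$widths) * m$arch$units_per_stage, 27L)
  err <- tryCatch(build_resnet_v2(depth = 57), error = conditionMessage)
  expect_match(err, "56")
  expect_match(err, "62")
  small <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 2,
                           input_size = 16L)
  expect_equal(count_weighted_layers(small), 8L)
})

test_that("the skip path carries the additive identity of the recursion", {
  m <- build_resnet_v2(depth = 6L, widths = 4L, n_classes = 2L,
                       input_size = 8L, seed = 3)
  set.seed(4)
  imgs <- lapply(1:3, function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  tr <- resnet_unit_trace(m, imgs)
  x1 <- tr$unit_inputs[[1]]
  x2 <- tr$unit_inputs[[2]]
  F1 <- tr$branch_outputs[[1]]
  F2 <- tr$branch_outputs[[2]]
  # x_{l+1} = x_l + F_l, and the deep activation is the shallow one plus
  # the summed branch outputs
  expect_lt(max(abs(x2 - (x1 + F1))), 1e-5)
  expect_lt(max(abs(tr$final_preact - (x1 + F1 + F2))), 1e-5)
})

test_that("zeroed residual branches reduce the network to its skip path", {
  m <- build_resnet_v2(depth = 6L, widths = 4L, n_classes = 2L,
                       input_size = 8L, seed = 5)
  for (nm in grep("conv2", names(m$params), value = TRUE))
    m$params[[nm]][] <- 0
  set.seed(6)
  imgs <- lapply(1:2, function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  tr <- resnet_unit_trace(m, imgs)
  # with every F = 0 the final pre-activation equals the first unit's input
  expect_lt(max(abs(tr$final_preact - tr$unit_inputs[[1]])), 1e-5)
  for (b in tr$branch_outputs) expect_true(all(b == 0))
})

test_that("analytic gradients match finite differences at salient entries", {
  m <- build_resnet_v2(depth = 6L, widths = 4L, n_classes = 2L,
                       input_size = 8L, seed = 3)
  set.seed(4)
  imgs <- lapply(1:4, function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  y <- c(0L, 1L, 0L, 1L)
  lg <- resnet_loss_grad(m, imgs, y)
  expect_true(is.finite(lg$loss))
  for (pn in c("stem_w", "s1u1_conv1", "s1u2_conv2", "fc_w", "bnf_g")) {
    g <- lg$grads[[pn]]
    i <- which.max(abs(g))
    h <- 5e-3
    bump <- function(delta) {
      mm <- m
      mm$params[[pn]][i] <- mm$params[[pn]][i] + delta
      resnet_loss_grad(mm, imgs, y)$loss
    }
    num <- (bump(h) - bump(-h)) / (2 * h)
    expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i])), 0.05,
              label = paste("gradient of", pn))
  }
})

test_that("softmax cross-entropy matches a hand-computed 3-logit value", {
  # craft weights so the logits are exactly (1, 2, 3): zero first layer
  # (sigmoid -> 0.5 everywhere), zero second-layer weights, biases (1, 2, 3)
  w <- list(W1 = matrix(0, 2, 1), b1 = c(0, 0),
            W2 = matrix(0, 3, 2), b2 = c(1, 2, 3))
  hand <- -log(exp(3) / sum(exp(1:3)))
  expect_equal(bpnn_loss(w, matrix(1, 1, 1), 2L), hand)
  hand2 <- -mean(log(c(exp(1), exp(3)) / sum(exp(1:3))))
  expect_equal(bpnn_loss(w, matrix(1, 2, 1), c(0L, 2L)), hand2)
})

test_that("a smoke-scale training run keeps tidy books", {
  ds <- small_image_set(10, 32, seed = 2)
  m <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 3,
                       input_size = 32L, seed = 1)
  fit <- train_resnet(m, ds, train_config(epochs = 3L, patience = Inf),
                      seed = 1)
  expect_lte(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$val_error >= 0 & fit$history$val_error <= 1))
  expect_gte(fit$best_epoch, 1)
  p <- predict(fit, dataset_split(ds, "test"))
  expect_length(p$labels, length(dataset_split(ds, "test")))
  expect_equal(rowSums(p$probs), rep(1, nrow(p$probs)), tolerance = 1e-5)
})

test_that("training is reproducible under a fixed seed", {
  ds <- small_image_set(8, 32, seed = 3)
  run <- function() {
    m <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 3,
                         input_size = 32L, seed = 2)
    train_resnet(m, ds, train_config(epochs = 2L), seed = 11)$history
  }
  expect_equal(run(), run(), tolerance = 1e-6)
})

test_that("empty splits and oversized label sets are rejected", {
  ds <- small_image_set(8, 32, seed = 3)
  ds$split[ds$split == "val"] <- "train"
  m <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 3,
                       input_size = 32L)
  expect_error(train_resnet(m, ds), "non-empty")
  ds2 <- small_image_set(8, 32, seed = 3)
  m2 <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 2,
                        input_size = 32L)
  expect_error(train_resnet(m2, ds2), "more classes")
})

test_that("transfer updates copy the trunk bitwise and rebuild the head", {
  base <- build_resnet_v2(depth = 8L, widths = 8L, n_classes = 3,
                          input_size = 32L, seed = 4)
  up <- transfer_update(base, 4, seed = 5)
  conv_names <- grep("conv|bn|stem", names(base$params), value = TRUE)
  conv_names <- setdiff(conv_names, c("fc_w", "fc_b"))
  for (nm in conv_names)
    expect_identical(up$params[[nm]], base$params[[nm]])
  expect_identical(up$bn_state, base$bn_state)
  expect_equal(dim(up$params$fc_w), c(4L, 8L))
  expect_equal(up$arch$n_classes, 4L)
  # with no further training, predictions use base trunk + fresh head
  imgs <- lapply(1:2, function(i) array(runif(32 * 32 * 3, 0, 255),
                                        c(32, 32, 3)))
  p <- predict(up, imgs)
  expect_equal(dim(p$probs), c(2L, 4L))
})

test_that("transfer learning reaches the target accuracy in fewer epochs", {
  # field-shifted data: same classes plus a noise class, shifted colours
  specs4 <- default_class_specs(include_noise = TRUE)
  ds1 <- make_insect_dataset(default_class_specs(), 40, 32, seed = 21,
                             provenance = "lab")
  ds1 <- split_dataset(ds1, c(7, 1.5, 1.5), seed = 21)
  ds2 <- make_insect_dataset(specs4, c(24, 20, 24, 40), 32, seed = 22,
                             provenance = "field",
                             color_shift = c(-18, -10, 8),
                             background_mean = 140)
  ds2 <- split_dataset(ds2, c(6, 2, 2), seed = 22)
  base <- build_resnet_v2(depth = 8L, widths = 12L, n_classes = 3,
                          input_size = 32L, seed = 23)
  base <- train_resnet(base, ds1, train_config(epochs = 6L), seed = 23)
  epochs_to <- function(model, seed) {
    fit <- train_resnet(model, ds2, train_config(epochs = 10L), seed = seed)
    hit <- which(fit$history$val_acc >= 0.85)
    if (length(hit)) hit[1] else Inf
  }
  seeds <- 31:35
  e_transfer <- vapply(seeds, function(s)
    epochs_to(transfer_update(base, 4, seed = s), s), numeric(1))
  e_scratch <- vapply(seeds, function(s)
    epochs_to(build_resnet_v2(depth = 8L, widths = 12L, n_classes = 4,
                              input_size = 32L, seed = s), s), numeric(1))
  expect_lte(median(e_transfer), median(e_scratch))
})
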