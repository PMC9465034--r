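#' Build a full pre-activation residual network
#'
#' Constructs the 56-layer pre-activation residual classifier (stem 3x3
#' convolution, three stages of residual units with widths 16/32/64, each
#' unit ordered BN -> ReLU -> conv -> BN -> ReLU -> conv with an identity
#' skip, 1x1 projections only where a stage halves resolution and doubles
#' width, then BN -> ReLU -> global average pool -> softmax). Valid depths
#' are `2 * S * n + 2` for `S` stages (6n+2 for the standard three): the
#' stem, two convolutions per unit, and the classifier are the weighted
#' layers; projection shortcuts are not counted, following the usual
#' convention.
#'
#' @param depth total weighted layers (default 56).
#' @param widths channel width per stage.
#' @param n_classes output classes.
#' @param input_size square input side, px (32--140).
#' @param seed integer seed for He-style weight initialization.
#' @return An object of class `resnet_v2`.
#' @export
build_resnet_v2 <- function(depth = 56L, widths = c(16L, 32L, 64L),
                            n_classes = 3L, input_size = 32L, seed = 1L) {
  S <- length(widths)
  if ((depth - 2L) %% (2L * S) != 0L || depth < 2L + 2L * S) {
    n_lo <- max(1L, (depth - 2L) %/% (2L * S))
    stop(sprintf("invalid depth %d for %d stages; nearest valid depths: %d, %d",
                 depth, S, 2L * S * n_lo + 2L, 2L * S * (n_lo + 1L) + 2L))
  }
  n <- (depth - 2L) %/% (2L * S)
  arch <- list(widths = as.integer(widths), units_per_stage = as.integer(n),
               n_classes = as.integer(n_classes),
               input_size = as.integer(input_size))
  st <- withr::with_seed(as.integer(seed), resnet_init_params(arch))
  structure(list(arch = arch, depth = as.integer(depth),
                 params = st$params, bn_state = st$bn_state,
                 adam = NULL, history = NULL, provenance = "untrained"),
            class = "resnet_v2")
}

# Parameter and BN-state lists in the canonical order shared with the C++
# core. Convolution weights are (C_out, C_in*9) He-initialized matrices.
resnet_init_params <- function(arch) {
  he <- function(c_out, fan_in) matrix(stats::rnorm(c_out * fan_in, 0,
                                                    sqrt(2 / fan_in)),
                                       c_out, fan_in)
  ones <- function(c) matrix(1, c, 1)
  zeros <- function(c) matrix(0, c, 1)
  params <- list(stem_w = he(arch$widths[1], 3L * 9L))
  bn <- list()
  c_in <- arch$widths[1]
  for (s in seq_along(arch$widths)) {
    c_out <- arch$widths[s]
    for (u in seq_len(arch$units_per_stage)) {
      stride <- if (s > 1 && u == 1) 2L else 1L
      tag <- sprintf("s%du%d", s, u)
      params[[paste0(tag, "_bn1_g")]] <- ones(c_in)
      params[[paste0(tag, "_bn1_b")]] <- zeros(c_in)
      params[[paste0(tag, "_conv1")]] <- he(c_out, c_in * 9L)
      params[[paste0(tag, "_bn2_g")]] <- ones(c_out)
      params[[paste0(tag, "_bn2_b")]] <- zeros(c_out)
      params[[paste0(tag, "_conv2")]] <- he(c_out, c_out * 9L)
      if (stride != 1L || c_in != c_out)
        params[[paste0(tag, "_proj")]] <- he(c_out, c_in)
      bn[[paste0(tag, "_bn1_mean")]] <- zeros(c_in)
      bn[[paste0(tag, "_bn1_var")]] <- ones(c_in)
      bn[[paste0(tag, "_bn2_mean")]] <- zeros(c_out)
      bn[[paste0(tag, "_bn2_var")]] <- ones(c_out)
      c_in <- c_out
    }
  }
  params$bnf_g <- ones(c_in)
  params$bnf_b <- zeros(c_in)
  params$fc_w <- matrix(stats::rnorm(arch$n_classes * c_in, 0, sqrt(1 / c_in)),
                        arch$n_classes, c_in)
  params$fc_b <- zeros(arch$n_classes)
  bn$bnf_mean <- zeros(c_in)
  bn$bnf_var <- ones(c_in)
  list(params = params, bn_state = bn)
}

#' Count the weighted layers of a residual network
#'
#' Stem convolution + two convolutions per residual unit + the final
#' classifier; projection shortcuts are excluded by convention.
#'
#' @param model a `resnet_v2`.
#' @return Integer layer count.
#' @export
count_weighted_layers <- function(model) {
  stopifnot(inherits(model, "resnet_v2"))
  2L * length(model$arch$widths) * model$arch$units_per_stage + 2L
}

#' @export
print.resnet_v2 <- function(x, ...) {
  cat(sprintf(
    "<resnet_v2> depth %d (%d stages x %d units, widths %s), %d classes, %s\n",
    x$depth, length(x$arch$widths), x$arch$units_per_stage,
    paste(x$arch$widths, collapse = "/"), x$arch$n_classes, x$provenance))
  invisible(x)
}

#' Training configuration for the residual network
#'
#' Defaults follow the published recipe: batch size 16, Adam with initial
#' learning rate 1e-3, online augmentation of training images, the best
#' model selected by minimum validation error (ties to the earlier epoch).
#' `epochs` defaults to the full 200-cycle schedule; desk-scale runs pass a
#' smaller value. `patience` stops training early after that many epochs
#' without a new best validation error (Inf disables early stopping).
#'
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param epochs maximum training epochs.
#' @param augment apply online augmentation to training images.
#' @param patience early-stopping patience in epochs.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 1e-3, epochs = 200L,
                         augment = TRUE, patience = Inf,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         bn_momentum = 0.9) {
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), augment = augment,
                 patience = patience, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, bn_momentum = bn_momentum),
            class = "train_config")
}

#' Pack a list of images into an `H x W x 3 x N` array
#' @param images list of equal-size `H x W x 3` arrays.
#' @return A 4-d array.
#' @export
pack_images <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(d, length(images)))
}

zero_like <- function(params) lapply(params, function(p) p * 0)

#' Train a residual network on a split dataset
#'
#' Runs Adam over the training split with per-epoch online augmentation
#' (training images only), records the validation error once per epoch, and
#' returns the model restored to its best-on-validation checkpoint.
#'
#' @param model a `resnet_v2` from [build_resnet_v2()] or [transfer_update()].
#' @param ds an [insect_dataset] with split assignments.
#' @param tc a [train_config()].
#' @param seed integer seed controlling shuffling and augmentation.
#' @return The trained `resnet_v2`, with a `history` data.frame (epoch,
#'   train_loss, train_acc, val_error, val_acc) and `best_epoch`.
#' @export
train_resnet <- function(model, ds, tc = train_config(), seed = 1L) {
  stopifnot(inherits(model, "resnet_v2"), inherits(ds, "insect_dataset"))
  train <- dataset_split(ds, "train")
  val <- dataset_split(ds, "val")
  if (length(train) == 0 || length(val) == 0)
    stop("dataset needs non-empty train and val splits")
  if (max(ds$labels) >= model$arch$n_classes)
    stop("dataset has more classes than the model head")
  y <- train$labels
  x_val <- pack_images(val$images)
  adam_m <- zero_like(model$params)
  adam_v <- zero_like(model$params)
  t_step <- 0L
  params <- model$params
  bn_state <- model$bn_state
  best <- list(err = Inf, epoch = 0L, params = params, bn_state = bn_state)
  hist <- vector("list", tc$epochs)
  seed <- as.integer(seed)
  for (epoch in seq_len(tc$epochs)) {
    ep_seed <- (seed * 1009L + epoch * 7919L) %% 2147483629L
    imgs <- if (tc$augment) {
      lapply(seq_along(train$images), function(i)
        augment(train$images[[i]], seed = (ep_seed + i) %% 2147483629L))
    } else train$images
    x_train <- pack_images(imgs)
    ord <- withr::with_seed(ep_seed, sample.int(length(y))) - 1L
    res <- resnet_train_epoch_cpp(params, adam_m, adam_v, t_step, bn_state,
                                  x_train, as.integer(y), model$arch, tc$lr,
                                  tc$batch_size, as.integer(ord),
                                  tc$bn_momentum, tc$beta1, tc$beta2,
                                  tc$adam_eps)
    params <- res$params
    adam_m <- res$adam_m
    adam_v <- res$adam_v
    bn_state <- res$bn_state
    t_step <- res$t_step
    probs <- resnet_predict_cpp(params, bn_state, x_val, model$arch, 64L)
    pred <- max.col(probs) - 1L
    val_acc <- mean(pred == val$labels)
    val_err <- 1 - val_acc
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = res$train_loss,
                                train_acc = res$train_acc,
                                val_error = val_err, val_acc = val_acc)
    if (val_err < best$err) {  # strict: ties stay with the earlier epoch
      best <- list(err = val_err, epoch = epoch, params = params,
                   bn_state = bn_state)
    }
    # a perfect validation epoch can never be displaced (ties go earlier),
    # so the best checkpoint is already final and training can stop
    if (best$err == 0) break
    if (epoch - best$epoch >= tc$patience) break
  }
  model$params <- best$params
  model$bn_state <- best$bn_state
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model$provenance <- paste0("trained:", ds$provenance)
  model
}

#' Predict class labels and probabilities
#'
#' @param object a trained `resnet_v2`.
#' @param newdata an [insect_dataset] or list of images.
#' @param ... unused.
#' @return A list with `labels` (0-based) and `probs` (N x K matrix).
#' @export
predict.resnet_v2 <- function(object, newdata, ...) {
  images <- if (inherits(newdata, "insect_dataset")) newdata$images else newdata
  x <- pack_images(images)
  probs <- resnet_predict_cpp(object$params, object$bn_state, x, object$arch,
                              64L)
  list(labels = max.col(probs) - 1L, probs = probs)
}

#' Evaluate a model on one split of a dataset
#' @param model a trained `resnet_v2`; @param ds split [insect_dataset];
#' @param split which split to score.
#' @return An `eval_report` (see [eval_metrics()]).
#' @export
evaluate_model <- function(model, ds, split = "test") {
  part <- dataset_split(ds, split)
  pred <- predict(model, part)$labels
  evaluate_predictions(part$labels, pred, model$arch$n_classes)
}

#' Transfer-learning update of a trained network
#'
#' Initializes a new model from a trained base: every convolutional and
#' batch-normalization parameter (and the BN running statistics) is copied
#' bit for bit, the fully connected classifier is discarded and re-created
#' for the new number of classes, and nothing is frozen — all parameters
#' remain trainable in the subsequent [train_resnet()] call.
#'
#' @param base a trained `resnet_v2`.
#' @param n_classes_new classes of the new head.
#' @param seed integer seed for the head initialization.
#' @return A `resnet_v2` ready for training on the new data.
#' @export
transfer_update <- function(base, n_classes_new, seed = 1L) {
  stopifnot(inherits(base, "resnet_v2"))
  model <- base
  model$arch$n_classes <- as.integer(n_classes_new)
  c_fin <- nrow(base$params$bnf_g)
  withr::with_seed(as.integer(seed), {
    model$params$fc_w <- matrix(stats::rnorm(n_classes_new * c_fin, 0,
                                             sqrt(1 / c_fin)),
                                n_classes_new, c_fin)
    model$params$fc_b <- matrix(0, n_classes_new, 1)
  })
  model$history <- NULL
  model$best_epoch <- NULL
  model$provenance <- paste0("transfer_from:", base$provenance)
  model
}

#' Record the per-unit activations of the skip path
#'
#' Inference-mode forward pass that returns every residual unit's input
#' activation and residual-branch output, so the additive identity of the
#' skip path (the activation entering unit L equals the activation at unit l
#' plus the sum of intervening branch outputs) can be checked numerically.
#'
#' @param model a `resnet_v2`; @param images list of images.
#' @return List with `unit_inputs`, `branch_outputs`, `final_preact`,
#'   `logits`.
#' @export
resnet_unit_trace <- function(model, images) {
  x <- pack_images(images)
  resnet_forward_debug_cpp(model$params, model$bn_state, x, model$arch)
}

#' Train-mode loss and analytic gradients on a small batch
#'
#' Exposed for finite-difference verification of the backward pass.
#'
#' @param model a `resnet_v2`; @param images list of images;
#' @param labels 0-based integer labels.
#' @return List with `loss` and `grads` (named like the parameter list).
#' @export
resnet_loss_grad <- function(model, images, labels) {
  x <- pack_images(images)
  resnet_loss_grad_cpp(model$params, model$bn_state, x, as.integer(labels),
                       model$arch)
}
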