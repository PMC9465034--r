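#' Stratified k-fold cross-validation partition
#'
#' Assigns each sample to one of `k` folds, shuffled within class so every
#' fold sees every class; folds are disjoint and cover the data exactly
#' once.
#'
#' @param y class labels.
#' @param k folds.
#' @param seed integer seed.
#' @return Integer fold assignment (1..k) per sample.
#' @export
make_cv_folds <- function(y, k = 10L, seed = 1L) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' PSO-SVM configuration
#'
#' A Gaussian-kernel SVM whose kernel width `gamma` and penalty factor `C`
#' are tuned by particle swarm optimization; the particle fitness is the
#' k-fold cross-validated identification rate. The swarm searches
#' log10-scaled ranges.
#'
#' @param gamma_range,C_range search ranges (positive, finite).
#' @param swarm particles.
#' @param inertia,cognitive,social PSO velocity coefficients.
#' @param iterations PSO iterations.
#' @param cv_folds cross-validation folds for the fitness.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(gamma_range = c(1e-3, 1e2), C_range = c(1e-2, 1e3),
                       swarm = 30L, inertia = 0.72, cognitive = 1.49,
                       social = 1.49, iterations = 100L, cv_folds = 10L) {
  stopifnot(all(gamma_range > 0), all(is.finite(gamma_range)),
            all(C_range > 0), all(is.finite(C_range)),
            swarm >= 2, iterations >= 1, cv_folds >= 2)
  structure(list(gamma_range = gamma_range, C_range = C_range,
                 swarm = as.integer(swarm), inertia = inertia,
                 cognitive = cognitive, social = social,
                 iterations = as.integer(iterations),
                 cv_folds = as.integer(cv_folds)),
            class = "svm_config")
}

svm_cv_fitness <- function(X, y, gamma, C, folds) {
  acc <- 0
  n <- length(y)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      gamma = gamma, cost = C, scale = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    acc <- acc + sum(pred == y[!tr])
  }
  acc / n
}

#' Train a particle-swarm-optimised SVM
#'
#' Maximizes the cross-validated identification rate over `(gamma, C)` with
#' a global-best particle swarm (positions in log10 space, velocities
#' clamped to the search box), then refits the SVM on the full training data
#' at the optimum. The search stops early once a particle reaches perfect
#' cross-validated accuracy, which no further iteration can improve.
#'
#' @param X numeric feature matrix (typically the GBDT-selected columns).
#' @param y class labels (coerced to factor; at least 2 classes).
#' @param config an [svm_config()].
#' @param seed integer seed.
#' @return A list of class `pso_svm`: `model` (the fitted SVM), `gamma`,
#'   `C`, `cv_accuracy`, and `trace` (best fitness per iteration,
#'   nondecreasing).
#' @export
train_pso_svm <- function(X, y, config = svm_config(), seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("empty feature set")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  lo <- log10(c(config$gamma_range[1], config$C_range[1]))
  hi <- log10(c(config$gamma_range[2], config$C_range[2]))
  folds <- make_cv_folds(y, config$cv_folds, seed)
  withr::with_seed(as.integer(seed) + 1L, {
    np <- config$swarm
    pos <- cbind(stats::runif(np, lo[1], hi[1]), stats::runif(np, lo[2], hi[2]))
    vel <- matrix(0, np, 2)
    fit <- apply(pos, 1, function(p)
      svm_cv_fitness(X, y, 10^p[1], 10^p[2], folds))
    pbest <- pos
    pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    trace <- numeric(0)
    for (it in seq_len(config$iterations)) {
      if (gbest_fit >= 1) {
        trace <- c(trace, rep(gbest_fit, 1))
        break
      }
      r1 <- matrix(stats::runif(np * 2), np, 2)
      r2 <- matrix(stats::runif(np * 2), np, 2)
      vel <- config$inertia * vel +
        config$cognitive * r1 * (pbest - pos) +
        config$social * r2 * (sweep(-pos, 2, gbest, `+`))
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      fit <- apply(pos, 1, function(p)
        svm_cv_fitness(X, y, 10^p[1], 10^p[2], folds))
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      if (max(fit) > gbest_fit) {
        g <- which.max(fit)
        gbest <- pos[g, ]
        gbest_fit <- fit[g]
      }
      trace <- c(trace, gbest_fit)
    }
  })
  gamma <- 10^gbest[1]
  C <- 10^gbest[2]
  final <- e1071::svm(X, y, kernel = "radial", gamma = gamma, cost = C,
                      scale = FALSE)
  structure(list(model = final, gamma = gamma, C = C,
                 cv_accuracy = gbest_fit, trace = trace),
            class = "pso_svm")
}

#' @export
predict.pso_svm <- function(object, newdata, ...) {
  stats::predict(object$model, as.matrix(newdata))
}

#' @export
print.pso_svm <- function(x, ...) {
  cat(sprintf("<pso_svm> gamma %.4g, C %.4g, CV accuracy %.3f (%d iterations)\n",
              x$gamma, x$C, x$cv_accuracy, length(x$trace)))
  invisible(x)
}

#' Exponential learning-rate decay schedule
#'
#' `lr(t) = lr0 * rate^(t / steps)` for global step `t`.
#'
#' @param lr0 initial rate; @param rate decay factor per `steps` steps;
#' @param steps decay period; @param t global step (vectorized).
#' @return Learning rate(s) at step `t`.
#' @export
exp_decay_lr <- function(lr0, rate, steps, t) lr0 * rate^(t / steps)

#' Back-propagation neural network configuration
#'
#' A single-hidden-layer network (sigmoid hidden units, softmax output)
#' trained by stochastic gradient descent with exponential learning-rate
#' decay and an L2 penalty on the weights, the weights initialized from a
#' Gaussian with mean 0 and standard deviation `1/n_in` (a `1/sqrt(n_in)`
#' option is available, as the literal reciprocal is unusually small). The
#' default geometry is 11 inputs (the selected features), 3 hidden nodes and
#' 3 outputs; the hidden width is exposed directly because empirical
#' formulas for it disagree.
#'
#' @param n_input,n_hidden,n_output layer sizes.
#' @param lr0,decay_rate,decay_steps exponential decay schedule (see
#'   [exp_decay_lr()]).
#' @param l2 L2 regularization strength (>= 0).
#' @param epochs training epochs; @param batch_size SGD minibatch.
#' @param init_sd `"reciprocal"` for 1/n_in or `"inv_sqrt"` for 1/sqrt(n_in).
#' @param cv_folds folds of the cross-validated training protocol.
#' @return A list of class `bpnn_config`.
#' @export
bpnn_config <- function(n_input = 11L, n_hidden = 3L, n_output = 3L,
                        lr0 = 0.5, decay_rate = 0.96, decay_steps = 200L,
                        l2 = 1e-4, epochs = 300L, batch_size = 8L,
                        init_sd = c("reciprocal", "inv_sqrt"),
                        cv_folds = 10L) {
  init_sd <- match.arg(init_sd)
  stopifnot(n_hidden >= 1, l2 >= 0, epochs >= 1)
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output), lr0 = lr0,
                 decay_rate = decay_rate, decay_steps = as.integer(decay_steps),
                 l2 = l2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), init_sd = init_sd,
                 cv_folds = as.integer(cv_folds)),
            class = "bpnn_config")
}

bpnn_init <- function(config) {
  sd_of <- function(n_in) if (config$init_sd == "reciprocal") 1 / n_in
    else 1 / sqrt(n_in)
  list(W1 = matrix(stats::rnorm(config$n_hidden * config$n_input, 0,
                                sd_of(config$n_input)),
                   config$n_hidden, config$n_input),
       b1 = numeric(config$n_hidden),
       W2 = matrix(stats::rnorm(config$n_output * config$n_hidden, 0,
                                sd_of(config$n_hidden)),
                   config$n_output, config$n_hidden),
       b2 = numeric(config$n_output))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

bpnn_forward <- function(w, X) {
  # X: n x m; returns hidden activations and class probabilities
  H <- sigmoid(sweep(X %*% t(w$W1), 2, w$b1, `+`))
  Z <- sweep(H %*% t(w$W2), 2, w$b2, `+`)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  list(H = H, P = E / rowSums(E))
}

#' Cross-entropy loss of a BPNN with L2 penalty
#'
#' @param w weight list (`W1`, `b1`, `W2`, `b2`).
#' @param X feature matrix; @param y 0-based labels; @param l2 penalty.
#' @return Mean cross-entropy plus `l2/2` times the squared weight norm.
#' @export
bpnn_loss <- function(w, X, y, l2 = 0) {
  P <- bpnn_forward(w, X)$P
  ce <- -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
  ce + l2 / 2 * (sum(w$W1^2) + sum(w$W2^2))
}

bpnn_sgd <- function(w, X, y, config, seed) {
  n <- nrow(X)
  K <- config$n_output
  t_step <- 0L
  withr::with_seed(as.integer(seed), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        B <- length(idx)
        fw <- bpnn_forward(w, X[idx, , drop = FALSE])
        dZ <- fw$P
        dZ[cbind(seq_len(B), y[idx] + 1L)] <-
          dZ[cbind(seq_len(B), y[idx] + 1L)] - 1
        dZ <- dZ / B
        gW2 <- t(dZ) %*% fw$H + config$l2 * w$W2
        gb2 <- colSums(dZ)
        dH <- dZ %*% w$W2 * fw$H * (1 - fw$H)
        gW1 <- t(dH) %*% X[idx, , drop = FALSE] + config$l2 * w$W1
        gb1 <- colSums(dH)
        lr <- exp_decay_lr(config$lr0, config$decay_rate, config$decay_steps,
                           t_step)
        w$W1 <- w$W1 - lr * gW1
        w$b1 <- w$b1 - lr * gb1
        w$W2 <- w$W2 - lr * gW2
        w$b2 <- w$b2 - lr * gb2
        t_step <- t_step + 1L
      }
    }
  })
  w
}

#' Train a back-propagation neural network
#'
#' Follows the cross-validated protocol: the network is trained on each
#' k-fold training portion and scored on the held-out fold (the mean
#' held-out accuracy is reported as `cv_accuracy`), then a final network is
#' trained on all the data.
#'
#' @param X feature matrix with exactly `config$n_input` columns.
#' @param y 0-based integer class labels.
#' @param config a [bpnn_config()].
#' @param seed integer seed.
#' @return A list of class `bpnn`: `weights`, `cv_accuracy`, `config`.
#' @export
train_bpnn <- function(X, y, config = bpnn_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (ncol(X) != config$n_input)
    stop(sprintf("X has %d columns but the network expects %d inputs",
                 ncol(X), config$n_input))
  if (length(unique(y)) != config$n_output)
    stop("number of observed classes must equal n_output")
  folds <- make_cv_folds(y, config$cv_folds, seed)
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    w <- withr::with_seed(as.integer(seed) + f,
                          bpnn_init(config))
    w <- bpnn_sgd(w, X[tr, , drop = FALSE], y[tr], config,
                  seed = as.integer(seed) + 100L + f)
    pred <- max.col(bpnn_forward(w, X[!tr, , drop = FALSE])$P) - 1L
    mean(pred == y[!tr])
  }, numeric(1))
  w <- withr::with_seed(as.integer(seed), bpnn_init(config))
  w <- bpnn_sgd(w, X, y, config, seed = as.integer(seed) + 999L)
  structure(list(weights = w, cv_accuracy = mean(accs), config = config),
            class = "bpnn")
}

#' @export
predict.bpnn <- function(object, newdata, ...) {
  P <- bpnn_forward(object$weights, as.matrix(newdata))$P
  list(labels = max.col(P) - 1L, probs = P)
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-%d, CV accuracy %.3f\n", x$config$n_input,
              x$config$n_hidden, x$config$n_output, x$cv_accuracy))
  invisible(x)
}
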