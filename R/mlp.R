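# Single-hidden-layer perceptron on pooled embeddings.
# The default configuration is the tuned one: 120 hidden units,
# identity activation (the network is effectively linear), adam with
# adaptive learning-rate schedule, minibatches of 250, L2 penalty
# 5e-4, early stopping after 20 stalled epochs at tolerance 1e-3.

#' Multilayer-perceptron training configuration
#'
#' Defaults are the selected values of the randomized hyperparameter
#' search (scored by adjusted balanced accuracy over grouped
#' cross-validation folds).
#'
#' @param hidden_units size of the single hidden layer.
#' @param activation `"identity"`, `"logistic"`, `"tanh"` or `"relu"`.
#' @param solver `"adam"` or `"sgd"`.
#' @param learning_rate schedule: `"constant"`, `"adaptive"` (divide by
#'   5 whenever `patience` epochs bring no improvement) or
#'   `"invscaling"`.
#' @param learning_rate_init initial learning rate.
#' @param max_epochs maximum number of passes over the training data.
#' @param patience epochs without loss improvement greater than `tol`
#'   before the schedule reacts (adaptive) or training stops.
#' @param tol minimum loss improvement that counts as progress.
#' @param l2_penalty L2 regularization strength (alpha).
#' @param batch_size minibatch size (capped at the sample count).
#' @param seed integer seed fixing initialization and batch order.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_units = 120, activation = "identity",
                       solver = "adam", learning_rate = "adaptive",
                       learning_rate_init = 0.01, max_epochs = 1000,
                       patience = 20, tol = 1e-3, l2_penalty = 5e-4,
                       batch_size = 250, seed = 22) {
  activation <- match.arg(activation, c("identity", "logistic", "tanh", "relu"))
  solver <- match.arg(solver, c("adam", "sgd"))
  learning_rate <- match.arg(learning_rate,
                             c("constant", "adaptive", "invscaling"))
  stopifnot(hidden_units >= 1, learning_rate_init > 0, max_epochs >= 1,
            patience >= 1, tol > 0, l2_penalty >= 0, batch_size >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation, solver = solver,
                 learning_rate = learning_rate,
                 learning_rate_init = learning_rate_init,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), tol = tol,
                 l2_penalty = l2_penalty,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

.qs_activation <- function(name) {
  switch(name,
    identity = list(f = function(z) z, g = function(z, a) 1),
    relu = list(f = function(z) pmax(z, 0), g = function(z, a) (z > 0) * 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    g = function(z, a) a * (1 - a)),
    tanh = list(f = tanh, g = function(z, a) 1 - a^2))
}

.qs_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Train the quaternary-state MLP
#'
#' Minimizes softmax cross-entropy with an L2 penalty by minibatch
#' adam (or sgd), with early stopping: an epoch whose full-data loss
#' does not improve on the best seen by more than `tol` counts as
#' stalled; after `patience` stalled epochs the adaptive schedule
#' divides the learning rate by 5 (training stops once it falls below
#' 1e-6), other schedules stop immediately.  A fixed seed makes the
#' fit reproducible.
#'
#' @param train a `qs_embedded` training set, or a numeric matrix
#'   (then `labels` must be given).
#' @param config an [mlp_config()].
#' @param labels integer labels when `train` is a matrix.
#' @return a `qs_mlp` model: weights, ordered class list, input
#'   dimension, config and loss curve.
#' @export
train_mlp <- function(train, config = mlp_config(), labels = NULL) {
  if (inherits(train, "qs_embedded")) {
    X <- train$vectors; y <- train$labels
  } else {
    X <- as.matrix(train); y <- labels
  }
  stopifnot(is.numeric(X), length(y) == nrow(X))
  if (!all(is.finite(X))) stop("non-finite values in training vectors")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  n <- nrow(X); D <- ncol(X); C <- length(classes)
  H <- config$hidden_units
  Y <- outer(y, classes, "==") * 1
  act <- .qs_activation(config$activation)
  alpha <- config$l2_penalty
  batch <- min(config$batch_size, n)
  state <- .qs_with_seed(config$seed, {
    glorot <- function(a, b) {
      r <- sqrt(6 / (a + b))
      matrix(runif(a * b, -r, r), a, b)
    }
    W1 <- glorot(D, H); b1 <- rep(0, H)
    W2 <- glorot(H, C); b2 <- rep(0, C)
    ms <- list(W1 * 0, b1 * 0, W2 * 0, b2 * 0); vs <- ms
    t <- 0; lr <- config$learning_rate_init
    best <- Inf; stalled <- 0; losses <- numeric(0)
    full_loss <- function() {
      P <- .qs_softmax(sweep(act$f(sweep(X %*% W1, 2, b1, "+")) %*% W2,
                             2, b2, "+"))
      -mean(log(pmax(rowSums(P * Y), 1e-12))) +
        alpha * (sum(W1^2) + sum(W2^2)) / (2 * n)
    }
    epochs_run <- 0
    for (ep in seq_len(config$max_epochs)) {
      epochs_run <- ep
      snap <- list(W1, b1, W2, b2)           # restored if the epoch diverges
      idx <- sample(n)
      for (st in split(idx, ceiling(seq_along(idx) / batch))) {
        Xb <- X[st, , drop = FALSE]; Yb <- Y[st, , drop = FALSE]
        m <- length(st)
        Z1 <- sweep(Xb %*% W1, 2, b1, "+"); A1 <- act$f(Z1)
        P <- .qs_softmax(sweep(A1 %*% W2, 2, b2, "+"))
        dZ2 <- (P - Yb) / m
        gW2 <- crossprod(A1, dZ2) + alpha * W2 / n
        gb2 <- colSums(dZ2)
        dZ1 <- (dZ2 %*% t(W2)) * act$g(Z1, A1)
        gW1 <- crossprod(Xb, dZ1) + alpha * W1 / n
        gb1 <- colSums(dZ1)
        gs <- list(gW1, gb1, gW2, gb2)
        t <- t + 1
        eff_lr <- if (config$learning_rate == "invscaling")
          config$learning_rate_init / sqrt(t) else lr
        if (config$solver == "adam") {
          for (j in 1:4) {
            ms[[j]] <- 0.9 * ms[[j]] + 0.1 * gs[[j]]
            vs[[j]] <- 0.999 * vs[[j]] + 0.001 * gs[[j]]^2
            gs[[j]] <- (ms[[j]] / (1 - 0.9^t)) /
              (sqrt(vs[[j]] / (1 - 0.999^t)) + 1e-8)
          }
        }
        W1 <- W1 - eff_lr * gs[[1]]; b1 <- b1 - eff_lr * gs[[2]]
        W2 <- W2 - eff_lr * gs[[3]]; b2 <- b2 - eff_lr * gs[[4]]
      }
      L <- full_loss()
      if (!is.finite(L)) {                   # diverged (e.g. absurd lr)
        W1 <- snap[[1]]; b1 <- snap[[2]]; W2 <- snap[[3]]; b2 <- snap[[4]]
        break
      }
      losses <- c(losses, L)
      if (L < best - config$tol) { best <- L; stalled <- 0 }
      else stalled <- stalled + 1
      if (stalled >= config$patience) {
        if (config$learning_rate == "adaptive") {
          lr <- lr / 5; stalled <- 0
          if (lr <= 1e-6) break
        } else break
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, losses = losses,
         epochs = epochs_run)
  })
  structure(list(W1 = state$W1, b1 = state$b1, W2 = state$W2,
                 b2 = state$b2, classes = classes, dim = D,
                 config = config, loss_curve = state$losses,
                 epochs = state$epochs),
            class = "qs_mlp")
}

#' @export
print.qs_mlp <- function(x, ...) {
  cat(sprintf(
    "qs_mlp: D = %d -> %d hidden (%s) -> %d classes (%s); %d epochs\n",
    x$dim, x$config$hidden_units, x$config$activation, length(x$classes),
    paste(x$classes, collapse = ","), x$epochs))
  invisible(x)
}

#' Class probabilities and labels for new records
#'
#' @param model a trained `qs_mlp`.
#' @param newdata a `qs_embedded` or numeric matrix with the model's
#'   input dimension.
#' @return data.frame with `id`, `predicted_qs`, `top_prob`, and one
#'   `p_<qs>` column per model class; probabilities sum to 1.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "qs_mlp"))
  if (inherits(newdata, "qs_embedded")) {
    X <- newdata$vectors; ids <- newdata$ids
  } else {
    X <- as.matrix(newdata)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  if (ncol(X) != model$dim) {
    stop(sprintf("dimension mismatch: model expects D = %d, got %d",
                 model$dim, ncol(X)))
  }
  act <- .qs_activation(model$config$activation)
  P <- .qs_softmax(sweep(act$f(sweep(X %*% model$W1, 2, model$b1, "+")) %*%
                           model$W2, 2, model$b2, "+"))
  best <- max.col(P, ties.method = "first")
  out <- data.frame(id = ids,
                    predicted_qs = model$classes[best],
                    top_prob = P[cbind(seq_len(nrow(P)), best)],
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(P)
  names(probs) <- paste0("p_", model$classes)
  cbind(out, probs)
}

#' @export
predict.qs_mlp <- function(object, newdata, ...) {
  predict_proba(object, newdata)$predicted_qs
}

#' Randomized hyperparameter search over grouped folds
#'
#' Samples `n_samples` configurations uniformly from `space` (a named
#' list of candidate values for [mlp_config()] arguments), trains each
#' on every fold's complement and scores it by the mean adjusted
#' balanced accuracy on the held-out folds, and returns the best
#' configuration with the full score table.
#'
#' @param dataset a `qs_embedded` training dataset.
#' @param folds data.frame from [make_cv_folds()] covering the dataset
#'   ids.
#' @param space named list, e.g.
#'   `list(learning_rate_init = c(0.001, 0.01), hidden_units = c(40, 120))`.
#' @param n_samples number of configurations to draw, >= 1.
#' @param seed integer seed for the draw.
#' @return list with `best_config` (an `mlp_config`) and `scores`
#'   (one row per sampled configuration).
#' @export
hyperparameter_search <- function(dataset, folds, space, n_samples = 10,
                                  seed = 1) {
  stopifnot(inherits(dataset, "qs_embedded"), n_samples >= 1)
  if (length(space) == 0) stop("empty hyperparameter space")
  bad <- setdiff(names(space), names(formals(mlp_config)))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  draws <- .qs_with_seed(seed, {
    lapply(seq_len(n_samples), function(i)
      lapply(space, function(vals) vals[[sample.int(length(vals), 1)]]))
  })
  fold_ids <- sort(unique(folds$fold))
  pos <- match(folds$id, dataset$ids)
  rows <- lapply(seq_along(draws), function(i) {
    cfg <- do.call(mlp_config, draws[[i]])
    bas <- vapply(fold_ids, function(f) {
      te <- pos[folds$fold == f]; tr <- pos[folds$fold != f]
      model <- train_mlp(dataset[tr], cfg)
      pred <- predict_proba(model, dataset[te])$predicted_qs
      adjusted_balanced_accuracy(dataset$labels[te], pred,
                                 n_classes = length(unique(dataset$labels)))
    }, numeric(1))
    cbind(data.frame(config_id = i, mean_adjusted_ba = mean(bas)),
          as.data.frame(draws[[i]], stringsAsFactors = FALSE))
  })
  scores <- do.call(rbind, rows)
  best <- which.max(scores$mean_adjusted_ba)
  list(best_config = do.call(mlp_config, draws[[best]]), scores = scores)
}

#' Save / load a trained model as self-describing JSON
#'
#' @param model a `qs_mlp`.
#' @param path JSON path.
#' @return `path` (save) or the restored `qs_mlp` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qs_mlp"))
  payload <- list(
    format = "qs_mlp", version = 1L,
    dim = model$dim, classes = model$classes,
    config = unclass(model$config),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "qs_mlp")) stop("not a qs_mlp model file: ", path)
  cfg <- do.call(mlp_config, p$config)
  structure(list(W1 = matrix(unlist(p$W1), nrow = p$dim),
                 b1 = as.numeric(p$b1),
                 W2 = matrix(unlist(p$W2), nrow = cfg$hidden_units),
                 b2 = as.numeric(p$b2),
                 classes = as.integer(p$classes), dim = as.integer(p$dim),
                 config = cfg, loss_curve = numeric(0), epochs = NA_integer_),
            class = "qs_mlp")
}
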