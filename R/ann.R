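# Multilayer perceptron mapping normalized lesion-side measurements to the
# matched normalized perturbation.  The network is small (four affine
# layers, ~200k parameters) and is trained directly with base matrix
# arithmetic: full-batch matrix products per minibatch, hand-written
# backpropagation, and Adam updates.

#' Network architecture specification
#'
#' Default architecture: 252 inputs (126 offset log-amplitudes followed by
#' 126 offset phases), three hidden layers of 256, 128, and 256 rectified
#' linear units, and a linear 252-wide output (126 real followed by 126
#' imaginary perturbation parts).
#'
#' @param layer_widths integer vector of layer widths, input first.
#' @return object of class `ann_spec`.
#' @export
ann_spec <- function(layer_widths = c(252, 256, 128, 256, 252)) {
  stopifnot(length(layer_widths) >= 2, all(layer_widths >= 1))
  structure(list(layer_widths = as.integer(layer_widths)),
            class = "ann_spec")
}

# Seeded uniform fan-in initialization: W ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
mlp_init <- function(spec, rng_seed = 1) {
  w <- spec$layer_widths
  with_seed(rng_seed, {
    lapply(seq_len(length(w) - 1), function(i) {
      bound <- 1 / sqrt(w[i])
      list(W = matrix(stats::runif(w[i] * w[i + 1], -bound, bound),
                      w[i], w[i + 1]),
           b = stats::runif(w[i + 1], -bound, bound))
    })
  })
}

mlp_n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass; returns output and (optionally) the per-layer activations
# needed for backpropagation.  X is n x d_in.
mlp_forward <- function(params, X, keep_activations = FALSE) {
  L <- length(params)
  acts <- if (keep_activations) vector("list", L + 1) else NULL
  A <- X
  if (keep_activations) acts[[1]] <- A
  for (i in seq_len(L)) {
    Z <- A %*% params[[i]]$W
    Z <- sweep(Z, 2, params[[i]]$b, "+")
    A <- if (i < L) pmax(Z, 0) else Z   # ReLU on hidden layers only
    if (keep_activations) acts[[i + 1]] <- A
  }
  if (keep_activations) list(output = A, activations = acts) else A
}

# Gradients of mean-squared-error loss (mean over all entries, matching the
# usual deep-learning reduction) with respect to all weights and biases.
mlp_gradients <- function(params, X, Y) {
  L <- length(params)
  fw <- mlp_forward(params, X, keep_activations = TRUE)
  acts <- fw$activations
  n_entries <- length(Y)
  delta <- 2 * (fw$output - Y) / n_entries
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(params[[i]]$W)
      delta <- delta * (acts[[i]] > 0)   # ReLU derivative
    }
  }
  list(grads = grads, loss = mean((fw$output - Y)^2))
}

#' Fit the perturbation-prediction network
#'
#' Trains the MLP that maps a normalized lesion-side measurement to the
#' matched normalized perturbation, so that difference imaging needs no
#' reference measurement at prediction time.  Optimization follows the
#' standard protocol for this model: mean squared error loss, Adam
#' (learning rate 1e-4, weight decay 1e-5 added to the gradients), 200
#' epochs of shuffled minibatches of 64, and a plateau schedule that
#' multiplies the learning rate by 0.2 whenever the validation loss has
#' not improved for three consecutive epochs.  The returned model carries
#' the parameters of the epoch with the lowest validation loss.
#'
#' @param train training `dot_corpus` (or a list with matrices `X`, `Y`).
#' @param validation validation corpus; when `NULL`, the training loss
#'   drives the schedule and checkpointing.
#' @param spec an [ann_spec()].
#' @param epochs,batch_size,learning_rate,weight_decay optimizer settings.
#' @param lr_factor,lr_patience plateau schedule: multiply the learning
#'   rate by `lr_factor` after `lr_patience` non-improving epochs.
#' @param rng_seed seed for initialization and batch shuffling.
#' @param verbose print a progress line every 20 epochs.
#' @return object of class `pert_ann`: fitted weights, the architecture,
#'   normalization constants, and the loss/learning-rate history.
#' @seealso [predict.pert_ann()], [plot.pert_ann()]
#' @export
pert_ann <- function(train, validation = NULL, spec = ann_spec(),
                     epochs = 200, batch_size = 64,
                     learning_rate = 1e-4, weight_decay = 1e-5,
                     lr_factor = 0.2, lr_patience = 3,
                     rng_seed = 1, verbose = FALSE) {
  X <- as.matrix(train$X); Y <- as.matrix(train$Y)
  if (nrow(X) == 0) stop("empty training corpus")
  if (ncol(X) != spec$layer_widths[1] ||
      ncol(Y) != spec$layer_widths[length(spec$layer_widths)])
    stop("corpus width does not match the network architecture")
  Xv <- if (!is.null(validation)) as.matrix(validation$X) else NULL
  Yv <- if (!is.null(validation)) as.matrix(validation$Y) else NULL

  params <- mlp_init(spec, rng_seed)
  adam <- list(m = rapply(params, function(p) p * 0, how = "replace"),
               v = rapply(params, function(p) p * 0, how = "replace"),
               t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  lr <- learning_rate
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_, lr = NA_real_)
  stall <- 0L
  n <- nrow(X)

  with_seed(derive_seed(rng_seed, "shuffle"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        g <- mlp_gradients(params, X[idx, , drop = FALSE],
                           Y[idx, , drop = FALSE])
        if (!is.finite(g$loss)) stop("training diverged: non-finite loss")
        adam$t <- adam$t + 1
        bc1 <- 1 - adam$beta1^adam$t
        bc2 <- 1 - adam$beta2^adam$t
        for (l in seq_along(params)) {
          for (nm in c("W", "b")) {
            gr <- g$grads[[l]][[nm]] + weight_decay * params[[l]][[nm]]
            adam$m[[l]][[nm]] <- adam$beta1 * adam$m[[l]][[nm]] +
              (1 - adam$beta1) * gr
            adam$v[[l]][[nm]] <- adam$beta2 * adam$v[[l]][[nm]] +
              (1 - adam$beta2) * gr^2
            params[[l]][[nm]] <- params[[l]][[nm]] -
              lr * (adam$m[[l]][[nm]] / bc1) /
                (sqrt(adam$v[[l]][[nm]] / bc2) + adam$eps)
          }
        }
        ep_loss <- ep_loss + g$loss * length(idx)
      }
      history$train_loss[ep] <- ep_loss / n
      monitor <- if (!is.null(Xv)) {
        vl <- mean((mlp_forward(params, Xv) - Yv)^2)
        history$val_loss[ep] <- vl
        vl
      } else history$train_loss[ep]
      history$lr[ep] <- lr
      if (monitor < best$loss) {
        best <- list(loss = monitor, params = params, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= lr_patience) {
          lr <- lr * lr_factor
          stall <- 0L
        }
      }
      if (verbose && ep %% 20 == 0)
        message(sprintf("epoch %3d  train %.3e  val %s  lr %.1e", ep,
                        history$train_loss[ep],
                        ifelse(is.null(Xv), "-",
                               sprintf("%.3e", history$val_loss[ep])), lr))
    }
  })

  structure(list(params = best$params, spec = spec,
                 best_epoch = best$epoch, best_loss = best$loss,
                 history = history,
                 normalization = c(common_max_logamp = 0,
                                   common_min_phase = 0),
                 input_layout = "logamp_then_phase_source_major",
                 output_layout = "real_then_imag_source_major",
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate,
                               weight_decay = weight_decay,
                               lr_factor = lr_factor,
                               lr_patience = lr_patience),
                 rng_seed = rng_seed),
            class = "pert_ann")
}

#' @export
print.pert_ann <- function(x, ...) {
  cat("perturbation-prediction MLP\n")
  cat(sprintf("  architecture: %s (%d parameters)\n",
              paste(x$spec$layer_widths, collapse = "-"),
              mlp_n_params(x$params)))
  cat(sprintf("  best %s loss %.4e at epoch %d of %d\n",
              if (all(is.na(x$history$val_loss))) "training" else "validation",
              x$best_loss, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
summary.pert_ann <- function(object, ...) {
  print(object)
  h <- object$history
  drops <- which(diff(h$lr) < 0)
  cat(sprintf("  final lr %.2e; schedule reductions at epochs: %s\n",
              h$lr[nrow(h)],
              if (length(drops)) paste(drops + 1, collapse = ", ") else "none"))
  cat(sprintf("  train loss: first %.3e, last %.3e\n",
              h$train_loss[1], h$train_loss[nrow(h)]))
  invisible(object)
}

#' @export
coef.pert_ann <- function(object, ...) object$params

#' Loss and learning-rate history plot
#'
#' @param x a fitted [pert_ann()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pert_ann <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, log10(cbind(h$train_loss, h$val_loss)),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "log10 MSE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict the matched perturbation from a lesion-side measurement
#'
#' The prediction is a pure function of the lesion-side measurement: no
#' reference measurement enters, which is the point of the approach --
#' the network always outputs a matched perturbation, immune to
#' reference-side mismatch.
#'
#' @param object a fitted [pert_ann()].
#' @param newdata an [fd_measurement()], or a numeric matrix of
#'   already-encoded network inputs (rows = cases).
#' @param ... unused.
#' @return a [perturbation()] (for a single measurement) or a matrix of
#'   encoded outputs (for a matrix input).
#' @export
predict.pert_ann <- function(object, newdata, ...) {
  if (inherits(newdata, "fd_measurement")) {
    x <- encode_network_input(newdata,
                              object$normalization[["common_max_logamp"]],
                              object$normalization[["common_min_phase"]])
    if (length(x) != object$spec$layer_widths[1])
      stop("measurement geometry does not match the network input width")
    y <- mlp_forward(object$params, matrix(x, 1))
    decode_network_output(as.vector(y), wavelength = newdata$wavelength,
                          geometry = newdata$geometry)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object$spec$layer_widths[1])
      stop("input width does not match the network")
    mlp_forward(object$params, newdata)
  }
}

#' Mean squared error of the best constant predictor
#'
#' The floor any useful model must beat: predicting the training-set mean
#' target for every case.
#'
#' @param train training corpus (provides the constant).
#' @param eval corpus on which the MSE is evaluated (defaults to `train`).
#' @return mean squared error of the constant predictor.
#' @export
constant_predictor_mse <- function(train, eval = train) {
  mu <- colMeans(as.matrix(train$Y))
  mean(sweep(as.matrix(eval$Y), 2, mu)^2)
}
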