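#' Bottleneck-of-one autoencoder architecture
#'
#' The seven-layer shape used throughout: input (8) -> dense(hidden,
#' activation) -> dropout -> dense(1, linear) -> dropout -> dense(hidden,
#' activation) -> dense(8, linear). Encoder and decoder share the hidden
#' width and activation; the central linear neuron's output is the composite
#' score.
#'
#' @param hidden Hidden-layer width (default 24).
#' @param activation Hidden activation: `"relu"`, `"tanh"`, `"sigmoid"` or
#'   `"linear"`.
#' @param dropout Dropout rate in `[0, 1)` applied after the hidden encoder
#'   layer and after the bottleneck, during training only (default 0.4).
#' @param input Number of input measures (default 8).
#' @return An object of class `ae_architecture`.
#' @export
ae_architecture <- function(hidden = 24L,
                            activation = c("relu", "tanh", "sigmoid", "linear"),
                            dropout = 0.4, input = 8L) {
  activation <- match.arg(activation)
  if (!is_scalar_number(hidden) || hidden < 1) abort("hidden must be a positive integer")
  if (!is_scalar_number(dropout) || dropout < 0 || dropout >= 1) {
    abort("dropout must lie in [0, 1)")
  }
  structure(
    list(input = as.integer(input), hidden = as.integer(hidden),
         bottleneck = 1L, activation = activation, dropout = dropout),
    class = "ae_architecture"
  )
}

#' @export
print.ae_architecture <- function(x, ...) {
  cat(sprintf(
    "<ae_architecture> %d -> %d (%s) -> dropout(%.2g) -> 1 (linear) -> dropout(%.2g) -> %d (%s) -> %d\n",
    x$input, x$hidden, x$activation, x$dropout, x$dropout, x$hidden,
    x$activation, x$input
  ))
  invisible(x)
}

act_forward <- function(x, name) {
  switch(name,
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    linear = x
  )
}

# derivative wrt pre-activation, expressed via pre and post values
act_deriv <- function(pre, post, name) {
  switch(name,
    relu = (pre > 0) + 0,
    tanh = 1 - post^2,
    sigmoid = post * (1 - post),
    linear = array(1, dim(pre))
  )
}

add_bias <- function(m, b) sweep(m, 2, b, "+")

# Clean (dropout-free) forward pass. Returns bottleneck scores and
# reconstruction.
ae_forward <- function(params, x, activation) {
  a1 <- act_forward(add_bias(x %*% params$W1, params$b1), activation)
  z <- add_bias(a1 %*% params$W2, params$b2)
  a3 <- act_forward(add_bias(z %*% params$W3, params$b3), activation)
  xhat <- add_bias(a3 %*% params$W4, params$b4)
  list(z = z, xhat = xhat)
}

#' Train the autoencoder
#'
#' Full-batch gradient descent with the Adam optimizer on the mean squared
#' reconstruction error `L = mean((x - x')^2)` (averaged over all entries).
#' Dropout is active during training only; the per-epoch loss trace and all
#' reported losses are computed dropout-free. Training is deterministic
#' given the seed (weight initialization and dropout masks draw from a
#' single seeded stream).
#'
#' @param data A standardized records-by-measures tibble or matrix (at least
#'   2 rows; column count must match `arch$input`).
#' @param arch An [ae_architecture()].
#' @param battery Optional battery restricting/ordering the measure columns.
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs Maximum number of full-batch epochs (default 2000).
#' @param patience Early-stopping patience in epochs on the dropout-free
#'   training loss (`Inf` disables; default 200).
#' @param min_delta Minimum loss improvement counted by early stopping.
#' @param seed Integer seed.
#' @return An object of class `composcore_ae` holding the learned
#'   parameters, architecture, loss trace, and seed.
#' @export
#' @examples
#' z <- generate_two_factor(two_factor_config(n_records = 50, seed = 1))
#' fit <- train_ae(z, ae_architecture(hidden = 10), epochs = 200, seed = 1)
#' glance(fit)
train_ae <- function(data, arch = ae_architecture(), battery = NULL,
                     learning_rate = 0.01, epochs = 2000L, patience = 200L,
                     min_delta = 1e-5, seed = 1L) {
  if (!inherits(arch, "ae_architecture")) abort("arch must be an ae_architecture()")
  x <- as_measure_matrix(data, battery)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2) abort("training requires at least 2 records")
  if (k != arch$input) {
    abort(sprintf("data has %d measures but the architecture expects %d", k, arch$input))
  }
  h <- arch$hidden
  p <- arch$dropout
  keep <- 1 - p
  act <- arch$activation

  init_w <- function(fan_in, fan_out) {
    matrix(runif(fan_in * fan_out, -1, 1) / sqrt(fan_in), fan_in, fan_out)
  }
  init_b <- function(fan_in, fan_out) runif(fan_out, -1, 1) / sqrt(fan_in)

  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  loss_initial <- NA_real_
  epochs_run <- 0L

  params <- withr::with_seed(seed, {
    prm <- list(
      W1 = init_w(k, h), b1 = init_b(k, h),
      W2 = init_w(h, 1L), b2 = init_b(h, 1L),
      W3 = init_w(1L, h), b3 = init_b(1L, h),
      W4 = init_w(h, k), b4 = init_b(h, k)
    )
    mom <- lapply(prm, function(w) w * 0)
    vel <- lapply(prm, function(w) w * 0)

    loss_initial <- mean((ae_forward(prm, x, act)$xhat - x)^2)
    best <- Inf
    wait <- 0L

    for (ep in seq_len(epochs)) {
      # training forward pass (inverted dropout)
      pre1 <- add_bias(x %*% prm$W1, prm$b1)
      a1 <- act_forward(pre1, act)
      if (p > 0) {
        m1 <- matrix(rbinom(n * h, 1L, keep), n, h) / keep
        a1d <- a1 * m1
      } else a1d <- a1
      z <- add_bias(a1d %*% prm$W2, prm$b2)
      if (p > 0) {
        m2 <- matrix(rbinom(n, 1L, keep), n, 1L) / keep
        zd <- z * m2
      } else zd <- z
      pre3 <- add_bias(zd %*% prm$W3, prm$b3)
      a3 <- act_forward(pre3, act)
      xhat <- add_bias(a3 %*% prm$W4, prm$b4)

      # backprop of L = mean((xhat - x)^2)
      g_out <- 2 * (xhat - x) / (n * k)
      grads <- list()
      grads$W4 <- crossprod(a3, g_out)
      grads$b4 <- colSums(g_out)
      d_a3 <- tcrossprod(g_out, prm$W4)
      d_p3 <- d_a3 * act_deriv(pre3, a3, act)
      grads$W3 <- crossprod(zd, d_p3)
      grads$b3 <- colSums(d_p3)
      d_zd <- tcrossprod(d_p3, prm$W3)
      d_z <- if (p > 0) d_zd * m2 else d_zd
      grads$W2 <- crossprod(a1d, d_z)
      grads$b2 <- colSums(d_z)
      d_a1d <- tcrossprod(d_z, prm$W2)
      d_a1 <- if (p > 0) d_a1d * m1 else d_a1d
      d_p1 <- d_a1 * act_deriv(pre1, a1, act)
      grads$W1 <- crossprod(x, d_p1)
      grads$b1 <- colSums(d_p1)

      bc1 <- 1 - beta1^ep
      bc2 <- 1 - beta2^ep
      for (nm in names(prm)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        prm[[nm]] <- prm[[nm]] -
          learning_rate * (mom[[nm]] / bc1) / (sqrt(vel[[nm]] / bc2) + eps)
      }

      loss <- mean((ae_forward(prm, x, act)$xhat - x)^2)
      if (!is.finite(loss)) {
        abort("training diverged (non-finite loss); try a lower learning_rate")
      }
      trace[ep] <- loss
      epochs_run <- ep
      if (loss < best - min_delta) {
        best <- loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (is.finite(patience) && wait >= patience) break
      }
    }
    prm
  })

  trace <- trace[seq_len(epochs_run)]
  structure(
    list(
      parameters = params,
      architecture = arch,
      measures = colnames(x),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      epochs_run = epochs_run,
      patience = patience,
      min_delta = min_delta,
      seed = as.integer(seed),
      loss_initial = loss_initial,
      loss_final = trace[epochs_run],
      loss_trace = trace,
      n_train = n
    ),
    class = "composcore_ae"
  )
}

# Check and order the columns of scoring data against the training measures.
ae_input_matrix <- function(model, data, battery = NULL) {
  x <- as_measure_matrix(data, battery)
  if (!is.null(model$measures)) {
    if (!is.null(colnames(x))) {
      miss <- setdiff(model$measures, colnames(x))
      if (length(miss) > 0) {
        abort(paste0(
          "battery mismatch: data lacks measure(s) the model was trained on: ",
          paste(miss, collapse = ", ")
        ))
      }
      x <- x[, model$measures, drop = FALSE]
    } else if (ncol(x) != length(model$measures)) {
      abort("battery mismatch: wrong number of measure columns")
    }
  } else if (ncol(x) != model$architecture$input) {
    abort("battery mismatch: wrong number of measure columns")
  }
  x
}

#' Composite scores from a trained autoencoder
#'
#' Runs the encoder (dropout inactive) and returns the activation of the
#' single central neuron — the raw composite score, one per record.
#' Deterministic given the trained model.
#'
#' @param model A `composcore_ae` from [train_ae()].
#' @param data Standardized data with the same measures the model was
#'   trained on.
#' @param battery Optional battery restricting/ordering the columns.
#' @return A numeric vector of raw composite scores.
#' @export
encode <- function(model, data, battery = NULL) {
  if (!inherits(model, "composcore_ae")) abort("model must be a composcore_ae")
  x <- ae_input_matrix(model, data, battery)
  drop(ae_forward(model$parameters, x, model$architecture$activation)$z)
}

#' Reconstruction from a trained autoencoder
#'
#' Full dropout-free forward pass; output has the same shape as the input.
#'
#' @inheritParams encode
#' @return A records-by-measures numeric matrix of reconstructed values.
#' @export
reconstruct <- function(model, data, battery = NULL) {
  if (!inherits(model, "composcore_ae")) abort("model must be a composcore_ae")
  x <- ae_input_matrix(model, data, battery)
  xhat <- ae_forward(model$parameters, x, model$architecture$activation)$xhat
  colnames(xhat) <- colnames(x)
  xhat
}

#' Decode bottleneck scores back to measure space
#'
#' Applies the decoder half only, so `decode(model, encode(model, x))`
#' equals `reconstruct(model, x)`.
#'
#' @param model A `composcore_ae`.
#' @param scores Numeric vector of bottleneck scores.
#' @return A records-by-measures matrix.
#' @export
decode <- function(model, scores) {
  if (!inherits(model, "composcore_ae")) abort("model must be a composcore_ae")
  prm <- model$parameters
  act <- model$architecture$activation
  z <- matrix(as.numeric(scores), ncol = 1L)
  a3 <- act_forward(add_bias(z %*% prm$W3, prm$b3), act)
  xhat <- add_bias(a3 %*% prm$W4, prm$b4)
  colnames(xhat) <- model$measures
  xhat
}

#' @export
predict.composcore_ae <- function(object, newdata,
                                  type = c("score", "reconstruction"), ...) {
  type <- match.arg(type)
  if (type == "score") encode(object, newdata) else reconstruct(object, newdata)
}

#' @export
print.composcore_ae <- function(x, ...) {
  cat("<composcore_ae>\n")
  print(x$architecture)
  cat(sprintf(
    "  trained %d/%d epochs on %d records (seed %d)\n  loss %.4g -> %.4g\n",
    x$epochs_run, x$epochs, x$n_train, x$seed, x$loss_initial, x$loss_final
  ))
  invisible(x)
}

#' @describeIn train_ae Tidy the learned parameters into a long tibble
#'   (`parameter`, `row`, `col`, `value`).
#' @param x A `composcore_ae`.
#' @param ... Unused.
#' @export
tidy.composcore_ae <- function(x, ...) {
  purrr::imap_dfr(x$parameters, function(w, nm) {
    w <- as.matrix(w)
    tibble(
      parameter = nm,
      row = as.integer(base::row(w)),
      col = as.integer(base::col(w)),
      value = as.numeric(w)
    )
  })
}

#' @describeIn train_ae One-row training summary.
#' @export
glance.composcore_ae <- function(x, ...) {
  tibble(
    hidden = x$architecture$hidden,
    activation = x$architecture$activation,
    dropout = x$architecture$dropout,
    learning_rate = x$learning_rate,
    epochs_run = x$epochs_run,
    loss_initial = x$loss_initial,
    loss_final = x$loss_final,
    seed = x$seed
  )
}
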