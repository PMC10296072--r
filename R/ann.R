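#' Configuration of the pseudo-value multilayer perceptron
#'
#' A small feed-forward network regressing jackknife pseudo survival
#' probabilities on patient features: 10 predictors in, 6 outcome horizons
#' out, 3 hidden layers of 3 sigmoid units, trained for 10 epochs with
#' mini-batches of 32 at learning rate 0.02 under the adaptive-moment (Adam)
#' optimizer, mean-squared-error loss. `momentum` is recorded for
#' completeness (classical momentum is 0; Adam maintains its own moment
#' estimates).
#'
#' @param epochs training epochs.
#' @param hidden hidden layer sizes (default three layers of 3 units; use
#'   `c(3)` for the single-hidden-layer reading).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param momentum classical momentum (kept at 0).
#' @param input_dim expected number of predictors.
#' @param output_dim number of outcome horizons.
#' @param head `"conditional"` (default): the 6 sigmoid outputs are
#'   per-interval conditional survival probabilities and the marginal curve is
#'   their cumulative product, hence non-increasing. `"marginal"`: outputs are
#'   the marginal probabilities directly (no monotonicity guarantee).
#' @param seed RNG seed for weight initialization and batch order.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(epochs = 10, hidden = c(3, 3, 3), batch_size = 32,
                       learning_rate = 0.02, momentum = 0,
                       input_dim = 10, output_dim = 6,
                       head = c("conditional", "marginal"), seed = 1L) {
  head <- match.arg(head)
  stopifnot(epochs >= 1, all(hidden >= 1), batch_size >= 1,
            learning_rate > 0, input_dim >= 1, output_dim >= 1)
  structure(list(epochs = as.integer(epochs), hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 head = head, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Default horizon grid for the discrete-time survival head
#'
#' Six equally spaced horizons over (0, 1095] days: 182.5, 365, ..., 1095.
#'
#' @param horizon_days upper end of the grid (default 1095, the 3-year
#'   outcome horizon).
#' @param k number of horizons (default 6, the network's output size).
#' @return increasing numeric vector of length `k`.
#' @export
ann_horizons <- function(horizon_days = 1095, k = 6) (seq_len(k) / k) * horizon_days

#' Pseudo-value regression dataset
#'
#' Builds the feature matrix and the pseudo survival probability responses
#' ([pseudo_values()]) on a horizon grid. With no censoring the responses are
#' exactly the survival indicators \eqn{I(T_j > t)}; under censoring they may
#' leave \[0, 1\] and are deliberately not clipped.
#'
#' @param data patient-level data.frame with `time`, `event` and features
#'   (see [landmark_features()]).
#' @param horizons strictly increasing evaluation times,
#'   default [ann_horizons()].
#' @param features feature column names (default: all but bookkeeping).
#' @return list with `x` (feature matrix), `y` (pseudo-response matrix,
#'   patients x horizons), `horizons`, `features`.
#' @export
build_pseudo_dataset <- function(data, horizons = ann_horizons(), features = NULL) {
  if (is.unsorted(horizons, strictly = TRUE)) stop("horizons must be strictly increasing")
  if (nrow(data) < 2) stop("need at least 2 patients")
  if (is.null(features))
    features <- setdiff(names(data), c("id", "time", "event"))
  pv <- pseudo_values(data$time, data$event, horizons)
  list(x = as.matrix(data[features]), y = pv$values,
       horizons = horizons, features = features)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(weights, x) {
  a <- list(x)
  for (l in seq_along(weights$W))
    a[[l + 1]] <- sigmoid(sweep(a[[l]] %*% weights$W[[l]], 2, weights$b[[l]], `+`))
  a
}

# row-wise cumulative product
row_cumprod <- function(m) t(apply(m, 1, cumprod))

#' Fit the pseudo-value multilayer perceptron
#'
#' Minimizes the mean squared error between the network's predicted marginal
#' survival probabilities and the pseudo-value responses by mini-batch Adam.
#' Under the default conditional head the marginal at horizon \eqn{k} is the
#' product of the first \eqn{k} sigmoid outputs, and the gradient is
#' propagated through that product. Training is fully deterministic given the
#' config seed (weight initialization and batch order).
#'
#' @param x feature matrix (patients x `input_dim`).
#' @param y pseudo-response matrix (patients x `output_dim`).
#' @param config an [mlp_config()].
#' @return object of class `pseudo_ann`: `weights`, `loss_trace` (mean
#'   training MSE per epoch), `config`, and the feature count.
#' @export
fit_mlp <- function(x, y, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != config$input_dim)
    stop("dimension mismatch: expected ", config$input_dim, " predictors, got ", ncol(x))
  if (ncol(y) != config$output_dim)
    stop("dimension mismatch: expected ", config$output_dim, " responses, got ", ncol(y))
  if (nrow(x) != nrow(y)) stop("x and y row counts differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite training values")

  set.seed(config$seed)
  sizes <- c(config$input_dim, config$hidden, config$output_dim)
  L <- length(sizes) - 1
  weights <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    weights$W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r), sizes[l], sizes[l + 1])
    weights$b[[l]] <- numeric(sizes[l + 1])
  }
  mW <- lapply(weights$W, function(w) w * 0); vW <- mW
  mb <- lapply(weights$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(x)
  loss_trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      xb <- x[bt, , drop = FALSE]; yb <- y[bt, , drop = FALSE]
      a <- mlp_forward(weights, xb)
      o <- a[[L + 1]]
      if (config$head == "conditional") {
        m <- row_cumprod(o)
        resid <- m - yb
        # dL/do_j = sum_{k >= j} dL/dm_k * m_k / o_j
        g <- resid * m
        grad_o <- t(apply(g, 1, function(r) rev(cumsum(rev(r))))) / o
        grad_o <- 2 * grad_o / length(yb)
      } else {
        m <- o
        grad_o <- 2 * (o - yb) / length(yb)
      }
      ep_loss <- ep_loss + sum((m - yb)^2)
      if (any(!is.finite(grad_o))) stop("non-finite loss gradient; aborting training")

      delta <- grad_o * o * (1 - o)
      for (l in L:1) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(weights$W[[l]])) * a[[l]] * (1 - a[[l]])
        step_l <- step  # same Adam step count for every layer in this batch
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        mhatW <- mW[[l]] / (1 - b1^(step_l + 1)); vhatW <- vW[[l]] / (1 - b2^(step_l + 1))
        mhatb <- mb[[l]] / (1 - b1^(step_l + 1)); vhatb <- vb[[l]] / (1 - b2^(step_l + 1))
        weights$W[[l]] <- weights$W[[l]] - config$learning_rate * mhatW / (sqrt(vhatW) + eps)
        weights$b[[l]] <- weights$b[[l]] - config$learning_rate * mhatb / (sqrt(vhatb) + eps)
      }
      step <- step + 1
    }
    loss_trace[ep] <- ep_loss / (n * config$output_dim)
  }

  structure(list(weights = weights, loss_trace = loss_trace, config = config,
                 n_features = ncol(x)),
            class = "pseudo_ann")
}

#' @export
print.pseudo_ann <- function(x, ...) {
  cfg <- x$config
  cat("Pseudo-value MLP:", cfg$input_dim, "->",
      paste(cfg$hidden, collapse = "-"), "->", cfg$output_dim,
      "(", cfg$head, "head )\n")
  cat("training MSE by epoch:", paste(signif(x$loss_trace, 4), collapse = " "), "\n")
  invisible(x)
}

#' Predicted marginal survival from the pseudo-value MLP
#'
#' Under the conditional head the marginal survival at horizon \eqn{k} is the
#' cumulative product of the first \eqn{k} per-interval conditional outputs,
#' hence non-increasing and in (0, 1\].
#'
#' @param fit a `pseudo_ann`.
#' @param x feature matrix or data.frame with the training features.
#' @param horizons optional horizon grid, used to label a single-patient
#'   `survcurve` return.
#' @return matrix (patients x horizons) of marginal survival probabilities,
#'   or a `survcurve` for a single patient when `horizons` is supplied.
#' @export
predict_survival_ann <- function(fit, x, horizons = NULL) {
  stopifnot(inherits(fit, "pseudo_ann"))
  x <- as.matrix(x)
  if (ncol(x) != fit$config$input_dim) stop("feature mismatch")
  o <- mlp_forward(fit$weights, x)[[length(fit$weights$W) + 1]]
  m <- if (fit$config$head == "conditional") row_cumprod(o) else o
  if (nrow(m) == 1 && !is.null(horizons)) return(new_survcurve(horizons, drop(m)))
  m
}
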