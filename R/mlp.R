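#' Multilayer perceptron classifier (one ReLU hidden layer)
#'
#' Minimal MLP matching the decoder used throughout the analysis: one hidden
#' layer of 100 rectified-linear units, softmax readout trained with
#' cross-entropy by Adam at a constant step size of 0.001, for at most 200
#' iterations or until the loss stops improving (tolerance 1e-4 over 10
#' consecutive iterations). Weights use Glorot-uniform initialization; a
#' small L2 penalty (1e-4) stabilizes the overparameterized fits.
#'
#' @param x numeric feature matrix (samples x features)
#' @param y class labels (factor or coercible)
#' @param hidden hidden-layer width (default 100)
#' @param learning_rate Adam step size (default 0.001)
#' @param max_iter maximum full-batch iterations (default 200)
#' @param tol convergence tolerance on the loss (default 1e-4)
#' @param n_iter_no_change iterations without `tol` improvement before
#'   stopping (default 10)
#' @param alpha L2 penalty (default 1e-4)
#' @param seed integer seed for weight initialization
#' @return object of class `mlp_classifier`
#' @export
mlp_fit <- function(x, y, hidden = 100L, learning_rate = 0.001,
                    max_iter = 200L, tol = 1e-4, n_iter_no_change = 10L,
                    alpha = 1e-4, seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 1)) stop("every class needs at least one sample")
  n <- nrow(x)
  d <- ncol(x)
  k <- nlevels(y)
  yi <- matrix(0, n, k)
  yi[cbind(seq_len(n), as.integer(y))] <- 1

  if (!is.null(seed)) set.seed(seed)
  glorot <- function(fan_in, fan_out) {
    b <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * fan_out, -b, b), fan_in, fan_out)
  }
  W1 <- glorot(d, hidden); b1 <- numeric(hidden)
  W2 <- glorot(hidden, k); b2 <- numeric(k)

  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  step <- function(s, g, t) {
    s$m <- b1a * s$m + (1 - b1a) * g
    s$v <- b2a * s$v + (1 - b2a) * g^2
    mhat <- s$m / (1 - b1a^t)
    vhat <- s$v / (1 - b2a^t)
    list(state = s, delta = learning_rate * mhat / (sqrt(vhat) + eps))
  }

  best <- Inf; stall <- 0L; n_iter <- 0L
  for (it in seq_len(max_iter)) {
    h <- pmax(x %*% W1 + rep(b1, each = n), 0)          # ReLU
    z <- h %*% W2 + rep(b2, each = n)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    p <- ez / rowSums(ez)                                # softmax
    loss <- -mean(log(pmax(p[yi == 1], 1e-12))) +
      alpha / (2 * n) * (sum(W1^2) + sum(W2^2))
    dz <- (p - yi) / n
    gW2 <- crossprod(h, dz) + alpha / n * W2
    gb2 <- colSums(dz)
    dh <- dz %*% t(W2)
    dh[h <= 0] <- 0
    gW1 <- crossprod(x, dh) + alpha / n * W1
    gb1 <- colSums(dh)
    u <- step(st$W1, gW1, it); st$W1 <- u$state; W1 <- W1 - u$delta
    u <- step(st$b1, gb1, it); st$b1 <- u$state; b1 <- b1 - u$delta
    u <- step(st$W2, gW2, it); st$W2 <- u$state; W2 <- W2 - u$delta
    u <- step(st$b2, gb2, it); st$b2 <- u$state; b2 <- b2 - u$delta
    n_iter <- it
    if (loss > best - tol) stall <- stall + 1L else stall <- 0L
    if (loss < best) best <- loss
    if (stall >= n_iter_no_change) break
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y),
                 n_iter = n_iter, loss = best),
            class = "mlp_classifier")
}

#' Predict classes with a fitted [mlp_fit()] model
#' @param object an `mlp_classifier`
#' @param newdata feature matrix
#' @param ... unused
#' @return factor of predicted labels
#' @export
predict.mlp_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  n <- nrow(x)
  h <- pmax(x %*% object$W1 + rep(object$b1, each = n), 0)
  z <- h %*% object$W2 + rep(object$b2, each = n)
  factor(object$levels[max.col(z, ties.method = "first")],
         levels = object$levels)
}
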