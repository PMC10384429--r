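## Baseline estimators: ordinary least squares on the a/b chromaticity ratio,
## and a small feed-forward network (sigmoid hidden layer, linear output)
## trained full-batch by Levenberg-Marquardt on the residual Jacobian.

#' Fit the linear a/b-ratio baseline
#'
#' Ordinary least squares of lycopene (ppm) on the a/b chromaticity ratio.
#'
#' @param ratios numeric vector of a/b ratios.
#' @param y numeric vector of lycopene values (ppm), same length.
#' @return a \code{LinearABModel}.
#' @export
fitLinearAB <- function(ratios, y) {
  ratios <- as.numeric(ratios); y <- as.numeric(y)
  stopifnot(length(ratios) == length(y), length(y) >= 2L)
  if (length(unique(ratios)) < 2L)
    stop("degenerate design: all ratio values identical")
  fit <- lm.fit(cbind(intercept = 1, slope = ratios), y)
  new("LinearABModel", slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]))
}

#' @rdname fitLinearAB
#' @param object a \code{LinearABModel}.
#' @param newdata numeric vector of ratios, or a data.frame carrying the
#'   model's input column (default \code{ratio_ab}).
#' @param ... ignored.
#' @export
setMethod("predict", "LinearABModel", function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata[[object@inputNames[1]]]
  object@intercept + object@slope * as.numeric(newdata)
})

setMethod("show", "LinearABModel", function(object) {
  cat(sprintf("LinearABModel: ppm = %.6g + %.6g * (a/b)\n",
              object@intercept, object@slope))
})

sigmoid <- function(z) 1 / (1 + exp(-z))

## forward pass on standardized inputs; returns list(yhat, H)
.mlpForward <- function(W1, b1, W2, b2, Xs) {
  H <- sigmoid(Xs %*% t(W1) + matrix(b1, nrow(Xs), length(b1), byrow = TRUE))
  list(yhat = as.vector(H %*% t(W2)) + b2, H = H)
}

## pack/unpack parameter vector theta = (W1, b1, W2, b2)
.mlpUnpack <- function(theta, h, p) {
  list(W1 = matrix(theta[seq_len(h * p)], h, p),
       b1 = theta[h * p + seq_len(h)],
       W2 = matrix(theta[h * p + h + seq_len(h)], 1, h),
       b2 = theta[h * p + 2 * h + 1])
}

#' Train the feed-forward network baseline by Levenberg-Marquardt
#'
#' Architecture: \code{hiddenUnits} sigmoid hidden neurons and one linear
#' output. Inputs are z-scored internally; weights are initialized uniformly
#' in [-0.5, 0.5] from the seeded generator. Each epoch computes the analytic
#' residual Jacobian and takes one accepted damped Gauss-Newton step: the
#' damping factor lambda is multiplied by \code{lambdaFactor} on a rejected
#' trial and divided by it on acceptance, so the accepted-step training MSE
#' sequence is non-increasing by construction.
#'
#' @param X numeric matrix (or data.frame) of inputs, one row per sample.
#' @param y numeric vector of targets (ppm).
#' @param hiddenUnits hidden layer width (default 10).
#' @param epochs number of accepted LM steps (default 10); 0 returns the
#'   initialized network untrained.
#' @param seed RNG seed for weight initialization.
#' @param lambdaInit,lambdaFactor Marquardt damping schedule (defaults 1e-3
#'   and 10).
#' @param maxReject inner-loop cap on consecutive rejected trials per epoch;
#'   when reached, training stops early and the best-so-far network is
#'   returned (not an error).
#' @return an \code{MLPModel} with the accepted-step MSE trace in
#'   \code{lossTrace} (element 1 is the MSE at initialization).
#' @export
trainMLP <- function(X, y, hiddenUnits = 10L, epochs = 10L, seed = 1L,
                     lambdaInit = 1e-3, lambdaFactor = 10, maxReject = 30L) {
  inputNames <- if (is.data.frame(X)) names(X) else
    (if (!is.null(colnames(X))) colnames(X) else
       paste0("x", seq_len(ncol(as.matrix(X)))))
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X); h <- as.integer(hiddenUnits); n <- nrow(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)[, , drop = FALSE]

  rng <- local({ set.seed(seed); runif(h * p + 2 * h + 1, -0.5, 0.5) })
  theta <- rng
  np <- length(theta)

  mse <- function(th) {
    w <- .mlpUnpack(th, h, p)
    r <- .mlpForward(w$W1, w$b1, w$W2, w$b2, Xs)$yhat - y
    mean(r^2)
  }
  jacres <- function(th) {
    w <- .mlpUnpack(th, h, p)
    fw <- .mlpForward(w$W1, w$b1, w$W2, w$b2, Xs)
    Hm <- fw$H                                   # n x h
    dH <- Hm * (1 - Hm)                          # sigmoid derivative
    G <- dH * matrix(w$W2, n, h, byrow = TRUE)   # n x h, dyhat/da_k
    J <- matrix(0, n, np)
    for (j in seq_len(p))                        # dyhat/dW1[k, j] = G_k x_j
      J[, (j - 1L) * h + seq_len(h)] <- G * Xs[, j]   # column-major W1 layout
    J[, h * p + seq_len(h)] <- G                 # dyhat/db1
    J[, h * p + h + seq_len(h)] <- Hm            # dyhat/dW2
    J[, np] <- 1                                 # dyhat/db2
    list(J = J, r = fw$yhat - y)
  }

  lossTrace <- mse(theta)
  if (!is.finite(lossTrace)) stop("non-finite loss at initialization")
  # one damped trial step: NULL unless it strictly improves on `cur`
  tryStep <- function(Hss, g, lam, cur) {
    step <- tryCatch(solve(Hss + diag(lam, np), g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    cand <- theta - as.vector(step)
    candLoss <- mse(cand)
    if (!is.finite(candLoss))
      stop("non-finite loss during training (lambda = ", lam, ")")
    if (candLoss < cur) list(theta = cand, loss = candLoss) else NULL
  }
  lambda <- lambdaInit
  epoch <- 0L
  while (epoch < epochs) {
    jr <- jacres(theta)
    g <- crossprod(jr$J, jr$r)
    Hss <- crossprod(jr$J)
    cur <- mean(jr$r^2)
    # classic Marquardt order: relax the damping first, then hold, then
    # inflate until a strictly improving step is found
    hit <- tryStep(Hss, g, lambda / lambdaFactor, cur)
    if (!is.null(hit)) {
      lambda <- lambda / lambdaFactor
    } else {
      for (trial in seq_len(maxReject)) {
        hit <- tryStep(Hss, g, lambda, cur)
        if (!is.null(hit)) break
        lambda <- lambda * lambdaFactor
      }
    }
    if (is.null(hit)) break   # cannot improve further; return best-so-far
    theta <- hit$theta
    lossTrace <- c(lossTrace, hit$loss)
    epoch <- epoch + 1L
  }

  w <- .mlpUnpack(theta, h, p)
  new("MLPModel", W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
      center = unname(ctr), scale = unname(scl), lossTrace = lossTrace,
      inputNames = inputNames, seed = as.integer(seed))
}

#' Forward pass of the network baseline
#'
#' @param object an \code{MLPModel}.
#' @param newdata matrix or data.frame with one row per sample; data.frames
#'   may carry the model's \code{inputNames} columns.
#' @param ... ignored.
#' @return numeric vector of predictions (ppm).
#' @export
setMethod("predict", "MLPModel", function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    nm <- object@inputNames
    if (all(nm %in% names(newdata))) newdata <- newdata[, nm, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = ncol(object@W1), byrow = TRUE)
  if (ncol(newdata) != ncol(object@W1))
    stop("expected ", ncol(object@W1), " input columns, got ", ncol(newdata))
  storage.mode(newdata) <- "double"
  Xs <- scale(newdata, center = object@center, scale = object@scale)
  .mlpForward(object@W1, object@b1, object@W2, object@b2, Xs)$yhat
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf(
    "MLPModel: %d -> %d sigmoid -> 1 linear; %d accepted LM step(s), final MSE %.4g\n",
    ncol(object@W1), nrow(object@W1), length(object@lossTrace) - 1L,
    utils::tail(object@lossTrace, 1)))
})
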