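#' Meta-model configuration
#'
#' Defaults follow the regime the meta-learner is insensitive to: sigmoid
#' hidden activation, Adam with learning rate 0.001, mini-batches of about 50,
#' 400 epochs, and a hidden layer wider than the input (2 x the number of base
#' models unless overridden). The loss is fixed to MSE.
#'
#' @param nHidden hidden-layer width; `NULL` (default) means twice the input
#'   width, and values below the input width are rejected at training time.
#' @param activation `"SIGMOID"` (default) or `"RELU"`.
#' @param optimizer `"ADAM"` (default), `"SGD"`, `"RMSPROP"` or `"ADAGRAD"`.
#' @param learningRate step size, default 0.001.
#' @param batchSize mini-batch size, default 50 (clipped to n).
#' @param epochs training epochs, default 400.
#' @param seed RNG seed for initialization and shuffling.
#' @return a list of class `MetaConfig`.
#' @export
metaConfig <- function(nHidden = NULL, activation = c("SIGMOID", "RELU"),
                       optimizer = c("ADAM", "SGD", "RMSPROP", "ADAGRAD"),
                       learningRate = 0.001, batchSize = 50L, epochs = 400L,
                       seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (epochs < 1L || batchSize < 1L) stop("epochs and batchSize must be >= 1")
  structure(list(nHidden = nHidden, activation = activation,
                 optimizer = optimizer, learningRate = learningRate,
                 batchSize = as.integer(batchSize), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "MetaConfig")
}

.actFun <- function(x, kind) {
  if (kind == "SIGMOID") 1 / (1 + exp(-x)) else pmax(x, 0)
}
.actGrad <- function(h, kind) {
  if (kind == "SIGMOID") h * (1 - h) else (h > 0) + 0
}

#' Train the single-hidden-layer perceptron meta-model
#'
#' Mini-batch gradient descent on the MSE loss with per-epoch seeded
#' shuffling. Implemented as a minimal self-contained network (Adam with
#' beta1 = 0.9, beta2 = 0.999, eps = 1e-8) so training is deterministic under
#' the configured seed. Inputs are not re-standardized: base-model predictions
#' already live on the standardized-phenotype scale.
#'
#' @param features n x s numeric matrix of base-model predictions.
#' @param targets numeric vector of length n (training phenotypes).
#' @param cfg a [metaConfig] object.
#' @return a [MetaModel-class] with the per-epoch loss curve recorded.
#' @export
trainMLP <- function(features, targets, cfg = metaConfig()) {
  X <- as.matrix(features)
  yv <- as.numeric(targets)
  if (nrow(X) != length(yv)) stop("features and targets disagree in length")
  if (any(!is.finite(X)) || any(!is.finite(yv)))
    stop("non-finite entries in the meta-model inputs")
  n <- nrow(X); s <- ncol(X)
  nh <- if (is.null(cfg$nHidden)) 2L * s else as.integer(cfg$nHidden)
  if (nh < s) stop("the hidden layer must be at least as wide as the input")
  bs <- min(cfg$batchSize, n)
  set.seed(cfg$seed)
  lim1 <- sqrt(6 / (s + nh)); lim2 <- sqrt(6 / (nh + 1))
  W1 <- matrix(stats::runif(s * nh, -lim1, lim1), s, nh)
  b1 <- rep(0, nh)
  W2 <- matrix(stats::runif(nh, -lim2, lim2), nh, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mState <- lapply(params, function(p) p * 0)
  vState <- mState
  lr <- cfg$learningRate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lossCurve <- numeric(cfg$epochs)

  forward <- function(Xb) {
    H <- .actFun(sweep(Xb %*% params$W1, 2L, params$b1, "+"), cfg$activation)
    list(H = H, yhat = drop(H %*% params$W2) + params$b2)
  }
  applyGrad <- function(g) {
    step <<- step + 1L
    for (nm in names(params)) {
      if (cfg$optimizer == "SGD") {
        params[[nm]] <<- params[[nm]] - lr * g[[nm]]
      } else if (cfg$optimizer == "ADAGRAD") {
        vState[[nm]] <<- vState[[nm]] + g[[nm]]^2
        params[[nm]] <<- params[[nm]] - lr * g[[nm]] / (sqrt(vState[[nm]]) + eps)
      } else if (cfg$optimizer == "RMSPROP") {
        vState[[nm]] <<- 0.9 * vState[[nm]] + 0.1 * g[[nm]]^2
        params[[nm]] <<- params[[nm]] - lr * g[[nm]] / (sqrt(vState[[nm]]) + eps)
      } else {
        mState[[nm]] <<- beta1 * mState[[nm]] + (1 - beta1) * g[[nm]]
        vState[[nm]] <<- beta2 * vState[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- mState[[nm]] / (1 - beta1^step)
        vh <- vState[[nm]] / (1 - beta2^step)
        params[[nm]] <<- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }

  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- yv[idx]
      fw <- forward(Xb)
      d <- 2 * (fw$yhat - yb) / length(yb)            # dL/dyhat
      gW2 <- crossprod(fw$H, d)
      gb2 <- sum(d)
      dH <- (d %*% t(params$W2)) * .actGrad(fw$H, cfg$activation)
      gW1 <- crossprod(Xb, dH)
      gb1 <- colSums(dH)
      if (!all(is.finite(gW1)) || !all(is.finite(gW2)))
        stop("non-finite loss gradient at epoch ", ep)
      applyGrad(list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
    }
    lossCurve[ep] <- mean((forward(X)$yhat - yv)^2)
    if (!is.finite(lossCurve[ep]))
      stop("non-finite training loss at epoch ", ep)
  }

  new("MetaModel", W1 = params$W1, b1 = params$b1, W2 = params$W2,
      b2 = params$b2, lossCurve = lossCurve,
      config = utils::modifyList(unclass(cfg), list(nHidden = nh)))
}

#' Deterministic forward pass of the meta-model
#'
#' @param object a [MetaModel-class].
#' @param features m x s matrix with the training feature count.
#' @param ... ignored.
#' @return numeric vector of m predictions.
#' @export
setMethod("predict", "MetaModel", function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != nrow(object@W1))
    stop(sprintf("feature count %d does not match the trained input width %d",
                 ncol(X), nrow(object@W1)))
  H <- .actFun(sweep(X %*% object@W1, 2L, object@b1, "+"),
               object@config$activation)
  drop(H %*% object@W2) + object@b2
})
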