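## Two-layer feedforward classifier: tanh hidden layer, two softmax output
## units read as posterior-like class scores, trained full-batch by
## resilient backpropagation (iRPROP-) against a mean-squared-error loss,
## with validation-based early stopping that returns the weights at the
## minimum validation error.

#' Build a network configuration
#'
#' @param hiddenUnits tanh hidden units (default 10).
#' @param maxEpochs epoch cap (default 10000).
#' @param goalMse training MSE at which training stops (default 1e-5).
#' @param patience consecutive validation-error increases tolerated before
#'   stopping (default 6).
#' @param seed integer seed for the weight initializer.
#' @return An [AnnConfig-class].
#' @export
annConfig <- function(hiddenUnits = 10L, maxEpochs = 10000L, goalMse = 1e-5,
                      patience = 6L, seed = 1L) {
  new("AnnConfig", hiddenUnits = as.integer(hiddenUnits),
      maxEpochs = as.integer(maxEpochs), goalMse = goalMse,
      patience = as.integer(patience), seed = as.integer(seed))
}

## One-hot targets, TD = column 1, ASD = column 2.
.targets <- function(y) {
  stopifnot(all(y %in% c("TD", "ASD")))
  rbind(TD = as.numeric(y == "TD"), ASD = as.numeric(y == "ASD"))
}

## Forward pass: X is features x n; returns list(H, Y) with Y 2 x n softmax.
.forward <- function(w, X) {
  H <- tanh(w$W1 %*% X + w$b1)
  Z <- w$W2 %*% H + w$b2
  Z <- sweep(Z, 2L, apply(Z, 2L, max))   # stabilized softmax
  E <- exp(Z)
  list(H = H, Y = sweep(E, 2L, colSums(E), "/"))
}

.mse <- function(Y, Tg) mean((Y - Tg)^2)

## Flatten / unflatten weights for the elementwise RPROP update.
.wvec <- function(w) c(w$W1, w$b1, w$W2, w$b2)
.wunvec <- function(v, dims) {
  i <- 0
  take <- function(n) { out <- v[(i + 1):(i + n)]; i <<- i + n; out }
  list(W1 = matrix(take(prod(dims$W1)), dims$W1[1], dims$W1[2]),
       b1 = take(dims$b1),
       W2 = matrix(take(prod(dims$W2)), dims$W2[1], dims$W2[2]),
       b2 = take(dims$b2))
}

## Gradient of the MSE loss through softmax and tanh; all full-batch.
.gradient <- function(w, X, Tg) {
  fw <- .forward(w, X)
  n <- ncol(X)
  dY <- 2 * (fw$Y - Tg) / (2 * n)
  s <- colSums(dY * fw$Y)
  dZ <- fw$Y * sweep(dY, 2L, s)          # softmax backprop
  dW2 <- dZ %*% t(fw$H)
  db2 <- rowSums(dZ)
  dH <- t(w$W2) %*% dZ
  dA <- dH * (1 - fw$H^2)
  list(grad = c(dA %*% t(X), rowSums(dA), dW2, db2),
       mse = .mse(fw$Y, Tg))
}

#' Train the network with early stopping
#'
#' Full-batch resilient backpropagation on the training set; after every
#' epoch the validation MSE is evaluated. Training stops at the epoch cap,
#' at the training-MSE goal, or once the validation error has increased
#' `patience` consecutive times since its minimum; the weights at the
#' minimum validation error are returned regardless of where training
#' stopped. Identical seed, data and configuration give identical weights.
#'
#' @param xTrain,xVal numeric matrices, subjects x features, equal feature
#'   counts.
#' @param yTrain,yVal labels in \{"TD", "ASD"\}; both classes must appear in
#'   \code{yTrain}.
#' @param cfg an [AnnConfig-class].
#' @return A [TrainedModel-class].
#' @export
trainAnn <- function(xTrain, yTrain, xVal, yVal, cfg = annConfig()) {
  xTrain <- as.matrix(xTrain); xVal <- as.matrix(xVal)
  if (ncol(xTrain) == 0L)
    stop("no features to train on (empty selection)")
  if (ncol(xTrain) != ncol(xVal))
    stop("training and validation feature counts differ")
  if (anyNA(xTrain) || anyNA(xVal)) stop("NaN/NA in inputs")
  if (!all(c("TD", "ASD") %in% yTrain))
    stop("both classes must be present in the training labels")
  d <- ncol(xTrain); h <- cfg@hiddenUnits
  Xt <- t(xTrain); Xv <- t(xVal)
  Tt <- .targets(yTrain); Tv <- .targets(yVal)
  dims <- list(W1 = c(h, d), b1 = h, W2 = c(2L, h), b2 = 2L)
  npar <- h * d + h + 2L * h + 2L
  w <- withLocalSeed(cfg@seed, {
    r <- 1 / sqrt(d)
    .wunvec(stats::runif(npar, -r, r), dims)
  })
  ## iRPROP- state
  delta <- rep(0.01, npar)
  gPrev <- rep(0, npar)
  v <- .wvec(w)
  trainTrace <- valTrace <- numeric(0)
  bestVal <- Inf; bestV <- v; bestEpoch <- 0L; fails <- 0L
  epoch <- 0L
  while (epoch < cfg@maxEpochs) {
    epoch <- epoch + 1L
    g <- .gradient(w, Xt, Tt)
    sgn <- g$grad * gPrev
    delta <- ifelse(sgn > 0, pmin(delta * 1.2, 1),
                    ifelse(sgn < 0, pmax(delta * 0.5, 1e-9), delta))
    grad <- ifelse(sgn < 0, 0, g$grad)   # iRPROP-: drop reversed gradients
    v <- v - sign(grad) * delta
    gPrev <- grad
    w <- .wunvec(v, dims)
    valMse <- .mse(.forward(w, Xv)$Y, Tv)
    trainTrace[epoch] <- g$mse
    valTrace[epoch] <- valMse
    if (valMse < bestVal) {
      bestVal <- valMse; bestV <- v; bestEpoch <- epoch; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg@patience) break
    }
    if (g$mse <= cfg@goalMse) break
  }
  new("TrainedModel", weights = .wunvec(bestV, dims),
      trace = list(epochs = epoch, trainMse = trainTrace,
                   valMse = valTrace, bestEpoch = bestEpoch,
                   bestValMse = bestVal),
      config = cfg)
}

#' Posterior-like class scores
#'
#' @param model a [TrainedModel-class].
#' @param x subjects x features matrix with the training feature count.
#' @param subjects optional subject identifiers for the output rows.
#' @return data.frame with columns \code{subject}, \code{pTD}, \code{pASD};
#'   each row sums to 1.
#' @export
predictScores <- function(model, x, subjects = NULL) {
  x <- as.matrix(x)
  d <- ncol(model@weights$W1)   # W1 is h x d
  if (ncol(x) != d)
    stop("feature count (", ncol(x), ") does not match training (", d, ")")
  Y <- .forward(model@weights, t(x))$Y   # row 1 = TD, row 2 = ASD
  if (is.null(subjects)) subjects <- rownames(x)
  if (is.null(subjects)) subjects <- sprintf("row%03d", seq_len(nrow(x)))
  data.frame(subject = subjects, pTD = Y[1L, ], pASD = Y[2L, ],
             row.names = NULL)
}

#' Hard labels from scores
#'
#' A subject is called ASD iff its ASD score is at least 0.5 (the tie at
#' exactly 0.5 goes to ASD).
#'
#' @param scores data.frame with a \code{pASD} column (from
#'   [predictScores()] or a fused score table).
#' @return Character vector of labels.
#' @export
predictLabels <- function(scores) {
  ifelse(scores$pASD >= 0.5, "ASD", "TD")
}

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", ncol(object@weights$W1), "inputs ->",
      nrow(object@weights$W1), "tanh ->", "2 softmax;",
      object@trace$epochs, "epochs, best validation MSE",
      format(object@trace$bestValMse, digits = 4), "at epoch",
      object@trace$bestEpoch, "\n")
})

#' Digest of a model's weights
#'
#' Stable hash of the returned weight vectors, used by leakage and
#' determinism checks.
#' @param model a [TrainedModel-class].
#' @export
modelDigest <- function(model) objectDigest(.wvec(model@weights))
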