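# Classifier backend contract
#
# fit_backend(model, x, y, settings, seed) fits one of the interchangeable
# classifiers on a numeric feature matrix `x` and integer class labels `y`
# (any subset of {0,1} or {0,1,2,3}; at least two distinct classes). The
# returned object records the observed class set; predict_proba() returns an
# n x length(classes) probability matrix over exactly those classes, each row
# non-negative and summing to 1, deterministic given the seed. Classes absent
# from training receive probability 0 when the matrix is later expanded to the
# full class set (see expand_proba()).

backend_names <- c("logistic", "adaboost", "xgboost")

#' Fit a classifier backend
#'
#' Backends are deliberately thin wrappers with fixed, recorded defaults:
#' \describe{
#'   \item{logistic}{multinomial logistic regression via [nnet::multinom()]
#'     (no penalty, iteration cap 1000).}
#'   \item{adaboost}{SAMME boosting of exact weighted decision stumps,
#'     100 rounds; class probabilities are the normalized weighted vote
#'     shares.}
#'   \item{xgboost}{gradient boosted trees via [xgboost::xgb.train()],
#'     100 rounds, depth 6, learning rate 0.3, `binary:logistic` or
#'     `multi:softprob` according to the number of classes, single thread.}
#' }
#'
#' @param model one of `"logistic"`, `"adaboost"`, `"xgboost"`.
#' @param x numeric feature matrix (rows = observations).
#' @param y integer class labels, at least two distinct values.
#' @param settings named list overriding backend defaults (e.g. `nrounds`,
#'   `max_depth`, `eta`, `maxit`).
#' @param seed integer seed; fits are deterministic given it.
#' @return Object of class `sc_backend` carrying the fit and its class set.
#' @seealso [predict_proba()]
#' @export
fit_backend <- function(model = backend_names, x, y, settings = list(), seed = 1) {
  model <- match.arg(model)
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2) {
    stop("degenerate training data: only one class present", call. = FALSE)
  }
  x <- as.matrix(x)
  fit <- with_seed(seed, switch(model,
    logistic = fit_logistic(x, y, classes, settings),
    adaboost = fit_adaboost(x, y, classes, settings),
    xgboost  = fit_xgb(x, y, classes, settings)
  ))
  structure(list(model = model, fit = fit, classes = classes,
                 n_features = ncol(x), settings = settings),
            class = c(paste0("sc_backend_", model), "sc_backend"))
}

#' Class-probability predictions from a fitted backend
#'
#' @param object an `sc_backend` from [fit_backend()].
#' @param x numeric feature matrix.
#' @return Matrix `nrow(x)` x `length(object$classes)`; columns named by
#'   class, rows summing to 1.
#' @export
predict_proba <- function(object, x) UseMethod("predict_proba")

feature_frame <- function(x) {
  x <- as.matrix(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df
}

# ---- logistic (nnet::multinom) ----------------------------------------------

fit_logistic <- function(x, y, classes, settings) {
  df <- feature_frame(x)
  df$.y <- factor(y, levels = classes)
  maxit <- settings$maxit %||% 1000
  utils::capture.output(
    fit <- nnet::multinom(.y ~ ., data = df, maxit = maxit, trace = FALSE,
                          MaxNWts = 10000)
  )
  fit
}

#' @export
predict_proba.sc_backend_logistic <- function(object, x) {
  p <- stats::predict(object$fit, newdata = feature_frame(x), type = "probs")
  if (is.null(dim(p))) {  # two classes: vector of P(second level)
    p <- cbind(1 - p, p)
  }
  p <- matrix(as.numeric(p), nrow = nrow(as.matrix(x)))
  colnames(p) <- object$classes
  p
}

# ---- AdaBoost (SAMME over decision stumps) ----------------------------------
# No boosting package is assumed; both the SAMME weighting scheme and the
# weighted stump search are implemented directly. Stumps are found by an exact
# sweep over all split points: feature sort orders are computed once per fit
# and every round reduces to cumulative weighted class counts, which keeps a
# 100-round fit at millisecond scale. Probabilities are normalized weighted
# vote shares, which sum to 1 by construction.

# Stump objects come from the compiled exact search (src/stump.cpp);
# `feature = 0` marks the no-split majority stump.
stump_predict <- function(stump, x) {
  if (stump$feature == 0L) return(rep(stump$left, nrow(x)))
  ifelse(x[, stump$feature] <= stump$threshold, stump$left, stump$right)
}

fit_adaboost <- function(x, y, classes, settings) {
  nrounds <- settings$nrounds %||% 100
  n <- nrow(x)
  k <- length(classes)
  y_idx <- match(as.integer(y), classes)
  w <- rep(1 / n, n)
  ord <- vapply(seq_len(ncol(x)), function(j) order(x[, j]), integer(n))
  xs <- vapply(seq_len(ncol(x)), function(j) x[ord[, j], j], numeric(n))
  stumps <- vector("list", nrounds)
  alphas <- numeric(nrounds)
  used <- 0
  for (r in seq_len(nrounds)) {
    stump <- .stump_search(ord, xs, y_idx, w, k)
    pred <- stump_predict(stump, x)
    err <- sum(w[pred != y_idx])
    if (err <= 1e-10) {
      # perfect stump: give it a large but finite weight and stop
      used <- used + 1
      stumps[[used]] <- stump
      alphas[used] <- log((1 - 1e-10) / 1e-10) + log(k - 1)
      break
    }
    if (err >= 1 - 1 / k) break  # no better than chance: stop boosting
    used <- used + 1
    stumps[[used]] <- stump
    alphas[used] <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alphas[used] * (pred != y_idx))
    w <- w / sum(w)
  }
  prior <- vapply(seq_len(k), function(c) mean(y_idx == c), numeric(1))
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       classes = classes, prior = prior)
}

#' @export
predict_proba.sc_backend_adaboost <- function(object, x) {
  fit <- object$fit
  x <- as.matrix(x)
  k <- length(fit$classes)
  if (length(fit$stumps) == 0) {
    return(matrix(fit$prior, nrow(x), k, byrow = TRUE,
                  dimnames = list(NULL, fit$classes)))
  }
  votes <- matrix(0, nrow(x), k, dimnames = list(NULL, fit$classes))
  for (r in seq_along(fit$stumps)) {
    pred <- stump_predict(fit$stumps[[r]], x)
    idx <- cbind(seq_len(nrow(x)), pred)
    votes[idx] <- votes[idx] + fit$alphas[r]
  }
  votes / sum(fit$alphas)
}

# ---- XGBoost ----------------------------------------------------------------

fit_xgb <- function(x, y, classes, settings) {
  k <- length(classes)
  label <- match(as.integer(y), classes) - 1L
  params <- list(max_depth = settings$max_depth %||% 6,
                 eta = settings$eta %||% 0.3,
                 nthread = 1)
  if (k == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- k
  }
  xgboost::xgb.train(params,
                     xgboost::xgb.DMatrix(x, label = label, nthread = 1),
                     nrounds = settings$nrounds %||% 100, verbose = 0)
}

#' @export
predict_proba.sc_backend_xgboost <- function(object, x) {
  x <- as.matrix(x)
  p <- stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # binary: vector of P(class 2)
  p <- matrix(as.numeric(p), nrow = nrow(x))
  colnames(p) <- object$classes
  p
}

# Expand a probability matrix over observed classes to the full class set,
# filling absent classes with exact zeros, and renormalise rows to absorb
# float32 round-off from the backends.
expand_proba <- function(p, classes, full_classes) {
  out <- matrix(0, nrow(p), length(full_classes),
                dimnames = list(NULL, full_classes))
  out[, match(classes, full_classes)] <- p
  out / rowSums(out)
}
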