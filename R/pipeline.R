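#' Forecast configuration
#'
#' Bundles and validates the knobs of one forecasting cell: how far ahead to
#' predict, which response encoding to use, which classifier backend, and the
#' chronological train fraction.
#'
#' @param gap positive integer; the state is forecast `gap` grid steps ahead
#'   (the study grid is \{1, 5, 10, 20\}).
#' @param mode `"original"` (raw 0/1 target) or `"transformed"` (four-class
#'   transition target, decoded back to 0/1 for evaluation).
#' @param model backend name: `"logistic"`, `"adaboost"` or `"xgboost"`.
#' @param train_fraction fraction of supervised pairs, in time order, used for
#'   training; "around 70%" is implemented as exactly `floor(0.7 * n)`.
#' @param backend_settings named list passed through to [fit_backend()].
#' @param seed integer seed for the backend fit.
#' @return Object of class `forecast_config`.
#' @export
forecast_config <- function(gap = 1, mode = c("original", "transformed"),
                            model = c("xgboost", "logistic", "adaboost"),
                            train_fraction = 0.7, backend_settings = list(),
                            seed = 1) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  gap <- as.integer(gap)
  if (gap < 1) stop("`gap` must be >= 1", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(gap = gap, mode = mode, model = model,
                 train_fraction = train_fraction,
                 backend_settings = backend_settings, seed = as.integer(seed)),
            class = "forecast_config")
}

#' Filter a cohort to individuals with learnable state sequences
#'
#' Removes individuals whose state sequence contains a single state overall,
#' or whose chronological training portion (the first
#' `floor(train_fraction * n_targets)` gap-lagged targets) contains a single
#' state, for any of the requested gaps. Mirrors the pre-analysis filter
#' "delete datasets with only one state either in training data (70%) or the
#' whole data".
#'
#' @param cohort an `sc_cohort`.
#' @param train_fraction chronological train fraction (default 0.7).
#' @param gaps integer vector of gaps the cohort must support (an individual
#'   is kept only if it passes the filter for every gap).
#' @return The filtered `sc_cohort`, with a `data.frame` of removals (id,
#'   reason) attached as attribute `"removed"`.
#' @export
filter_cohort <- function(cohort, train_fraction = 0.7, gaps = 1L) {
  if (length(cohort$individuals) == 0) stop("empty cohort", call. = FALSE)
  reasons <- vapply(cohort$individuals, function(ind) {
    s <- ind$states
    if (length(unique(s)) < 2) return("single state in full sequence")
    for (gap in gaps) {
      if (length(s) <= gap + 1) return(sprintf("too short for gap %d", gap))
      targets <- s[(gap + 1):length(s)]
      train <- targets[seq_len(floor(train_fraction * length(targets)))]
      if (length(unique(train)) < 2) {
        return(sprintf("single state in training data (gap %d)", gap))
      }
    }
    ""
  }, character(1))
  keep <- reasons == ""
  if (!any(keep)) stop("no individuals left after filtering", call. = FALSE)
  out <- cohort
  out$individuals <- cohort$individuals[keep]
  out$baseline <- cohort$baseline[
    cohort$baseline$individual_id %in% names(out$individuals), , drop = FALSE]
  attr(out, "removed") <- data.frame(
    individual_id = names(cohort$individuals)[!keep],
    reason = unname(reasons[!keep]), stringsAsFactors = FALSE)
  out
}

#' Build the gap-lagged supervised problem for one individual
#'
#' Pairs the monitored vector at time `t` with the response at time
#' `t + gap`: the raw state \eqn{s_{t+gap}} in original mode, or the
#' transition class \eqn{s^*_{t+gap}} in transformed mode. Features are the
#' time-`t` monitored values only, so no future information leaks into a pair.
#' Original mode yields `T - gap` pairs (`t = 1..T-gap`); transformed mode one
#' fewer (`t = 1..T-gap-1`) because the transition out of the final
#' observation is undefined.
#'
#' @param individual an `sc_individual`.
#' @param gap forecast gap (grid steps).
#' @param mode `"original"` or `"transformed"`.
#' @return Object of class `sc_pairs`: list with `features` (matrix),
#'   `targets` (integer vector), `target_times` (1-based absolute indices
#'   `t + gap`), plus `gap`, `mode`, `id`, and the full state sequence.
#' @export
make_supervised <- function(individual, gap, mode = c("original", "transformed")) {
  mode <- match.arg(mode)
  gap <- as.integer(gap)
  t_n <- length(individual$states)
  if (t_n <= gap + 1) {
    stop(sprintf("individual %s: series length %d too short for gap %d",
                 individual$id, t_n, gap), call. = FALSE)
  }
  n_pairs <- if (mode == "original") t_n - gap else t_n - gap - 1L
  tt <- seq_len(n_pairs)
  targets <- if (mode == "original") {
    individual$states[tt + gap]
  } else {
    encode_transitions(individual$states)[tt + gap]
  }
  structure(list(features = individual$monitors[tt, , drop = FALSE],
                 targets = as.integer(targets),
                 target_times = tt + gap,
                 gap = gap, mode = mode, id = individual$id,
                 states = individual$states),
            class = "sc_pairs")
}

subset_pairs <- function(pairs, idx) {
  out <- pairs
  out$features <- pairs$features[idx, , drop = FALSE]
  out$targets <- pairs$targets[idx]
  out$target_times <- pairs$target_times[idx]
  out
}

#' Chronological train/test split
#'
#' The first `floor(train_fraction * n)` pairs, in time order, form the
#' training set; the remainder the test set. No shuffling.
#'
#' @param pairs an `sc_pairs` from [make_supervised()].
#' @param train_fraction fraction in (0, 1).
#' @return List with elements `train` and `test`, both `sc_pairs`.
#' @export
chronological_split <- function(pairs, train_fraction = 0.7) {
  n <- length(pairs$targets)
  if (n == 0) stop("no supervised pairs to split", call. = FALSE)
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop(sprintf("split of %d pairs at fraction %.2f leaves an empty side",
                 n, train_fraction), call. = FALSE)
  }
  list(train = subset_pairs(pairs, seq_len(n_train)),
       test = subset_pairs(pairs, (n_train + 1):n))
}

#' Fit a backend on training pairs and predict the test pairs
#'
#' In original mode the backend is a binary classifier; its state-1 score is
#' the positive-class probability and hard labels are the argmax. In
#' transformed mode the backend is an up-to-4-class classifier; predicted
#' probabilities over classes absent from training are exactly 0, hard labels
#' are the argmax class decoded back to 0/1 via [decode_states()], and the
#' state-1 score is [score_state1()]. Evaluation truth is always the binary
#' state at the test target times, so both modes are compared on the same
#' footing.
#'
#' @param train,test `sc_pairs` (same mode and gap).
#' @param model backend name.
#' @param backend_settings named list for [fit_backend()].
#' @param seed integer seed.
#' @param decode_convention passed to [decode_states()].
#' @param keep_backend also return the fitted backend (element `backend`).
#' @return Object of class `sc_prediction`: id, model, gap, mode,
#'   `target_times`, `truth`, `pred`, `score`.
#' @export
fit_and_predict <- function(train, test, model = "xgboost",
                            backend_settings = list(), seed = 1,
                            decode_convention = "current",
                            keep_backend = FALSE) {
  stopifnot(train$mode == test$mode, train$gap == test$gap)
  mode <- train$mode
  full_classes <- if (mode == "original") 0:1 else 0:3
  if (length(unique(train$targets)) < 2) {
    stop(sprintf("individual %s: degenerate training data (single class) for gap %d",
                 train$id, train$gap), call. = FALSE)
  }
  backend <- tryCatch(
    fit_backend(model, train$features, train$targets,
                settings = backend_settings, seed = seed),
    error = function(e) stop(sprintf("backend %s failed for individual %s (gap %d, %s): %s",
                                     model, train$id, train$gap, mode,
                                     conditionMessage(e)), call. = FALSE))
  p <- predict_proba(backend, test$features)
  p <- expand_proba(p, backend$classes, full_classes)
  hard_class <- full_classes[max.col(p, ties.method = "first")]
  if (mode == "original") {
    pred <- hard_class
    score <- p[, 2]
  } else {
    pred <- decode_states(hard_class, convention = decode_convention)
    score <- score_state1(p)
  }
  truth <- test$states[test$target_times]
  structure(list(id = train$id, model = model, gap = train$gap, mode = mode,
                 target_times = test$target_times, truth = truth,
                 pred = pred, score = unname(score),
                 backend = if (keep_backend) backend),
            class = "sc_prediction")
}

#' Fit one gap-ahead state forecaster for one individual
#'
#' The single-model entry point: builds the gap-lagged supervised problem,
#' splits it chronologically, fits the requested backend and evaluates it on
#' the held-out tail of the series.
#'
#' @param individual an `sc_individual` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param gap forecast horizon in grid steps.
#' @param mode `"original"` or `"transformed"` response encoding.
#' @param model `"xgboost"`, `"logistic"` or `"adaboost"`.
#' @param train_fraction chronological train fraction.
#' @param backend_settings named list of backend overrides.
#' @param seed integer seed.
#' @return Object of class `state_forecast` with the fitted backend, the test
#'   `sc_prediction`, and per-individual metrics; supports `print()`,
#'   `summary()`, `predict()`, `plot()` and `coef()`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 2, t_min = 150,
#'                                   t_max = 200, seed = 7))
#' fit <- state_forecast(coh$individuals[[1]], gap = 5, mode = "transformed",
#'                       model = "logistic")
#' fit
#' summary(fit)
#' @export
state_forecast <- function(individual, gap = 1,
                           mode = c("original", "transformed"),
                           model = c("xgboost", "logistic", "adaboost"),
                           train_fraction = 0.7, backend_settings = list(),
                           seed = 1) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  pairs <- make_supervised(individual, gap, mode)
  split <- chronological_split(pairs, train_fraction)
  pred <- fit_and_predict(split$train, split$test, model,
                          backend_settings = backend_settings, seed = seed,
                          keep_backend = TRUE)
  backend <- pred$backend
  pred$backend <- NULL
  structure(list(call = match.call(), id = individual$id, gap = gap,
                 mode = mode, model = model, train_fraction = train_fraction,
                 n_train = length(split$train$targets),
                 n_test = length(split$test$targets),
                 backend = backend, prediction = pred,
                 metrics = metrics_from_prediction(pred)),
            class = "state_forecast")
}

#' @export
print.state_forecast <- function(x, ...) {
  cat(sprintf("Gap-%d state forecast for %s (%s response, %s backend)\n",
              x$gap, x$id, x$mode, x$model))
  cat(sprintf("  %d training / %d test pairs (chronological %.0f%% split)\n",
              x$n_train, x$n_test, 100 * x$train_fraction))
  m <- x$metrics
  cat(sprintf("  test AUC %.3f, F1 %.3f, sensitivity %.3f\n",
              m$auc, m$f1, m$sensitivity))
  invisible(x)
}

#' @export
summary.state_forecast <- function(object, ...) {
  cc <- confusion_counts(object$prediction$truth, object$prediction$pred)
  out <- list(metrics = object$metrics, confusion = cc,
              id = object$id, gap = object$gap, mode = object$mode,
              model = object$model)
  class(out) <- "summary.state_forecast"
  out
}

#' @export
print.summary.state_forecast <- function(x, ...) {
  cat(sprintf("Individual %s | gap %d | %s response | %s\n",
              x$id, x$gap, x$mode, x$model))
  cat("Test confusion: ")
  print(unclass(x$confusion))
  print(x$metrics[, c("auc", "f1", "sensitivity", "specificity", "precision")],
        row.names = FALSE)
  invisible(x)
}

#' @export
#' @param object a `state_forecast`.
#' @param newdata matrix of monitored values (one row per time point).
#' @param type `"score"` (state-1 probability), `"state"` (decoded 0/1
#'   label) or `"prob"` (full class-probability matrix).
#' @rdname state_forecast
predict.state_forecast <- function(object, newdata,
                                   type = c("score", "state", "prob"), ...) {
  type <- match.arg(type)
  full_classes <- if (object$mode == "original") 0:1 else 0:3
  p <- expand_proba(predict_proba(object$backend, newdata),
                    object$backend$classes, full_classes)
  switch(type,
         prob = p,
         score = if (object$mode == "original") p[, 2] else score_state1(p),
         state = {
           hard <- full_classes[max.col(p, ties.method = "first")]
           if (object$mode == "original") hard else decode_states(hard)
         })
}

#' @export
plot.state_forecast <- function(x, ...) {
  pr <- x$prediction
  if (length(unique(pr$truth)) < 2) {
    stop("ROC curve undefined: single-class test truth", call. = FALSE)
  }
  thr <- sort(unique(c(-Inf, pr$score, Inf)), decreasing = TRUE)
  sens <- vapply(thr, function(h) mean(pr$score[pr$truth == 1] >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(pr$score[pr$truth == 0] >= h), numeric(1))
  plot(fpr, sens, type = "l", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s, gap %d, %s (AUC %.3f)", x$id, x$gap, x$mode,
                      x$metrics$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
coef.state_forecast <- function(object, ...) {
  if (object$model == "logistic") stats::coef(object$backend$fit) else NULL
}

#' Run a model grid over a cohort
#'
#' For every individual and every (model, gap, mode) cell: build the
#' gap-lagged pairs, split chronologically, fit, predict the test window, and
#' compute per-individual metrics. With `comparable = TRUE` (default) the
#' final original-mode pair (target time `T`) is dropped before splitting so
#' both response modes use identical train/test target times, making the
#' downstream paired t-tests exact pairings. Individuals whose fit fails are
#' logged (attribute `"skipped"`) and skipped, not fatal.
#'
#' @param cohort an `sc_cohort`, ideally already passed through
#'   [filter_cohort()].
#' @param models,gaps,modes character/integer vectors defining the grid
#'   (defaults: the full study grid).
#' @param train_fraction chronological train fraction.
#' @param backend_settings named list for [fit_backend()].
#' @param seed root seed; each (individual, model, gap, mode) fit derives its
#'   own substream.
#' @param comparable align original-mode pairs to the transformed-mode range.
#' @param keep_predictions also return per-time-point test predictions
#'   (attribute `"predictions"`, a long data.frame).
#' @return `data.frame` of per-individual metrics, one row per
#'   (individual, model, gap, mode), class `sc_metrics`.
#' @export
run_experiment <- function(cohort, models = c("logistic", "adaboost", "xgboost"),
                           gaps = c(1, 5, 10, 20),
                           modes = c("original", "transformed"),
                           train_fraction = 0.7, backend_settings = list(),
                           seed = 1, comparable = TRUE,
                           keep_predictions = FALSE) {
  stopifnot(all(models %in% backend_names))
  gaps <- as.integer(gaps)
  inds <- cohort$individuals
  if (length(inds) == 0) stop("empty cohort", call. = FALSE)
  rows <- list()
  preds <- list()
  skipped <- list()
  cell <- 0L
  for (i in seq_along(inds)) {
    ind <- inds[[i]]
    for (gap in gaps) {
      pairs_by_mode <- list()
      for (mode in modes) {
        pairs_by_mode[[mode]] <- tryCatch(make_supervised(ind, gap, mode),
                                          error = function(e) e)
      }
      if (comparable && all(c("original", "transformed") %in% modes) &&
          !inherits(pairs_by_mode$original, "error")) {
        # drop the final original pair so both modes share target times
        n_tra <- length(ind$states) - gap - 1L
        pairs_by_mode$original <- subset_pairs(pairs_by_mode$original,
                                               seq_len(n_tra))
      }
      for (model in models) {
        for (mode in modes) {
          cell <- cell + 1L
          pairs <- pairs_by_mode[[mode]]
          res <- tryCatch({
            if (inherits(pairs, "error")) stop(conditionMessage(pairs))
            split <- chronological_split(pairs, train_fraction)
            fit_and_predict(split$train, split$test, model,
                            backend_settings = backend_settings,
                            seed = derive_seed(seed, cell))
          }, error = function(e) e)
          if (inherits(res, "error")) {
            skipped[[length(skipped) + 1L]] <- data.frame(
              individual_id = ind$id, model = model, gap = gap, mode = mode,
              reason = conditionMessage(res), stringsAsFactors = FALSE)
          } else {
            rows[[length(rows) + 1L]] <- metrics_from_prediction(res)
            if (keep_predictions) {
              preds[[length(preds) + 1L]] <- data.frame(
                individual_id = res$id, model = model, gap = gap, mode = mode,
                time = res$target_times - 1L,  # 0-based, matching the CSVs
                true_state = res$truth, pred_state = res$pred,
                score_state1 = res$score, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    stop("experiment failed for every individual in the cohort", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sc_metrics", "data.frame")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(individual_id = character(), model = character(),
               gap = integer(), mode = character(), reason = character())
  if (keep_predictions) {
    attr(out, "predictions") <- do.call(rbind, preds)
  }
  out
}
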