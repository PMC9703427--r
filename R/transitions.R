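#' Encode a binary state sequence as transition classes
#'
#' Re-expresses a 0/1 state sequence as the four ways a state can evolve
#' between consecutive time points:
#'
#' \describe{
#'   \item{0}{stay at 0 (\eqn{s_t = 0, s_{t+1} = 0})}
#'   \item{1}{recovery (\eqn{s_t = 1, s_{t+1} = 0})}
#'   \item{2}{onset (\eqn{s_t = 0, s_{t+1} = 1})}
#'   \item{3}{stay at 1 (\eqn{s_t = 1, s_{t+1} = 1})}
#' }
#'
#' The class at position \eqn{t} describes the pair \eqn{(s_t, s_{t+1})}, so
#' the output is one element shorter than the input: the transition out of the
#' final observation is unobserved and is dropped.
#'
#' @param states integer/numeric vector of 0/1 states, length at least 2.
#' @return Integer vector over \{0, 1, 2, 3\} of length `length(states) - 1`.
#' @seealso [decode_states()] for the inverse (current-state) mapping,
#'   [score_state1()] for reducing class probabilities to a state-1 score.
#' @examples
#' encode_transitions(c(0, 0, 1, 1, 0))  # 0 2 3 1
#' @export
encode_transitions <- function(states) {
  states <- check_binary(states)
  if (length(states) < 2) {
    stop("`states` must have length >= 2 to define at least one transition",
         call. = FALSE)
  }
  a <- states[-length(states)]
  b <- states[-1]
  a + 2L * b
}

#' Decode transition classes back to binary states
#'
#' Maps each transition class back to a 0/1 state. Under the default
#' `"current"` convention the class at position \eqn{t} is mapped to the state
#' \eqn{s_t} it implies: classes \{1, 3\} (the current state is 1) decode to 1
#' and classes \{0, 2\} decode to 0. This makes a decoded prediction at target
#' index \eqn{t} directly comparable to the true state \eqn{s_t}. The
#' alternative `"next"` convention maps classes \{2, 3\} (the next state is 1)
#' to 1.
#'
#' Predicted class sequences need not be mutually consistent (a classifier can
#' emit any class at any position); decoding is applied elementwise and makes
#' no consistency assumption.
#'
#' @param transitions vector over \{0, 1, 2, 3\}.
#' @param convention `"current"` (default) or `"next"`; which component of the
#'   encoded state pair to recover.
#' @return Integer 0/1 vector, same length as `transitions`.
#' @examples
#' decode_states(c(0, 2, 3, 1))  # 0 0 1 1
#' @export
decode_states <- function(transitions, convention = c("current", "next")) {
  convention <- match.arg(convention)
  if (length(transitions) == 0 || anyNA(transitions) ||
      !all(transitions %in% 0:3)) {
    stop("`transitions` must be a non-empty vector over {0, 1, 2, 3}",
         call. = FALSE)
  }
  transitions <- as.integer(transitions)
  if (convention == "current") transitions %% 2L else as.integer(transitions >= 2L)
}

#' Reduce transition-class probabilities to a state-1 score
#'
#' Given per-time-point probabilities over the four transition classes,
#' returns the total probability that the (current) state is 1, i.e.
#' `P(class 1) + P(class 3)`. This is the continuous score used for ROC/AUC in
#' transformed mode, mirroring how the positive-class probability is used in
#' plain binary classification.
#'
#' @param class_probabilities numeric vector of length 4, or a matrix with 4
#'   columns (one row per time point), ordered as classes 0, 1, 2, 3. Each
#'   probability vector must be non-negative and sum to 1 within `tol`.
#' @param tol tolerance on the sum-to-one check (default `1e-9`).
#' @return Numeric scalar (or vector, one per row) in \[0, 1\].
#' @examples
#' score_state1(c(0.1, 0.2, 0.3, 0.4))  # 0.6
#' @export
score_state1 <- function(class_probabilities, tol = 1e-9) {
  p <- class_probabilities
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 4 || anyNA(p)) {
    stop("`class_probabilities` must be 4 probabilities (or an n x 4 matrix) with no NA",
         call. = FALSE)
  }
  if (any(p < 0) || any(abs(rowSums(p) - 1) > tol)) {
    stop("each probability vector must be non-negative and sum to 1", call. = FALSE)
  }
  out <- p[, 2] + p[, 4]
  if (is.null(dim(class_probabilities))) out[[1]] else unname(out)
}
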