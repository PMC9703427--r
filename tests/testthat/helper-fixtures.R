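# in-code fixtures shared across test files

# individual with a prescribed state sequence and state-separated features:
# column means shift by `effect` when the state is 1, so toy problems are
# separable at will
manual_individual <- function(states, k = 3, effect = 4, seed = 1,
                              id = "toy01") {
  states <- as.integer(states)
  m <- statecast:::with_seed(seed, {
    outer(states, rep(effect, k)) + matrix(rnorm(length(states) * k),
                                           length(states), k)
  })
  colnames(m) <- sprintf("v%02d", seq_len(k))
  structure(list(id = id, monitors = m, states = states,
                 baseline = list(sex = "female", age = 50, weight = 70,
                                 height = 168)),
            class = "sc_individual")
}

manual_cohort <- function(individuals) {
  ids <- vapply(individuals, `[[`, character(1), "id")
  names(individuals) <- ids
  baseline <- do.call(rbind, lapply(individuals, function(i) {
    data.frame(individual_id = i$id, sex = i$baseline$sex, age = i$baseline$age,
               weight = i$baseline$weight, height = i$baseline$height,
               stringsAsFactors = FALSE)
  }))
  rownames(baseline) <- NULL
  structure(list(individuals = individuals, baseline = baseline, config = NULL),
            class = "sc_cohort")
}

# brute-force Mann-Whitney AUC oracle: explicit pairwise comparison with
# half credit for ties (independent of the rank-based implementation)
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# all binary sequences of length len, one per row
all_binary_sequences <- function(len) {
  as.matrix(expand.grid(rep(list(0:1), len)))
}

# small default-signal cohort already passed through the filter
small_filtered_cohort <- function(n = 6, t_min = 120, t_max = 200, seed = 11,
                                  gaps = 1) {
  coh <- simulate_cohort(sim_config(n_individuals = n, t_min = t_min,
                                    t_max = t_max, seed = seed))
  filter_cohort(coh, gaps = gaps)
}
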