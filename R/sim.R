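#' Configuration for the synthetic ICU-style cohort simulator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' simulator emulates the statistical structure of a high-resolution critical
#' care cohort on a regular (5-minute-style) time grid: a rare, persistent
#' binary failure state driven by a two-state Markov chain; monitored
#' variables whose distributions shift between states; a gradual drift of
#' those variables in the window preceding every onset (so that upcoming
#' transitions are forecastable); and baseline covariates (sex, age) that
#' modulate how much signal an individual's monitors carry.
#'
#' @param n_individuals number of individuals in the cohort.
#' @param t_min,t_max per-individual series length is drawn uniformly from
#'   `t_min:t_max` grid steps; `t_min` must be at least 50.
#' @param k_vars number of monitored variables (the last one is binarised into
#'   a drug-presence-style indicator).
#' @param p_onset per-step probability of a 0 to 1 transition. Default 0.01:
#'   with `p_recover = 0.04` this gives long-run state-1 prevalence
#'   `p_onset / (p_onset + p_recover) = 0.2` and episodes lasting on average
#'   25 grid steps (about two hours on a 5-minute grid).
#' @param p_recover per-step probability of a 1 to 0 transition; must exceed
#'   `p_onset` so that state 1 is the rare class.
#' @param drift_lead number of steps before each onset during which monitored
#'   variables drift linearly from their state-0 mean towards their state-1
#'   mean.
#' @param effect_size standardized mean shift of monitored variables between
#'   state 0 and state 1 (per-variable shifts are scaled by fixed weights in
#'   \[0.4, 1\] with alternating sign, so some variables rise and some fall
#'   under failure).
#' @param drift_size standardized magnitude the pre-onset drift reaches just
#'   before the transition. The default equals `effect_size`: deterioration
#'   approaches, but does not exceed, the settled failure-state level, so the
#'   pre-onset window carries early-warning signal without creating
#'   short-horizon negatives that look more extreme than true failure rows.
#' @param baseline_effect strength of baseline modulation: the per-individual
#'   signal multiplier is `1 + baseline_effect * (I(male) - 0.5) -
#'   baseline_effect * z(age)` (floored at 0.2), so older individuals carry
#'   weaker signal and detectable subgroup effects exist.
#' @param seed root seed; every individual derives an independent substream
#'   from it, so single records are reproducible in isolation.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_individual()]
#' @export
sim_config <- function(n_individuals = 70, t_min = 100, t_max = 3000,
                       k_vars = 18, p_onset = 0.01, p_recover = 0.04,
                       drift_lead = 40, effect_size = 1.0, drift_size = 1.0,
                       baseline_effect = 0.15, seed = 1) {
  cfg <- list(n_individuals = as.integer(n_individuals), t_min = as.integer(t_min),
              t_max = as.integer(t_max), k_vars = as.integer(k_vars),
              p_onset = p_onset, p_recover = p_recover,
              drift_lead = as.integer(drift_lead), effect_size = effect_size,
              drift_size = drift_size, baseline_effect = baseline_effect,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_cfg(cfg$n_individuals >= 0, "n_individuals must be >= 0")
  stopifnot_cfg(cfg$t_min >= 50, "t_min must be >= 50")
  stopifnot_cfg(cfg$t_max >= cfg$t_min, "t_max must be >= t_min")
  stopifnot_cfg(cfg$k_vars >= 2, "k_vars must be >= 2")
  stopifnot_cfg(cfg$p_onset >= 0 && cfg$p_onset < 1, "p_onset must be in [0, 1)")
  stopifnot_cfg(cfg$p_recover > 0 && cfg$p_recover < 1, "p_recover must be in (0, 1)")
  stopifnot_cfg(cfg$p_onset < cfg$p_recover,
                "p_onset must be < p_recover (state 1 is the rare class)")
  stopifnot_cfg(cfg$drift_lead >= 1, "drift_lead must be >= 1")
  stopifnot_cfg(cfg$effect_size >= 0 && cfg$drift_size >= 0,
                "effect_size and drift_size must be >= 0")
  invisible(cfg)
}

# Fixed per-variable signal geometry: alternating direction, magnitudes
# spanning [0.4, 1] of effect_size. Deterministic in k so that two cohorts of
# the same width are directly comparable.
variable_weights <- function(k_vars) {
  dir <- rep(c(1, -1), length.out = k_vars)
  mag <- seq(0.4, 1, length.out = k_vars)
  dir * mag
}

# Per-individual signal multiplier from baseline covariates.
baseline_multiplier <- function(baseline, baseline_effect) {
  z_age <- (baseline$age - 54) / 20.8  # age ~ U[18, 90]: mean 54, sd ~20.8
  m <- 1 + baseline_effect * ((baseline$sex == "male") - 0.5) -
    baseline_effect * z_age
  max(0.2, m)
}

#' Simulate one individual's monitored series and state sequence
#'
#' States follow a two-state Markov chain started in state 0 with per-step
#' transition probabilities `p_onset` (0 to 1) and `p_recover` (1 to 0). Each
#' monitored variable is unit-variance Gaussian around a state-dependent mean;
#' in the `drift_lead` steps preceding every onset the mean ramps linearly
#' from the state-0 level up to `drift_size` standard deviations in the
#' state-1 direction. The last variable is thresholded at the midpoint of its
#' two state means into a binary drug-presence-style indicator.
#'
#' @param cfg a [sim_config()].
#' @param baseline list or one-row data.frame with `sex` ("male"/"female"),
#'   `age`, `weight`, `height`.
#' @param seed substream seed for this individual.
#' @param id identifier stored on the record.
#' @return An object of class `sc_individual`: list with `id`, `monitors`
#'   (`T x k_vars` matrix with columns `v01..`), `states` (integer 0/1 vector),
#'   and `baseline`.
#' @export
simulate_individual <- function(cfg, baseline, seed = cfg$seed, id = "ind001") {
  validate_sim_config(cfg)
  with_seed(seed, {
    t_n <- if (cfg$t_max > cfg$t_min) sample(cfg$t_min:cfg$t_max, 1) else cfg$t_min
    s <- integer(t_n)
    u <- stats::runif(t_n)
    for (t in 2:t_n) {
      s[t] <- if (s[t - 1] == 0L) as.integer(u[t] < cfg$p_onset)
              else as.integer(u[t] >= cfg$p_recover)
    }
    w_k <- variable_weights(cfg$k_vars)
    mult <- baseline_multiplier(baseline, cfg$baseline_effect)

    # pre-onset ramp: 0 outside drift windows, rising to 1 just before onset
    ramp <- numeric(t_n)
    for (on in which(diff(s) == 1L) + 1L) {
      win <- max(1L, on - cfg$drift_lead):(on - 1L)
      ramp[win] <- pmax(ramp[win], (win - (on - cfg$drift_lead)) / cfg$drift_lead)
    }
    ramp[s == 1L] <- 0

    shift <- cfg$effect_size * s + cfg$drift_size * ramp
    mu <- outer(shift, w_k * mult)
    monitors <- mu + matrix(stats::rnorm(t_n * cfg$k_vars), t_n, cfg$k_vars)

    # drug-presence-like indicator: threshold the last variable halfway
    # between its state-0 and state-1 means
    thr <- w_k[cfg$k_vars] * mult * cfg$effect_size / 2
    monitors[, cfg$k_vars] <- as.numeric(
      if (w_k[cfg$k_vars] >= 0) monitors[, cfg$k_vars] > thr
      else monitors[, cfg$k_vars] < thr
    )
    colnames(monitors) <- sprintf("v%02d", seq_len(cfg$k_vars))

    structure(list(id = id, monitors = monitors, states = s,
                   baseline = as.list(baseline)),
              class = "sc_individual")
  })
}

#' Simulate a synthetic cohort
#'
#' Draws baseline covariates (sex Bernoulli(0.5); age Uniform\[18, 90\];
#' weight Normal(75, 15) truncated above 30 kg; height Normal(170, 10)) and
#' then simulates each individual with [simulate_individual()] on its own
#' derived substream, so any single record can be regenerated independently.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sc_cohort`: list with `individuals` (list of
#'   `sc_individual`), `baseline` (data.frame, one row per individual), and
#'   `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 3, t_min = 60, t_max = 80))
#' coh
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  baseline <- with_seed(derive_seed(cfg$seed, 0L), {
    if (n == 0) {
      data.frame(individual_id = character(), sex = character(),
                 age = numeric(), weight = numeric(), height = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      weight <- stats::rnorm(n, 75, 15)
      while (any(weight <= 30)) {
        weight[weight <= 30] <- stats::rnorm(sum(weight <= 30), 75, 15)
      }
      data.frame(individual_id = ids,
                 sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
                 age = stats::runif(n, 18, 90),
                 weight = weight,
                 height = stats::rnorm(n, 170, 10),
                 stringsAsFactors = FALSE)
    }
  })
  individuals <- lapply(seq_len(n), function(i) {
    simulate_individual(cfg, as.list(baseline[i, -1, drop = FALSE]),
                        seed = derive_seed(cfg$seed, i), id = ids[i])
  })
  names(individuals) <- ids
  structure(list(individuals = individuals, baseline = baseline, config = cfg),
            class = "sc_cohort")
}

#' @export
print.sc_cohort <- function(x, ...) {
  n <- length(x$individuals)
  tt <- vapply(x$individuals, function(i) length(i$states), integer(1))
  s1 <- vapply(x$individuals, function(i) sum(i$states), numeric(1))
  cat(sprintf("Synthetic cohort: %d individuals, %d monitored variables\n",
              n, x$config$k_vars))
  if (n > 0) {
    cat(sprintf("  series length: %d-%d (total %d observations)\n",
                min(tt), max(tt), sum(tt)))
    cat(sprintf("  pooled state-1 prevalence: %.3f\n", sum(s1) / sum(tt)))
  }
  invisible(x)
}

#' @export
print.sc_individual <- function(x, ...) {
  cat(sprintf("Individual %s: %d time points, %d monitored variables, %d onset(s)\n",
              x$id, length(x$states), ncol(x$monitors),
              sum(diff(x$states) == 1)))
  invisible(x)
}

#' Write / read a cohort as long-format CSV
#'
#' `write_cohort()` writes `monitored.csv` (header
#' `individual_id,time,state,v01..vK`; `time` is a 0-based grid index) and
#' `baseline.csv` (`individual_id,sex,age,weight,height`) into `dir`.
#' `read_cohort()` reads the same dialect back into an `sc_cohort`, accepting
#' user-supplied cohorts in that layout.
#'
#' @param cohort an `sc_cohort` (for reading, any CSV pair in the same dialect).
#' @param dir directory to write to / read from (created if missing).
#' @return `write_cohort()` returns the two file paths invisibly;
#'   `read_cohort()` returns an `sc_cohort` (with `config = NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- do.call(rbind, lapply(cohort$individuals, function(ind) {
    data.frame(individual_id = ind$id,
               time = seq_along(ind$states) - 1L,
               state = ind$states,
               ind$monitors,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  f_mon <- file.path(dir, "monitored.csv")
  f_bas <- file.path(dir, "baseline.csv")
  utils::write.csv(long, f_mon, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$baseline, f_bas, row.names = FALSE, quote = FALSE)
  invisible(c(monitored = f_mon, baseline = f_bas))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  long <- utils::read.csv(file.path(dir, "monitored.csv"),
                          stringsAsFactors = FALSE)
  baseline <- utils::read.csv(file.path(dir, "baseline.csv"),
                              stringsAsFactors = FALSE)
  need <- c("individual_id", "time", "state")
  if (!all(need %in% names(long))) {
    stop("monitored.csv must have columns individual_id, time, state, v..",
         call. = FALSE)
  }
  vcols <- setdiff(names(long), need)
  ids <- unique(long$individual_id)
  individuals <- lapply(ids, function(id) {
    rows <- long[long$individual_id == id, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    b <- baseline[baseline$individual_id == id, -1, drop = FALSE]
    structure(list(id = id,
                   monitors = as.matrix(rows[, vcols, drop = FALSE]),
                   states = check_binary(rows$state),
                   baseline = if (nrow(b)) as.list(b[1, ]) else NULL),
              class = "sc_individual")
  })
  names(individuals) <- ids
  structure(list(individuals = individuals, baseline = baseline, config = NULL),
            class = "sc_cohort")
}
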