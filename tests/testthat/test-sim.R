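test_that("invalid simulator configurations fail before any sampling", {
  expect_error(sim_config(p_onset = 0.2, p_recover = 0.1), "p_onset must be <")
  expect_error(sim_config(p_onset = 0.05, p_recover = 0.05), "p_onset must be <")
  expect_error(sim_config(t_min = 20), "t_min")
  expect_error(sim_config(drift_lead = 0), "drift_lead")
  expect_error(sim_config(p_recover = 1.2), "p_recover")
  expect_error(sim_config(effect_size = -1), "effect_size")
})

test_that("zero onset hazard keeps every state at 0", {
  cfg <- sim_config(n_individuals = 1, p_onset = 0, p_recover = 0.1,
                    t_min = 100, t_max = 100, seed = 3)
  ind <- simulate_individual(cfg, list(sex = "male", age = 40, weight = 80,
                                       height = 175), seed = 3)
  expect_true(all(ind$states == 0L))
})

test_that("identical config and seed reproduce a cohort exactly", {
  cfg <- sim_config(n_individuals = 4, t_min = 60, t_max = 120, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$individuals, c2$individuals)
  expect_identical(c1$baseline, c2$baseline)
  # per-individual substreams: record 3 is reproducible in isolation
  ind3 <- simulate_individual(cfg, as.list(c1$baseline[3, -1]),
                              seed = statecast:::derive_seed(99, 3),
                              id = "ind003")
  expect_identical(ind3, c1$individuals[[3]])
  c3 <- simulate_cohort(sim_config(n_individuals = 4, t_min = 60, t_max = 120,
                                   seed = 100))
  expect_false(identical(c1$individuals, c3$individuals))
})

test_that("empty cohorts are allowed", {
  coh <- simulate_cohort(sim_config(n_individuals = 0, t_min = 60, t_max = 80))
  expect_length(coh$individuals, 0)
  expect_identical(nrow(coh$baseline), 0L)
})

test_that("long-run state-1 fraction matches the two-state chain's stationary law", {
  # closed form: p_onset / (p_onset + p_recover) = 0.02 / 0.12 = 1/6
  cfg <- sim_config(n_individuals = 1, p_onset = 0.02, p_recover = 0.10,
                    t_min = 10000, t_max = 10000, seed = 12)
  ind <- simulate_individual(cfg, list(sex = "female", age = 60, weight = 65,
                                       height = 160), seed = 12)
  expect_lt(abs(mean(ind$states) - 1 / 6), 0.05)
})

test_that("baseline covariates respect their stated ranges", {
  coh <- simulate_cohort(sim_config(n_individuals = 40, t_min = 50, t_max = 60,
                                    seed = 5))
  b <- coh$baseline
  expect_true(all(b$sex %in% c("male", "female")))
  expect_true(all(b$age >= 18 & b$age <= 90))
  expect_true(all(b$weight > 30))
  expect_true(all(abs(b$height - 170) < 60))
})

test_that("monitored variables separate the two states (pooled t-test)", {
  coh <- simulate_cohort(sim_config(n_individuals = 10, t_min = 200,
                                    t_max = 400, seed = 21))
  pooled_m <- do.call(rbind, lapply(coh$individuals, `[[`, "monitors"))
  pooled_s <- unlist(lapply(coh$individuals, `[[`, "states"))
  expect_gt(sum(pooled_s), 50)
  for (k in c(1, 9, 17)) {
    p <- t.test(pooled_m[pooled_s == 0, k], pooled_m[pooled_s == 1, k])$p.value
    expect_lt(p, 0.01)
  }
  # the drug-presence-style variable is binary yet still state-dependent
  drug <- pooled_m[, ncol(pooled_m)]
  expect_true(all(drug %in% c(0, 1)))
  expect_lt(chisq.test(table(drug, pooled_s))$p.value, 0.01)
})

test_that("monitored variables drift upward in the window before an onset", {
  cfg <- sim_config(n_individuals = 1, t_min = 8000, t_max = 8000, seed = 31)
  ind <- simulate_individual(cfg, list(sex = "male", age = 54, weight = 75,
                                       height = 170), seed = 31)
  s <- ind$states
  onsets <- which(diff(s) == 1L) + 1L
  expect_gt(length(onsets), 3)
  win <- unique(unlist(lapply(onsets, function(u) {
    max(1, u - cfg$drift_lead):(u - 1)
  })))
  win <- win[s[win] == 0L]
  quiet0 <- setdiff(which(s == 0L), win)
  # variable 17 has positive direction and near-maximal weight
  expect_gt(mean(ind$monitors[win, 17]) - mean(ind$monitors[quiet0, 17]), 0.2)
})

test_that("cohort CSV export is byte-stable and round-trips", {
  coh <- simulate_cohort(sim_config(n_individuals = 3, t_min = 60, t_max = 90,
                                    seed = 8))
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(coh, d1)
  write_cohort(coh, d2)
  expect_identical(readLines(file.path(d1, "monitored.csv")),
                   readLines(file.path(d2, "monitored.csv")))
  expect_identical(readLines(file.path(d1, "baseline.csv")),
                   readLines(file.path(d2, "baseline.csv")))
  back <- read_cohort(d1)
  expect_identical(names(back$individuals), names(coh$individuals))
  for (id in names(coh$individuals)) {
    expect_identical(back$individuals[[id]]$states, coh$individuals[[id]]$states)
    expect_equal(back$individuals[[id]]$monitors, coh$individuals[[id]]$monitors,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
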