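test_that("study configs validate before any computation", {
  expect_error(study_config(models = "svm"), "unknown model")
  expect_error(study_config(gaps = 0), "gaps")
  expect_error(study_config(train_fraction = 1.2), "train_fraction")
  expect_error(study_config(subgroup_model = "adaboost", models = "logistic"),
               "subgroup cell")
  expect_error(run_study(list(models = "nonesuch"), out_dir = tempfile()),
               "unknown model")
})

test_that("a study run is end-to-end deterministic and fully written out", {
  cfg <- study_config(seed = 4, sim = list(n_individuals = 6, t_min = 120,
                                           t_max = 200),
                      models = c("logistic", "xgboost"), gaps = c(1, 5),
                      backend_settings = list(nrounds = 30))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_study(cfg, out_dir = d1)
  r2 <- run_study(cfg, out_dir = d2)
  digest <- function(r) vapply(r$manifest$files, `[[`, character(1), "md5")
  expect_identical(digest(r1), digest(r2))
  expect_true(all(file.exists(file.path(d1, c("monitored.csv", "baseline.csv",
                                              "removed.csv", "metrics.csv",
                                              "comparison.csv", "subgroup.csv",
                                              "manifest.json")))))
  # comparison covers the configured grid: 2 models x 2 gaps x 3 metrics
  expect_identical(nrow(r1$comparison), 12L)
  expect_identical(r1$manifest$counts$metrics_rows, nrow(r1$metrics))
  # manifest row counts match the files on disk
  cmp_file <- read.csv(file.path(d1, "comparison.csv"))
  expect_identical(nrow(cmp_file), nrow(r1$comparison))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a YAML config reproduces the equivalent in-memory config", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 4",
               "sim:", "  n_individuals: 6", "  t_min: 120", "  t_max: 200",
               "models: [logistic]", "gaps: [1, 5]",
               "subgroup_model: logistic",
               "backend_settings:", "  nrounds: 30"), yml)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_study(yml, out_dir = d1)
  r2 <- run_study(study_config(seed = 4,
                               sim = list(n_individuals = 6, t_min = 120,
                                          t_max = 200),
                               models = "logistic", gaps = c(1, 5),
                               subgroup_model = "logistic",
                               backend_settings = list(nrounds = 30)),
                  out_dir = d2)
  expect_identical(vapply(r1$manifest$files, `[[`, character(1), "md5"),
                   vapply(r2$manifest$files, `[[`, character(1), "md5"))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a user-supplied data directory can replace simulation", {
  coh <- simulate_cohort(sim_config(n_individuals = 4, t_min = 120,
                                    t_max = 160, seed = 10))
  dat <- tempfile()
  write_cohort(coh, dat)
  out <- tempfile()
  r <- run_study(study_config(seed = 1, data_dir = dat, models = "logistic",
                              gaps = 1, subgroup_model = "logistic"),
                 out_dir = out)
  expect_identical(r$manifest$counts$individuals_simulated, 4L)
  expect_gt(nrow(r$metrics), 0)
  unlink(c(dat, out), recursive = TRUE)
})
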