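test_that("paired t matches the closed form and flags degenerate input", {
  x <- c(0.9, 0.8, 0.7)
  y <- c(0.85, 0.70, 0.68)
  r <- paired_t_test(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 17 / 7, tolerance = 1e-9)
  expect_equal(r$p, 2 * pt(17 / 7, df = 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_identical(r$n, 3L)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_match(same$reason, "zero difference variance")
  expect_true(is.na(same$t))

  few <- paired_t_test(c(1, NA), c(2, 3))
  expect_true(few$degenerate)
})

test_that("paired t is antisymmetric and drops incomplete pairs", {
  set.seed(3)
  x <- runif(12); y <- runif(12)
  x[c(2, 5)] <- NA
  a <- paired_t_test(x, y)
  b <- paired_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_identical(a$n, 10L)
})

test_that("two-group ANOVA F equals the hand value and the squared pooled t", {
  r <- statecast:::anova_ftest(c(1, 2, 3, 4, 5, 6),
                               rep(c("female", "male"), each = 3))
  expect_equal(r$F, 13.5, tolerance = 1e-9)  # SSB 13.5, SSW/df 1
  expect_equal(unname(r$group_means), c(2, 5))
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)

  const <- statecast:::anova_ftest(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(const$F, 0)
  single <- statecast:::anova_ftest(1:4, c("a", "a", "a", "b"))
  expect_true(single$degenerate)
})

test_that("regression F equals the squared slope t", {
  set.seed(8)
  y <- rnorm(30); x <- rnorm(30)
  r <- statecast:::regression_ftest(y, x)
  fit <- summary(lm(y ~ x))
  expect_equal(r$F, unname(fit$coefficients["x", "t value"])^2, tolerance = 1e-9)
  expect_equal(r$p, unname(fit$coefficients["x", "Pr(>|t|)"]), tolerance = 1e-12)
  expect_equal(r$slope, unname(coef(lm(y ~ x))[2]))
  expect_true(statecast:::regression_ftest(y, rep(2, 30))$degenerate)
})

make_metrics_table <- function(n_ind = 10, models = "xgboost", gaps = c(5, 20),
                               seed = 1) {
  set.seed(seed)
  grid <- expand.grid(individual_id = sprintf("ind%03d", seq_len(n_ind)),
                      model = models, gap = gaps,
                      mode = c("original", "transformed"),
                      stringsAsFactors = FALSE)
  grid$auc <- runif(nrow(grid), 0.6, 0.95)
  grid$f1 <- runif(nrow(grid), 0.4, 0.9)
  grid$sensitivity <- runif(nrow(grid), 0.4, 0.9)
  grid$specificity <- runif(nrow(grid), 0.5, 1)
  grid$precision <- runif(nrow(grid), 0.4, 1)
  grid
}

test_that("method comparison emits one row per model x gap x metric", {
  m <- make_metrics_table(n_ind = 8, models = c("logistic", "xgboost"))
  cmp <- compare_methods(m)
  expect_identical(nrow(cmp), 2L * 2L * 3L)
  expect_identical(unique(cmp$metric), c("auc", "f1", "sensitivity"))
  expect_true(all(cmp$n_pairs == 8))
  expect_true(all(is.finite(cmp$t)))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  # positive t must mean original beat transformed on the paired means
  for (i in seq_len(nrow(cmp))) {
    expect_equal(sign(cmp$t[i]), sign(cmp$ori_mean[i] - cmp$tra_mean[i]))
  }
})

test_that("copied modes give equal means and degenerate t", {
  m <- make_metrics_table(n_ind = 6)
  m[m$mode == "transformed", c("auc", "f1", "sensitivity")] <-
    m[m$mode == "original", c("auc", "f1", "sensitivity")]
  cmp <- compare_methods(m)
  expect_equal(cmp$ori_mean, cmp$tra_mean)
  expect_true(all(is.na(cmp$t)))
})

test_that("comparison refuses tables missing a mode", {
  m <- make_metrics_table()
  expect_error(compare_methods(m[m$mode == "original", ]), "both response modes")
  expect_error(compare_methods(m[!(m$mode == "transformed" & m$gap == 20), ]),
               "incomplete experiment")
})

test_that("subgroup analysis tests sex by ANOVA and continuous variables by regression", {
  m <- make_metrics_table(n_ind = 20, gaps = 5)
  base <- data.frame(individual_id = sprintf("ind%03d", 1:20),
                     sex = rep(c("male", "female"), 10),
                     age = seq(20, 88, length.out = 20),
                     weight = rnorm(20, 75, 10), height = rnorm(20, 170, 8),
                     stringsAsFactors = FALSE)
  sg <- subgroup_analysis(m, base, model = "xgboost", mode = "transformed")
  expect_identical(nrow(sg), 4L * 3L)  # variables x metrics x 1 gap
  sex_rows <- sg[sg$variable == "sex", ]
  expect_true(all(is.finite(sex_rows$F)))
  expect_true(all(is.finite(sex_rows$mean_female + sex_rows$mean_male)))
  cont <- sg[sg$variable != "sex", ]
  expect_true(all(is.finite(cont$slope)))
  expect_true(all(is.na(cont$mean_male)))
  # agreement with a direct computation for one cell
  cell <- merge(m[m$model == "xgboost" & m$mode == "transformed" & m$gap == 5, ],
                base, by = "individual_id")
  direct <- statecast:::regression_ftest(cell$auc, cell$age)
  got <- sg[sg$variable == "age" & sg$metric == "auc", ]
  expect_equal(got$F, direct$F)
  expect_equal(got$slope, direct$slope)
  # constant metric across individuals: F = 0 for continuous variables
  m0 <- m; m0$auc <- 0.8
  sg0 <- subgroup_analysis(m0, base, metric_names = "auc")
  expect_equal(sg0$F[sg0$variable == "age"], 0)
})
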