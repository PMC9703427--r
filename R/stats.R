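#' Paired t-test over per-individual metrics
#'
#' Two-sided paired Student t-test on the differences `d = x - y`, individuals
#' aligned by position; pairs with any missing value are dropped. Degenerate
#' inputs (fewer than 2 complete pairs, or zero difference variance) are
#' reported as such rather than raised.
#'
#' @param x,y equal-length numeric vectors (e.g. per-individual AUC under the
#'   original and the transformed response).
#' @param paired if `FALSE`, a Welch two-sample test is used instead.
#' @return List with `t`, `p`, `n` (complete pairs used), `mean_diff`, and
#'   `degenerate` (logical, with `reason` when `TRUE`; `t` and `p` are then
#'   `NA`).
#' @export
paired_t_test <- function(x, y, paired = TRUE) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length (aligned by individual)",
         call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  degenerate <- function(reason) {
    list(t = NA_real_, p = NA_real_, n = n,
         mean_diff = if (n) mean(x - y) else NA_real_,
         degenerate = TRUE, reason = reason)
  }
  if (n < 2) return(degenerate("fewer than 2 complete pairs"))
  if (paired && stats::sd(x - y) == 0) return(degenerate("zero difference variance"))
  if (!paired && stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(degenerate("zero variance in both samples"))
  }
  ht <- stats::t.test(x, y, paired = paired)
  list(t = unname(ht$statistic), p = ht$p.value, n = n,
       mean_diff = mean(x) - mean(y), degenerate = FALSE, reason = NA_character_)
}

#' Compare original- and transformed-response performance across a cohort
#'
#' For every (model, gap, metric) cell, computes the per-mode mean and
#' standard deviation of the per-individual metric and a paired t-test of
#' original minus transformed (so positive `t` favours the original
#' response).
#'
#' @param metrics an `sc_metrics` table from [run_experiment()] containing
#'   both modes for every (model, gap).
#' @param metric_names metrics to compare (default AUC, F1, sensitivity).
#' @param paired use the paired test (default); `FALSE` gives Welch.
#' @return `data.frame` with one row per model x gap x metric: `ori_mean`,
#'   `ori_sd`, `tra_mean`, `tra_sd`, `t`, `p`, `n_pairs`.
#' @export
compare_methods <- function(metrics, metric_names = c("auc", "f1", "sensitivity"),
                            paired = TRUE) {
  stopifnot(is.data.frame(metrics))
  models <- unique(metrics$model)
  gaps <- sort(unique(metrics$gap))
  if (!all(c("original", "transformed") %in% unique(metrics$mode))) {
    stop("`metrics` must contain both response modes", call. = FALSE)
  }
  grid <- expand.grid(metric = metric_names, gap = gaps, model = models,
                      stringsAsFactors = FALSE)[, c("model", "gap", "metric")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pick <- function(mode) {
      sub <- metrics[metrics$model == g$model & metrics$gap == g$gap &
                       metrics$mode == mode, c("individual_id", g$metric)]
      if (nrow(sub) == 0) {
        stop(sprintf("incomplete experiment: no %s rows for model %s gap %d",
                     mode, g$model, g$gap), call. = FALSE)
      }
      sub
    }
    ori <- pick("original")
    tra <- pick("transformed")
    ids <- union(ori$individual_id, tra$individual_id)
    x <- ori[[g$metric]][match(ids, ori$individual_id)]
    y <- tra[[g$metric]][match(ids, tra$individual_id)]
    tt <- paired_t_test(x, y, paired = paired)
    data.frame(model = g$model, gap = g$gap, metric = g$metric,
               ori_mean = mean(x, na.rm = TRUE), ori_sd = stats::sd(x, na.rm = TRUE),
               tra_mean = mean(y, na.rm = TRUE), tra_sd = stats::sd(y, na.rm = TRUE),
               t = tt$t, p = tt$p, n_pairs = tt$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sc_comparison", "data.frame")
  out
}

# Overall F-test of a simple linear regression y ~ x; slope reported.
regression_ftest <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3 || stats::sd(x) == 0) {
    return(list(F = NA_real_, p = NA_real_, slope = NA_real_, n = length(y),
                degenerate = TRUE))
  }
  if (stats::sd(y) == 0) {  # constant metric: no variation to explain
    return(list(F = 0, p = 1, slope = 0, n = length(y), degenerate = FALSE))
  }
  fit <- stats::lm(y ~ x)
  fs <- summary(fit)$fstatistic
  if (is.null(fs)) {
    return(list(F = NA_real_, p = NA_real_, slope = NA_real_, n = length(y),
                degenerate = TRUE))
  }
  list(F = unname(fs[1]), p = unname(stats::pf(fs[1], fs[2], fs[3],
                                               lower.tail = FALSE)),
       slope = unname(stats::coef(fit)[2]), n = length(y), degenerate = FALSE)
}

# One-way ANOVA F-test of y between groups; group means reported.
anova_ftest <- function(y, group) {
  ok <- stats::complete.cases(y, group)
  y <- y[ok]; group <- factor(group[ok])
  group <- droplevels(group)
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    return(list(F = NA_real_, p = NA_real_, group_means = NULL, n = length(y),
                degenerate = TRUE))
  }
  if (stats::sd(y) == 0) {
    return(list(F = 0, p = 1, group_means = vapply(split(y, group), mean, numeric(1)),
                n = length(y), degenerate = FALSE))
  }
  av <- stats::anova(stats::lm(y ~ group))
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
       group_means = vapply(split(y, group), mean, numeric(1)),
       n = length(y), degenerate = FALSE)
}

#' Subgroup analysis of performance against baseline covariates
#'
#' Tests whether per-individual performance depends on baseline variables, for
#' one (model, mode) cell across the requested gaps. Categorical `sex` uses a
#' one-way ANOVA F-test; continuous `age`, `weight`, `height` use the overall
#' F-test of a simple linear regression (identical to ANOVA for a categorical
#' predictor), reporting the fitted slope. Raw p-values are reported;
#' `p_adjust = "BH"` optionally applies Benjamini-Hochberg across the rows.
#'
#' @param metrics an `sc_metrics` table from [run_experiment()].
#' @param baselines `data.frame` with `individual_id`, `sex`, `age`, `weight`,
#'   `height` (e.g. `cohort$baseline`).
#' @param model,mode the cell to analyse (default: xgboost / transformed).
#' @param metric_names metrics to analyse.
#' @param variables baseline variables to test.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with one row per variable x metric x gap: `F`, `p`,
#'   `slope` (NA for sex), `mean_female`/`mean_male` (NA for continuous
#'   variables), `n`.
#' @export
subgroup_analysis <- function(metrics, baselines,
                              model = "xgboost", mode = "transformed",
                              metric_names = c("auc", "f1", "sensitivity"),
                              variables = c("sex", "age", "weight", "height"),
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  sub <- metrics[metrics$model == model & metrics$mode == mode, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no metrics rows for model %s, mode %s", model, mode),
         call. = FALSE)
  }
  gaps <- sort(unique(sub$gap))
  rows <- list()
  for (gap in gaps) {
    cell <- merge(sub[sub$gap == gap, ], baselines, by = "individual_id")
    for (metric in metric_names) {
      for (variable in variables) {
        if (variable == "sex") {
          r <- anova_ftest(cell[[metric]], cell$sex)
          gm <- r$group_means
          rows[[length(rows) + 1L]] <- data.frame(
            variable = variable, metric = metric, gap = gap,
            F = r$F, p = r$p, slope = NA_real_,
            mean_female = if (!is.null(gm)) unname(gm["female"]) else NA_real_,
            mean_male = if (!is.null(gm)) unname(gm["male"]) else NA_real_,
            n = r$n, stringsAsFactors = FALSE)
        } else {
          r <- regression_ftest(cell[[metric]], cell[[variable]])
          rows[[length(rows) + 1L]] <- data.frame(
            variable = variable, metric = metric, gap = gap,
            F = r$F, p = r$p, slope = r$slope,
            mean_female = NA_real_, mean_male = NA_real_,
            n = r$n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("sc_subgroup", "data.frame")
  out
}

#' Write cohort-comparison and subgroup tables as CSV
#'
#' `write_comparison()` writes the tidy comparison table (one row per model x
#' gap x metric). `write_subgroup()` writes one row per variable x metric x
#' gap with a single `slope_or_groupmeans` column (the slope for continuous
#' variables, `"female=..;male=.."` for sex).
#'
#' @param comparison an `sc_comparison` from [compare_methods()].
#' @param subgroup an `sc_subgroup` from [subgroup_analysis()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_comparison
#' @export
write_subgroup <- function(subgroup, path) {
  out <- as.data.frame(subgroup)
  out$slope_or_groupmeans <- ifelse(
    out$variable == "sex",
    sprintf("female=%.6g;male=%.6g", out$mean_female, out$mean_male),
    as.character(out$slope))
  out <- out[, c("variable", "metric", "gap", "F", "p",
                 "slope_or_groupmeans", "n")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
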