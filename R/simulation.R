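#' Monte-Carlo study design
#'
#' The default values reproduce the evaluation conditions of the growth
#' study: nine artificial tests per occasion (lengths 10/30/60 crossed
#' with dichotomous:polytomous mix ratios 2, 1, 0.5), dichotomous
#' difficulties drawn from N(0, 1), four-category step parameters drawn
#' from N(-1.5, 0.2), N(-0.5, 0.2), N(0.5, 0.2) and N(1.5, 0.2)
#' (mean/SD), a 17-point true-ability grid from -4 to 4 in steps of 0.5,
#' growth values 1.0 / 0.8 / 0.6 attached to low (`theta1 < -2`),
#' medium (`-2 <= theta1 <= 2`) and high (`theta1 > 2`) initial
#' ability, and 1000 replications per level.
#'
#' @param regime `"longitudinal"` or `"unidimensional"`.
#' @param test_lengths Test lengths per occasion.
#' @param mix_ratios Dichotomous:polytomous ratios (`lambda`).
#' @param theta1_grid True initial-ability grid.
#' @param theta2_levels Named growth values for `low`/`medium`/`high`
#'   initial ability (longitudinal only).
#' @param n_reps Replications per ability level.
#' @param n_categories Categories per polytomous item.
#' @param step_means,step_sd Means and common SD of the step-parameter
#'   distributions (one mean per category).
#' @param b_mean,b_sd Dichotomous difficulty distribution.
#' @param a_mode `"fixed"` keeps all discriminations at 1 (Rasch);
#'   `"uniform"` draws them from `a_range` (the two-parameter logistic
#'   mode used by the unidimensional study).
#' @param a_range Range of the uniform discrimination draw.
#' @return A list of class `study_design`.
#' @export
study_design <- function(regime = c("longitudinal", "unidimensional"),
                         test_lengths = c(10L, 30L, 60L),
                         mix_ratios = c(2, 1, 0.5),
                         theta1_grid = seq(-4, 4, by = 0.5),
                         theta2_levels = c(low = 1.0, medium = 0.8, high = 0.6),
                         n_reps = 1000L,
                         n_categories = 4L,
                         step_means = c(-1.5, -0.5, 0.5, 1.5),
                         step_sd = 0.2,
                         b_mean = 0, b_sd = 1,
                         a_mode = c("fixed", "uniform"),
                         a_range = c(0.75, 4 / 3)) {
  regime <- match.arg(regime)
  a_mode <- match.arg(a_mode)
  stopifnot(all(test_lengths >= 2), all(mix_ratios > 0), n_reps >= 1,
            n_categories >= 2, length(step_means) == n_categories,
            step_sd >= 0, b_sd > 0, length(a_range) == 2,
            a_range[1] > 0, a_range[1] <= a_range[2],
            all(c("low", "medium", "high") %in% names(theta2_levels)))
  structure(list(regime = regime, test_lengths = as.integer(test_lengths),
                 mix_ratios = mix_ratios, theta1_grid = theta1_grid,
                 theta2_levels = theta2_levels, n_reps = as.integer(n_reps),
                 n_categories = as.integer(n_categories),
                 step_means = step_means, step_sd = step_sd,
                 b_mean = b_mean, b_sd = b_sd,
                 a_mode = a_mode, a_range = a_range),
            class = "study_design")
}

#' Growth value attached to an initial ability
#'
#' High initial ability gets low gain and vice versa:
#' `theta1 > 2 -> theta2_levels["high"]` (0.6 by default),
#' `-2 <= theta1 <= 2 -> "medium"` (0.8), `theta1 < -2 -> "low"` (1.0).
#'
#' @param theta1 Numeric vector of initial abilities.
#' @param design A [study_design()].
#' @return Numeric vector of growth values.
#' @export
theta2_for <- function(theta1, design = study_design()) {
  lv <- design$theta2_levels
  ifelse(theta1 > 2, lv[["high"]], ifelse(theta1 < -2, lv[["low"]],
                                          lv[["medium"]]))
}

#' Number of dichotomous items for a length/mix condition
#'
#' `round(length * lambda / (1 + lambda))`, which reproduces the study's
#' printed splits: 7/5/3 of 10, 20/15/10 of 30 and 40/30/20 of 60 for
#' `lambda` = 2, 1, 0.5.
#'
#' @param test_length Items per occasion.
#' @param mix_ratio Dichotomous:polytomous ratio `lambda`.
#' @return Integer count of dichotomous items.
#' @export
n_dichotomous <- function(test_length, mix_ratio) {
  stopifnot(test_length >= 2, mix_ratio > 0)
  nd <- as.integer(round(test_length * mix_ratio / (1 + mix_ratio)))
  stopifnot(nd >= 1, nd <= test_length - 1)
  nd
}

#' Derive a child seed from integer components
#'
#' Deterministic mixing of a master seed with structural indices
#' (condition, ability level, replication), so every stochastic output
#' is exactly reproducible from `(master seed, condition, level,
#' replication)` without consuming a shared RNG stream.  The result is
#' always a valid 32-bit seed.
#'
#' @param ... Integer components, master seed first.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(...) {
  vals <- c(...)
  stopifnot(length(vals) >= 1, all(is.finite(vals)))
  x <- 1
  for (v in vals) x <- (x * 69069 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(x)
}

#' Draw an item bank for a simulation condition
#'
#' Dichotomous difficulties are N(`b_mean`, `b_sd`); the `h` step
#' parameters of each polytomous item come from the per-category normal
#' distributions of the design.  Longitudinal banks contain
#' `test_length` items per occasion with the same format split at both
#' occasions; unidimensional banks contain a single set.
#' Discriminations are 1 unless the design's `a_mode` is `"uniform"`.
#'
#' @param test_length Items per occasion.
#' @param n_dich Number of dichotomous items per occasion.
#' @param design A [study_design()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A [test_form()].
#' @export
draw_item_bank <- function(test_length, n_dich, design = study_design(),
                           seed = NULL) {
  stopifnot(n_dich >= 1, n_dich <= test_length - 1)
  if (!is.null(seed)) set.seed(seed)
  n_poly <- test_length - n_dich
  occasions <- if (design$regime == "longitudinal")
    c("pretest", "posttest") else NA_character_

  draw_a <- function(n) {
    if (design$a_mode == "uniform")
      stats::runif(n, design$a_range[1], design$a_range[2])
    else rep(1, n)
  }
  blocks <- lapply(occasions, function(occ) {
    tag <- if (is.na(occ)) "" else paste0(substr(occ, 1, 3), "_")
    b <- stats::rnorm(n_dich, design$b_mean, design$b_sd)
    a <- draw_a(n_dich)
    dich <- do.call(bind_items, lapply(seq_len(n_dich), function(i)
      dichotomous_item(sprintf("%sd%02d", tag, i), b = b[i], a = a[i],
                       occasion = occ)))
    steps <- vapply(design$step_means,
                    function(mu) stats::rnorm(n_poly, mu, design$step_sd),
                    numeric(n_poly))
    steps <- matrix(steps, nrow = n_poly)
    poly <- do.call(bind_items, lapply(seq_len(n_poly), function(i)
      polytomous_item(sprintf("%sp%02d", tag, i), steps = steps[i, ],
                      occasion = occ)))
    bind_items(dich, poly)
  })
  test_form(do.call(bind_items, blocks), regime = design$regime)
}

#' Run one simulation condition
#'
#' For each level of the true-ability grid (growth attached by
#' [theta2_for()] in the longitudinal regime), simulates `n_reps`
#' response patterns from the model, removes degenerate (all-extreme)
#' patterns, and scores every remaining pattern with each requested
#' estimator on the identical response data.  Each replication draws
#' from its own child seed ([derive_seed()]), so individual records are
#' reproducible in isolation.
#'
#' @param form A [test_form()] (typically from [draw_item_bank()]).
#' @param design A [study_design()].
#' @param estimators Estimator names passed to the scoring machinery.
#' @param seed Master seed for the condition.
#' @param theta1_levels Subset of the ability grid to run.
#' @param n_reps Replications per level.
#' @param cond_id Integer tag mixed into child seeds.
#' @param control An [est_control()].
#' @return A list with `records` (one row per level x replication x
#'   estimator: `theta1`, `theta2`, `rep`, `estimator`, `theta1_hat`,
#'   `theta2_hat`, `converged`), `exclusions` (per-level degenerate
#'   counts) and the `form`.
#' @export
run_condition <- function(form, design = study_design(),
                          estimators = c("wle", "twle", "iwle"),
                          seed = 1L,
                          theta1_levels = design$theta1_grid,
                          n_reps = design$n_reps,
                          cond_id = 1L,
                          control = est_control()) {
  stopifnot(inherits(form, "test_form"), length(estimators) >= 1)
  longitudinal <- form$regime == "longitudinal"
  n_est <- length(estimators)
  n_lev <- length(theta1_levels)

  rec_theta1 <- rec_theta2 <- rec_rep <- rec_t1h <- rec_t2h <- rec_conv <-
    vector("list", n_lev)
  rec_est <- vector("list", n_lev)
  excl <- integer(n_lev)

  for (li in seq_len(n_lev)) {
    t1 <- theta1_levels[li]
    t2 <- if (longitudinal) theta2_for(t1, design) else NA_real_
    ability <- if (longitudinal) c(t1, t2) else t1
    t1h <- t2h <- matrix(NA_real_, n_reps, n_est)
    conv <- matrix(NA, n_reps, n_est)
    keep <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(seed, cond_id, li, r))
      resp <- simulate_responses(form, ability, n = 1L)[1L, ]
      if (detect_degenerate(form, resp)) next
      keep[r] <- TRUE
      fits <- .estimate_pattern(form, resp, estimators, control)
      for (ei in seq_len(n_est)) {
        f <- fits[[estimators[ei]]]
        t1h[r, ei] <- f$theta1
        t2h[r, ei] <- f$theta2
        conv[r, ei] <- f$converged
      }
    }
    excl[li] <- sum(!keep)
    idx <- which(keep)
    rec_theta1[[li]] <- rep(t1, length(idx) * n_est)
    rec_theta2[[li]] <- rep(t2, length(idx) * n_est)
    rec_rep[[li]] <- rep(idx, times = n_est)
    rec_est[[li]] <- rep(estimators, each = length(idx))
    rec_t1h[[li]] <- as.vector(t1h[idx, , drop = FALSE])
    rec_t2h[[li]] <- as.vector(t2h[idx, , drop = FALSE])
    rec_conv[[li]] <- as.vector(conv[idx, , drop = FALSE])
  }

  records <- data.frame(
    theta1 = unlist(rec_theta1), theta2 = unlist(rec_theta2),
    rep = unlist(rec_rep), estimator = unlist(rec_est),
    theta1_hat = unlist(rec_t1h), theta2_hat = unlist(rec_t2h),
    converged = unlist(rec_conv), stringsAsFactors = FALSE)
  exclusions <- data.frame(theta1 = theta1_levels, n_excluded = excl,
                           n_total = n_reps)
  list(records = records, exclusions = exclusions, form = form)
}

.condition_label <- function(n_dich, n_poly) sprintf("%dd+%dp", n_dich, n_poly)

.summarize_condition <- function(cond, longitudinal) {
  out <- list(
    metrics_theta1 = condition_metrics(cond$records, "theta1"),
    correlations = condition_correlations(cond$records, "theta1"),
    exclusions = cond$exclusions)
  if (longitudinal) {
    out$metrics_theta2 <- condition_metrics(cond$records, "theta2")
    out$correlations_theta2 <- condition_correlations(cond$records, "theta2")
  }
  out
}

.run_study <- function(design, estimators, seed, test_lengths, mix_ratios,
                       n_reps, control, keep_records) {
  conditions <- list()
  cond_id <- 0L
  for (len in test_lengths) {
    for (lam in mix_ratios) {
      cond_id <- cond_id + 1L
      nd <- n_dichotomous(len, lam)
      label <- .condition_label(nd, len - nd)
      form <- draw_item_bank(len, nd, design,
                             seed = derive_seed(seed, cond_id, 0L))
      cond <- run_condition(form, design, estimators,
                            seed = seed, n_reps = n_reps,
                            cond_id = cond_id, control = control)
      summ <- .summarize_condition(cond, design$regime == "longitudinal")
      summ$label <- label
      summ$test_length <- len
      summ$mix_ratio <- lam
      summ$form <- form
      if (keep_records) summ$records <- cond$records
      conditions[[label]] <- summ
    }
  }
  structure(list(conditions = conditions, design = design, seed = seed,
                 estimators = estimators, n_reps = n_reps),
            class = "simulation_summary")
}

#' Run the longitudinal growth study
#'
#' Orchestrates the full factorial of test lengths and mix ratios under
#' the two-occasion growth model: per condition, one item bank is drawn
#' and every ability level of the grid is replicated `n_reps` times,
#' scored by all requested estimators, and summarised into per-level
#' absolute bias / RMSE / RMSD tables plus pooled truth-estimate
#' correlations.
#'
#' @param design A [study_design()] (`regime` forced to longitudinal).
#' @param estimators Estimator names.
#' @param seed Master seed.
#' @param test_lengths,mix_ratios Condition subsets (defaults: all nine).
#' @param n_reps Replications per ability level.
#' @param control An [est_control()].
#' @param keep_records Keep raw replication records per condition.
#' @return A `simulation_summary`.
#' @export
run_study1 <- function(design = study_design(),
                       estimators = c("wle", "twle", "iwle"),
                       seed = 1L,
                       test_lengths = design$test_lengths,
                       mix_ratios = design$mix_ratios,
                       n_reps = design$n_reps,
                       control = est_control(),
                       keep_records = FALSE) {
  design$regime <- "longitudinal"
  .run_study(design, estimators, seed, test_lengths, mix_ratios, n_reps,
             control, keep_records)
}

#' Run the unidimensional mixed-format study
#'
#' Same grids and metrics as [run_study1()] but under the
#' unidimensional regime: a two-parameter-logistic + partial-credit
#' mixed test (discriminations drawn uniformly by default, or all 1 with
#' `a_mode = "fixed"`), comparing the maximum likelihood and
#' item-weighted likelihood estimators.
#'
#' @inheritParams run_study1
#' @param a_mode Discrimination mode, overriding the design.
#' @return A `simulation_summary`.
#' @export
run_study2 <- function(design = study_design(regime = "unidimensional",
                                             a_mode = "uniform"),
                       estimators = c("mle", "iwle"),
                       seed = 1L,
                       test_lengths = design$test_lengths,
                       mix_ratios = design$mix_ratios,
                       n_reps = design$n_reps,
                       control = est_control(),
                       keep_records = FALSE,
                       a_mode = NULL) {
  design$regime <- "unidimensional"
  if (!is.null(a_mode)) design$a_mode <- match.arg(a_mode, c("fixed", "uniform"))
  .run_study(design, estimators, seed, test_lengths, mix_ratios, n_reps,
             control, keep_records)
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("<simulation_summary> ", x$design$regime, ", ",
      length(x$conditions), " condition(s), ", x$n_reps,
      " replications/level, seed ", x$seed, "\n", sep = "")
  for (label in names(x$conditions)) {
    co <- x$conditions[[label]]
    cors <- co$correlations
    cat("  ", label, ": pooled r(theta1) ",
        paste(sprintf("%s=%.4f", toupper(cors$estimator), cors$correlation),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
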