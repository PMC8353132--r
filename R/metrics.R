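#' Monte-Carlo evaluation criteria
#'
#' Absolute bias, root mean squared error and root mean squared
#' difference of a vector of ability estimates against a true value,
#' all with population (`1/N`) denominators:
#'
#' * `abs_bias(x, theta) = |mean(x) - theta|`
#' * `rmse(x, theta) = sqrt(mean((x - theta)^2))`
#' * `rmsd(x) = sqrt(mean((x - mean(x))^2))` — estimator variability
#'   around its own mean, not error.
#'
#' The three are tied by the exact identity
#' `rmse^2 = (mean(x) - theta)^2 + rmsd^2`.
#'
#' @param estimates Numeric vector of estimates (non-empty, no `NA`).
#' @param theta_true True parameter value.
#' @return Non-negative scalar.
#' @name metrics
NULL

.check_estimates <- function(estimates) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  if (anyNA(estimates)) stop("estimates contain NA; drop excluded patterns ",
                             "before computing metrics", call. = FALSE)
  as.numeric(estimates)
}

#' @rdname metrics
#' @export
abs_bias <- function(estimates, theta_true) {
  x <- .check_estimates(estimates)
  abs(mean(x) - theta_true)
}

#' @rdname metrics
#' @export
rmse <- function(estimates, theta_true) {
  x <- .check_estimates(estimates)
  sqrt(mean((x - theta_true)^2))
}

#' @rdname metrics
#' @export
rmsd <- function(estimates) {
  x <- .check_estimates(estimates)
  sqrt(mean((x - mean(x))^2))
}

#' Correlation between true and estimated abilities
#'
#' Pearson correlation over pooled (truth, estimate) pairs, typically
#' accumulated across all ability levels and replications of a
#' simulation condition; pairs with a missing estimate (excluded
#' patterns) are dropped.
#'
#' @param theta_true Numeric vector of true values.
#' @param theta_hat Numeric vector of estimates, same length.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_true_est <- function(theta_true, theta_hat) {
  stopifnot(length(theta_true) == length(theta_hat))
  keep <- !is.na(theta_true) & !is.na(theta_hat)
  x <- theta_true[keep]; y <- theta_hat[keep]
  if (length(unique(x)) < 2L)
    stop("need at least two distinct true ability values", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("estimates have zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Per-level metric table for simulation records
#'
#' Aggregates a replication record table (as produced by
#' [run_condition()]) into the per-ability-level summary reported by the
#' simulation studies: absolute bias, RMSE and RMSD per estimator at
#' each true-ability level, with the number of non-excluded
#' replications used.
#'
#' @param records `data.frame` with columns `theta1`, `theta2`,
#'   `estimator`, `theta1_hat`, `theta2_hat`.
#' @param parameter `"theta1"` or `"theta2"`: which dimension to
#'   evaluate (levels are still indexed by the true `theta1` grid).
#' @return `data.frame` with columns `theta1`, `theta2`, `estimator`,
#'   `abs_bias`, `rmse`, `rmsd`, `n_used`.
#' @export
condition_metrics <- function(records, parameter = c("theta1", "theta2")) {
  parameter <- match.arg(parameter)
  est_col <- paste0(parameter, "_hat")
  keep <- !is.na(records[[est_col]])
  records <- records[keep, , drop = FALSE]
  key <- interaction(records$theta1, records$estimator, drop = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    x <- d[[est_col]]
    truth <- d[[parameter]][1L]
    data.frame(theta1 = d$theta1[1L], theta2 = d$theta2[1L],
               estimator = d$estimator[1L],
               abs_bias = abs_bias(x, truth),
               rmse = rmse(x, truth),
               rmsd = rmsd(x),
               n_used = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$theta1, out$estimator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled truth-estimate correlations for simulation records
#'
#' One correlation per estimator, pooling all ability levels and
#' replications of a condition (the construction that yields a single
#' number per condition).
#'
#' @inheritParams condition_metrics
#' @return `data.frame` with columns `estimator`, `parameter`,
#'   `correlation`, `n_pairs`.
#' @export
condition_correlations <- function(records,
                                   parameter = c("theta1", "theta2")) {
  parameter <- match.arg(parameter)
  est_col <- paste0(parameter, "_hat")
  pieces <- lapply(split(records, records$estimator), function(d) {
    keep <- !is.na(d[[est_col]])
    data.frame(estimator = d$estimator[1L], parameter = parameter,
               correlation = correlation_true_est(d[[parameter]][keep],
                                                  d[[est_col]][keep]),
               n_pairs = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
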