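# Shared fixture builders and independent oracles.  Everything here is
# coded directly from the model formulas (logistic response curve,
# adjacent-category partial credit probabilities, score-variance
# information), independently of the package internals it is used to
# check.

toy_long_form <- function() {
  test_form(bind_items(
    dichotomous_item("d1", b = -1, occasion = "pretest"),
    dichotomous_item("d2", b = 0, occasion = "pretest"),
    polytomous_item("p1", steps = c(-1.5, -0.5, 0.5, 1.5), occasion = "pretest"),
    dichotomous_item("d3", b = 0.5, occasion = "posttest"),
    dichotomous_item("d4", b = -0.5, occasion = "posttest"),
    polytomous_item("p2", steps = c(-1, 0, 1, 2), occasion = "posttest")
  ), regime = "longitudinal")
}

toy_uni_form <- function() {
  test_form(bind_items(
    dichotomous_item("d1", b = -1.2),
    dichotomous_item("d2", b = 0),
    dichotomous_item("d3", b = 0.7, a = 1.3),
    polytomous_item("p1", steps = c(-1.5, -0.5, 0.5, 1.5)),
    polytomous_item("p2", steps = c(-0.8, 0.2, 0.9, 1.7))
  ), regime = "unidimensional")
}

rasch_form <- function(n, b = 0) {
  test_form(do.call(bind_items, lapply(seq_len(n), function(i)
    dichotomous_item(paste0("r", i), b = b))), regime = "unidimensional")
}

# --- independent model oracles ------------------------------------------

oracle_poly_probs <- function(theta, steps) {
  h <- length(steps)
  num <- vapply(seq_len(h),
                function(j) exp(j * theta - sum(steps[seq_len(j)])),
                numeric(1))
  num / sum(num)
}

oracle_item_info <- function(item_row, theta) {
  if (item_row$kind == "dichotomous") {
    p <- 1 / (1 + exp(-item_row$a * (theta - item_row$b)))
    return(item_row$a^2 * p * (1 - p))
  }
  sc <- grep("^b[0-9]+$", names(item_row), value = TRUE)
  steps <- as.numeric(item_row[1, sc])
  steps <- steps[!is.na(steps)]
  p <- oracle_poly_probs(theta, steps)
  j <- seq_along(p)
  sum(j^2 * p) - sum(j * p)^2
}

# log-likelihood of one pattern evaluated directly from the formulas,
# with optional per-item weights; theta = c(t1) or c(t1, t2)
oracle_loglik <- function(form, resp, theta, weights = NULL) {
  t2 <- if (length(theta) > 1) theta[2] else 0
  total <- 0
  for (i in seq_len(form$n)) {
    row <- form$items[i, ]
    t_eff <- theta[1] + t2 * form$occ2[i]
    li <- if (row$kind == "dichotomous") {
      p <- 1 / (1 + exp(-row$a * (t_eff - row$b)))
      if (resp[i] == 1) log(p) else log(1 - p)
    } else {
      sc <- grep("^b[0-9]+$", names(row), value = TRUE)
      steps <- as.numeric(row[1, sc])
      steps <- steps[!is.na(steps)]
      log(oracle_poly_probs(t_eff, steps)[resp[i]])
    }
    w <- if (is.null(weights)) 1 else weights[i]
    total <- total + w * li
  }
  total
}

oracle_test_info <- function(form, theta) {
  t2 <- if (length(theta) > 1) theta[2] else 0
  sum(vapply(seq_len(form$n), function(i)
    oracle_item_info(form$items[i, ], theta[1] + t2 * form$occ2[i]),
    numeric(1)))
}

# dense-grid argmax of a 1-D objective (independent estimator oracle)
oracle_grid_argmax <- function(fn, lower = -6, upper = 6, by = 0.001) {
  grid <- seq(lower, upper, by = by)
  grid[which.max(vapply(grid, fn, numeric(1)))]
}
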